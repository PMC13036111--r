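test_that("expected influence is the signed sum of incident weights", {
  labels <- c("a", "b", "c", "d")
  W <- matrix(0, 4, 4, dimnames = list(labels, labels))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["a", "c"] <- W["c", "a"] <- 0.3
  W["a", "d"] <- W["d", "a"] <- -0.2
  net <- ising_network(setNames(rep(0, 4), labels), W,
                       setNames(c("A", "A", "B", "B"), labels))
  expect_equal(unname(expected_influence(net)["a"]), 0.6)
  empty <- ising_network(setNames(rep(0, 4), labels),
                         matrix(0, 4, 4, dimnames = list(labels, labels)),
                         setNames(c("A", "A", "B", "B"), labels))
  expect_equal(unname(expected_influence(empty)), rep(0, 4))
  perm <- c(2, 4, 1, 3)
  pnet <- ising_network(net$thresholds[perm], W[perm, perm], net$community[perm])
  expect_equal(expected_influence(pnet), expected_influence(net)[perm])
})

test_that("bridge strength and EI sum cross-community weights; betweenness counts paths", {
  labels <- c("a1", "b1", "b2")
  W <- matrix(0, 3, 3, dimnames = list(labels, labels))
  W["a1", "b1"] <- W["b1", "a1"] <- 0.4
  W["a1", "b2"] <- W["b2", "a1"] <- -0.1
  net <- ising_network(setNames(rep(0, 3), labels), W,
                       setNames(c("A", "B", "B"), labels))
  bc <- bridge_indices(net)
  expect_equal(bc$bridge_strength[bc$item == "a1"], 0.5)
  expect_equal(bc$bridge_expected_influence[bc$item == "a1"], 0.3)

  # 3-node path a1 - b1 - b2, all weights 0.5: b1 lies on the one shortest
  # path between the cross-community pair (a1, b2)
  W2 <- matrix(0, 3, 3, dimnames = list(labels, labels))
  W2["a1", "b1"] <- W2["b1", "a1"] <- 0.5
  W2["b1", "b2"] <- W2["b2", "b1"] <- 0.5
  path <- ising_network(setNames(rep(0, 3), labels), W2,
                        setNames(c("A", "B", "B"), labels))
  pb <- bridge_indices(path)
  expect_equal(pb$bridge_betweenness, c(0, 1, 0))
  # closeness of a1: mean distance to b1 (2) and b2 (4) -> 1/3
  expect_equal(pb$bridge_closeness[pb$item == "a1"], 1 / 3)
})

test_that("a single community is refused and isolated nodes score zero", {
  labels <- c("a", "b")
  net <- ising_network(setNames(c(0, 0), labels),
                       matrix(0, 2, 2, dimnames = list(labels, labels)),
                       setNames(c("A", "A"), labels))
  expect_error(bridge_indices(net), "two communities")
  iso <- random_network(5, density = 0, seed = 1)
  bi <- bridge_indices(iso)
  for (col in c("bridge_strength", "bridge_expected_influence",
                "bridge_betweenness", "bridge_closeness")) {
    expect_equal(bi[[col]], rep(0, 5))
  }
})

test_that("all indices match the brute-force path-enumeration oracle", {
  for (s in 1:20) {
    p <- sample(4:10, 1)
    net <- random_network(p, density = 0.35, seed = 300 + s)
    got <- bridge_indices(net)
    want <- oracle_bridge_indices(net)
    for (col in names(want)) {
      expect_equal(got[[col]], unname(want[[col]]), tolerance = 1e-9,
                   label = sprintf("%s (seed %d)", col, 300 + s))
    }
  }
})

test_that("bridge strength bounds |bridge EI|, with equality for all-positive networks", {
  for (s in 1:10) {
    net <- random_network(8, density = 0.5, seed = 400 + s)
    bc <- bridge_indices(net)
    expect_true(all(bc$bridge_strength >= abs(bc$bridge_expected_influence) - 1e-12))
    pos <- random_network(8, density = 0.5, seed = 400 + s, positive = TRUE)
    bp <- bridge_indices(pos)
    expect_equal(bp$bridge_strength, bp$bridge_expected_influence)
  }
})

test_that("z columns standardize each index across nodes", {
  net <- random_network(7, density = 0.5, seed = 77)
  bc <- bridge_indices(net)
  expect_equal(mean(bc$z_bridge_strength), 0, tolerance = 1e-12)
  expect_equal(sd(bc$z_bridge_strength), 1, tolerance = 1e-12)
})

make_stability <- function(df) {
  out <- tibble::as_tibble(df)
  out$index <- "bridge_strength"
  out$failed <- is.na(out$correlation)
  class(out) <- c("stability_result", class(out))
  out
}

test_that("the CS coefficient applies the all-proportions-up-to-q rule", {
  grid <- seq(0.05, 0.75, by = 0.05)
  perfect <- make_stability(tidyr::expand_grid(proportion = grid, replicate = 1:4,
                                               correlation = 1))
  expect_equal(cs_coefficient(perfect), 0.75)
  bad <- make_stability(tidyr::expand_grid(proportion = grid, replicate = 1:4,
                                           correlation = 0.3))
  expect_equal(cs_coefficient(bad), 0)
  # pass at 0.05-0.25, fail at 0.30, pass again at 0.35: CS = 0.25
  grid2 <- seq(0.05, 0.35, by = 0.05)
  df <- tidyr::expand_grid(proportion = grid2, replicate = 1:4)
  df$correlation <- ifelse(df$proportion == 0.30, 0.5, 0.9)
  expect_equal(cs_coefficient(make_stability(df)), 0.25)
  # replicate order is irrelevant
  shuffled <- make_stability(df[sample(nrow(df)), ])
  expect_equal(cs_coefficient(shuffled), 0.25)
})

test_that("case-dropping bootstrap is seeded and exact at a vanishing drop", {
  net <- random_network(6, density = 0.6, seed = 88, positive = TRUE,
                        weight_range = c(0.5, 1.2), threshold_range = c(-1.5, 0))
  dat <- generate_dataset(net, n = 400, seed = 89)
  st1 <- case_drop_bootstrap(dat, index = "bridge_strength",
                             drop_proportions = c(0.1, 0.2), B = 3, seed = 7)
  st2 <- case_drop_bootstrap(dat, index = "bridge_strength",
                             drop_proportions = c(0.1, 0.2), B = 3, seed = 7)
  expect_equal(st1, st2)
  # q so small the subsample is the full sample: correlation exactly 1
  st0 <- case_drop_bootstrap(dat, index = "bridge_strength",
                             drop_proportions = 1e-6, B = 2, seed = 7)
  expect_true(all(st0$correlation == 1))
})
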
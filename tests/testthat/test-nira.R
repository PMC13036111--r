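test_that("threshold perturbation shifts one node by multiples of the threshold SD", {
  net <- four_node()
  expect_equal(sd(net$thresholds), 1)  # hand: sd(-1,-1,-1,1) = 1
  sc <- perturb_threshold(net, "s4", "alleviating")
  expect_equal(unname(sc$perturbed_network$thresholds["s4"]), -1)
  expect_equal(sc$perturbed_network$thresholds[c("s1", "s2", "s3")],
               net$thresholds[c("s1", "s2", "s3")])
  expect_identical(sc$perturbed_network$weights, net$weights)
  # null multiplier leaves the network untouched
  null <- perturb_threshold(net, "s2", "alleviating", sd_multiplier = 0)
  expect_equal(null$perturbed_network$thresholds, net$thresholds)
  # aggravating then alleviating with the same SD referent restores the
  # original thresholds (the deltas are additive inverses); note the
  # perturbation itself changes sd(tau), hence the explicit reference
  up <- perturb_threshold(net, "s1", "aggravating", sd_multiplier = 1.5)
  down <- perturb_threshold(up$perturbed_network, "s1", "alleviating",
                            sd_multiplier = 1.5,
                            sd_reference = sd(net$thresholds))
  expect_equal(down$perturbed_network$thresholds, net$thresholds)
  expect_equal(perturb_threshold(net, "s1", "alleviating", 1.5)$delta, -up$delta)
  expect_error(perturb_threshold(net, "nope", "alleviating"), "unknown target")
  single <- ising_network(c(only = 0), matrix(0, 1, 1), c(only = "A"))
  expect_error(perturb_threshold(single, "only", "alleviating"), "SD undefined")
})

test_that("scenario simulation is seeded and a null scenario reproduces baseline", {
  net <- four_node()
  base <- simulate_scenario(net, net$item_labels, n_sim = 300, seed = 17)
  null <- perturb_threshold(net, "s1", "alleviating", sd_multiplier = 0)
  expect_identical(simulate_scenario(null, net$item_labels, n_sim = 300, seed = 17),
                   base)
  expect_identical(simulate_scenario(net, net$item_labels, n_sim = 300, seed = 17),
                   base)
})

test_that("scenario comparison reports differences, Welch tests, FDR and ranks", {
  set.seed(5)
  base <- rbinom(400, 4, 0.5)
  mk <- function(target, direction, shift) {
    list(target = target, direction = direction,
         sums = pmax(base + shift + rbinom(400, 1, 0.5) - rbinom(400, 1, 0.5), 0))
  }
  scen <- list(mk("a", "alleviating", -3), mk("b", "alleviating", -1),
               mk("c", "alleviating", 0))
  res <- compare_scenarios(base, scen)
  expect_equal(res$mean_difference,
               vapply(scen, function(s) mean(s$sums) - mean(base), numeric(1))[
                 match(res$target, c("a", "b", "c"))])
  expect_equal(res$target[res$rank == 1], "a")
  expect_equal(res$rank, rank(-abs(res$mean_difference)), ignore_attr = TRUE)
  # adjusted p matches the hand step-up oracle and is monotone in raw p
  expect_equal(res$p_adjusted, oracle_bh(res$p_value))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_equal(order(res$p_adjusted), order(res$p_value))
  # identical scenario: zero difference, t = 0
  same <- compare_scenarios(base, list(list(target = "x", direction = "alleviating",
                                            sums = base)))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$t, 0)
  # both arms constant: t undefined by policy, p = 1
  const <- compare_scenarios(rep(2L, 50),
                             list(list(target = "x", direction = "alleviating",
                                       sums = rep(2L, 50))))
  expect_true(is.na(const$t))
  expect_equal(const$p_value, 1)
})

test_that("the BH step-up oracle reproduces the textbook example", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("alleviation lowers and aggravation raises the exact expected sum score", {
  for (s in 1:4) {
    p <- sample(5:10, 1)
    net <- random_network(p, density = 0.4, seed = 500 + s, positive = TRUE,
                          weight_range = c(0.2, 0.8), threshold_range = c(-1.5, 0.5))
    base <- expected_sum_score(net)
    for (item in net$item_labels) {
      down <- perturb_threshold(net, item, "alleviating")$perturbed_network
      up <- perturb_threshold(net, item, "aggravating")$perturbed_network
      expect_lt(expected_sum_score(down), base)
      expect_gt(expected_sum_score(up), base)
    }
  }
})

test_that("a full intervention run is reproducible and correctly bookkept", {
  net <- four_node(tau = c(-1, -0.5, -1.5, 0))
  r1 <- run_nira(net, candidate_items = c("s1", "s2"), n_sim = 500, master_seed = 3)
  r2 <- run_nira(net, candidate_items = c("s1", "s2"), n_sim = 500, master_seed = 3)
  expect_equal(r1, r2)
  expect_equal(nrow(r1), 4)  # 2 candidates x 2 directions
  expect_equal(sort(unique(r1$rank)), 1:2)
  # reported difference equals the difference of the stored sum-score means
  sums <- attr(r1, "scenario_sums")
  base <- attr(r1, "baseline_sums")
  for (i in seq_len(nrow(r1))) {
    key <- paste(r1$direction[i], r1$target[i], sep = ":")
    expect_equal(r1$mean_difference[i], mean(sums[[key]]) - mean(base))
  }
  # disjoint candidate and outcome sets are a valid configuration
  cross <- run_nira(net, candidate_items = c("s1", "s2"),
                    outcome_items = c("s3", "s4"),
                    directions = "alleviating", n_sim = 200, master_seed = 4)
  expect_equal(nrow(cross), 2)
  # single candidate: BH is the identity
  one <- run_nira(net, candidate_items = "s1", directions = "alleviating",
                  n_sim = 200, master_seed = 5)
  expect_equal(one$p_adjusted, one$p_value)
})
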
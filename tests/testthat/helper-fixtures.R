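# Seeded random Ising networks for property tests. Labels item1..itemp, two
# communities split roughly in half.
random_network <- function(p, density = 0.3, seed = 1,
                           weight_range = c(-1, 1), threshold_range = c(-1, 1),
                           positive = FALSE) {
  set.seed(seed)
  labels <- paste0("item", seq_len(p))
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < density) {
        w <- runif(1, weight_range[1], weight_range[2])
        if (positive) w <- abs(w)
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  tau <- stats::setNames(runif(p, threshold_range[1], threshold_range[2]), labels)
  comm <- stats::setNames(rep(c("A", "B"), c(ceiling(p / 2), floor(p / 2))), labels)
  ising_network(tau, W, comm)
}

# Map {0,1} draws to state indices 1..2^p (bit j-1 = item j), plus the
# total-variation distance between empirical draws and an exact distribution.
state_index <- function(draws) {
  p <- ncol(draws)
  as.integer(draws %*% 2^(seq_len(p) - 1)) + 1L
}

empirical_tv <- function(draws, dist) {
  emp <- tabulate(state_index(draws), nbins = 2^dist$p) / nrow(draws)
  sum(abs(emp - dist$prob)) / 2
}

write_likert_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "likert.csv")
  writeLines(lines, path)
  path
}

# Small two-community network with hand-checkable thresholds.
four_node <- function(tau = c(-1, -1, -1, 1)) {
  labels <- paste0("s", 1:4)
  W <- matrix(0, 4, 4, dimnames = list(labels, labels))
  W["s1", "s2"] <- W["s2", "s1"] <- 0.5
  W["s3", "s4"] <- W["s4", "s3"] <- 0.4
  ising_network(stats::setNames(tau, labels), W,
                stats::setNames(c("A", "A", "B", "B"), labels))
}

two_item_community <- function(labels) {
  stats::setNames(rep(c("A", "B"), length.out = length(labels)), labels)
}
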
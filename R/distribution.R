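# All 2^p binary states, one row per state, column j = bit j - 1 of the row
# index. Item order = column order of the network.
states_matrix <- function(p) {
  idx <- 0:(2^p - 1)
  vapply(seq_len(p), function(j) as.double(bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L),
         numeric(2^p))
}

#' Exact Ising state distribution by enumeration
#'
#' Enumerates all 2^p states x in \{0,1\}^p and normalizes
#' P(x) proportional to exp(sum_i tau_i x_i + sum_\{i<j\} omega_ij x_i x_j).
#' Feasible for moderate p; beyond `cap` items use [sample_gibbs()].
#'
#' @param network An `ising_network`.
#' @param cap Enumeration cap on the number of items (default 20, about a
#'   million states).
#' @return An object of class `state_distribution`: list with `p`, `states`
#'   (2^p x p matrix), `prob`, `log_partition`.
#' @export
exact_distribution <- function(network, cap = 20L) {
  stopifnot(inherits(network, "ising_network"))
  p <- length(network$item_labels)
  if (p > cap) {
    stop(sprintf("p = %d exceeds the enumeration cap (%d); use sample_gibbs()", p, cap),
         call. = FALSE)
  }
  S <- states_matrix(p)
  colnames(S) <- network$item_labels
  # x'Wx/2 = sum_{i<j} w_ij x_i x_j for symmetric zero-diagonal W
  logw <- drop(S %*% network$thresholds) + rowSums((S %*% network$weights) * S) / 2
  logZ <- log_sum_exp(logw)
  structure(
    list(p = p, states = S, prob = exp(logw - logZ), log_partition = logZ),
    class = "state_distribution"
  )
}

#' Marginal activation probabilities of an exact distribution
#'
#' @param dist A `state_distribution`.
#' @return Named numeric vector P(x_i = 1).
#' @export
state_marginals <- function(dist) {
  stopifnot(inherits(dist, "state_distribution"))
  drop(crossprod(dist$states, dist$prob))
}

#' Draw i.i.d. samples from the exact Ising distribution
#'
#' @param network An `ising_network` with p within the enumeration cap.
#' @param n Number of draws (0 allowed).
#' @param seed Integer seed; identical seeds give identical draws.
#' @param cap Enumeration cap, as in [exact_distribution()].
#' @return A `sample_set`: list with `draws` (n x p matrix in \{0,1\}),
#'   `seed`, `method = "exact"`.
#' @export
sample_exact <- function(network, n, seed, cap = 20L) {
  dist <- exact_distribution(network, cap = cap)
  stopifnot(n >= 0)
  if (n == 0) {
    draws <- dist$states[integer(0), , drop = FALSE]
  } else {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(as.integer(seed))
    idx <- sample.int(nrow(dist$states), n, replace = TRUE, prob = dist$prob)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    draws <- dist$states[idx, , drop = FALSE]
  }
  rownames(draws) <- NULL
  structure(list(draws = draws, seed = as.integer(seed), method = "exact"),
            class = "sample_set")
}

#' Gibbs sampling from the Ising distribution
#'
#' Single-site Gibbs sampler with the full conditional
#' P(x_j = 1 | rest) = logistic(tau_j + sum_k omega_jk x_k), fixed ascending
#' scan order, for networks too large to enumerate.
#'
#' @param network An `ising_network`.
#' @param n Number of retained draws.
#' @param seed Integer seed.
#' @param burn_in Discarded initial full sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep after burn-in (default 1).
#' @return A `sample_set` with `method = "gibbs"` and the sampler settings.
#' @export
sample_gibbs <- function(network, n, seed, burn_in = 1000L, thin = 1L) {
  stopifnot(inherits(network, "ising_network"), n >= 0, burn_in >= 0, thin >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  draws <- gibbs_sample_cpp(unname(network$thresholds), unname(network$weights),
                            as.integer(n), as.integer(burn_in), as.integer(thin))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  colnames(draws) <- network$item_labels
  structure(list(draws = draws, seed = as.integer(seed), method = "gibbs",
                 burn_in = as.integer(burn_in), thin = as.integer(thin)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d draws x %d items (%s, seed %d)\n",
              nrow(x$draws), ncol(x$draws), x$method, x$seed))
  invisible(x)
}

#' Sum scores over an outcome item set
#'
#' Per simulated observation, the number of active symptoms among
#' `outcome_items` — the severity summary that intervention scenarios are
#' compared on (higher = more psychopathology).
#'
#' @param samples A `sample_set` (or a \{0,1\} matrix with item columns).
#' @param outcome_items Character vector of item labels; defaults to all
#'   items.
#' @return Integer vector, one sum score per draw.
#' @export
sum_scores <- function(samples, outcome_items = NULL) {
  draws <- if (inherits(samples, "sample_set")) samples$draws else as.matrix(samples)
  if (is.null(outcome_items)) outcome_items <- colnames(draws)
  if (length(outcome_items) == 0) stop("outcome_items must be nonempty", call. = FALSE)
  unknown <- setdiff(outcome_items, colnames(draws))
  if (length(unknown)) stop("unknown outcome items: ", paste(unknown, collapse = ", "), call. = FALSE)
  as.integer(rowSums(draws[, outcome_items, drop = FALSE]))
}

#' Exact expected sum score of an Ising network
#'
#' The expectation of the outcome sum score under the enumerated state
#' distribution — the sampling-free counterpart of simulating and averaging,
#' used to verify intervention effects without Monte-Carlo noise.
#'
#' @param network An `ising_network` with p within the enumeration cap.
#' @param outcome_items Labels to sum over (default: all items).
#' @param cap Enumeration cap.
#' @return A single number, E\[sum of active outcome items\].
#' @export
expected_sum_score <- function(network, outcome_items = NULL, cap = 20L) {
  dist <- exact_distribution(network, cap = cap)
  if (is.null(outcome_items)) outcome_items <- network$item_labels
  unknown <- setdiff(outcome_items, network$item_labels)
  if (length(unknown)) stop("unknown outcome items: ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(state_marginals(dist)[outcome_items])
}
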
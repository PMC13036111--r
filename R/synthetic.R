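#' Specification of a synthetic two-community ground-truth network
#'
#' Describes the generator for the verification networks used throughout:
#' two symptom communities (by default 5 "MW"-like and 13 "PSVU"-like
#' items), positive within-community associations, a handful of explicit
#' cross-community bridge edges with one dominant bridge, and heterogeneous
#' negative-leaning activation thresholds.
#'
#' @param n_a,n_b Community sizes (defaults 5 and 13).
#' @param labels_a,labels_b Community names (defaults `"MW"`, `"PSVU"`; item
#'   labels are `MW1..`, `PSVU1..`).
#' @param within_density Probability that a within-community pair gets an
#'   edge (default 0.3).
#' @param weight_range Uniform range for within-community weights (default
#'   `c(0.3, 0.9)`, all positive).
#' @param bridges Data frame `(from, to, weight)` of cross-community edges;
#'   the default plants three bridges with one dominant:
#'   MW5-PSVU8 at 0.8, MW5-PSVU3 at 0.4, MW1-PSVU5 at 0.35.
#' @param threshold_range Uniform range for thresholds (default `c(-2, 0)`).
#' @param seed Integer seed making the draw deterministic.
#' @return A `ground_truth_spec` list.
#' @export
ground_truth_spec <- function(n_a = 5L, n_b = 13L,
                              labels_a = "MW", labels_b = "PSVU",
                              within_density = 0.3,
                              weight_range = c(0.3, 0.9),
                              bridges = NULL,
                              threshold_range = c(-2, 0),
                              seed = 1L) {
  if (is.null(bridges)) {
    bridges <- tibble::tibble(
      from = c(paste0(labels_a, 5), paste0(labels_a, 5), paste0(labels_a, 1)),
      to = c(paste0(labels_b, 8), paste0(labels_b, 3), paste0(labels_b, 5)),
      weight = c(0.8, 0.4, 0.35)
    )
  }
  structure(
    list(n_a = n_a, n_b = n_b, labels_a = labels_a, labels_b = labels_b,
         within_density = within_density, weight_range = weight_range,
         bridges = tibble::as_tibble(bridges), threshold_range = threshold_range,
         seed = as.integer(seed)),
    class = "ground_truth_spec"
  )
}

#' Build a ground-truth Ising network from a spec
#'
#' Draws within-community edges independently with the spec's density and
#' positive uniform weights, plants exactly the listed bridge edges across
#' communities, and draws heterogeneous thresholds. Deterministic under the
#' spec's seed.
#'
#' @param spec A [ground_truth_spec()].
#' @return An `ising_network` whose community map is the two-block
#'   partition. A bridge pair falling inside one community is an error.
#' @export
make_ground_truth <- function(spec = ground_truth_spec()) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  labels <- c(paste0(spec$labels_a, seq_len(spec$n_a)),
              paste0(spec$labels_b, seq_len(spec$n_b)))
  community <- setNames(rep(c(spec$labels_a, spec$labels_b), c(spec$n_a, spec$n_b)),
                        labels)
  p <- length(labels)
  unknown <- setdiff(c(spec$bridges$from, spec$bridges$to), labels)
  if (length(unknown)) stop("bridge items not in the network: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  same <- community[spec$bridges$from] == community[spec$bridges$to]
  if (any(same)) {
    stop("bridge edges must cross communities: ",
         paste(spec$bridges$from[same], spec$bridges$to[same],
               sep = "-", collapse = ", "), call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(spec$seed)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (community[i] != community[j]) next
      if (runif(1) < spec$within_density) {
        W[i, j] <- W[j, i] <- runif(1, spec$weight_range[1], spec$weight_range[2])
      }
    }
  }
  for (r in seq_len(nrow(spec$bridges))) {
    i <- spec$bridges$from[r]; j <- spec$bridges$to[r]
    W[i, j] <- W[j, i] <- spec$bridges$weight[r]
  }
  tau <- setNames(runif(p, spec$threshold_range[1], spec$threshold_range[2]), labels)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  ising_network(tau, W, community)
}

#' Sample a binary dataset from a network
#'
#' Exact i.i.d. sampling (within the enumeration cap) wrapped into a
#' `binary_dataset` carrying the network's community map. The default
#' sample size of 1989 matches a realistic questionnaire study.
#'
#' @param network An `ising_network`.
#' @param n Number of persons (default 1989).
#' @param seed Integer seed.
#' @param cap Enumeration cap for exact sampling; larger networks fall back
#'   to Gibbs sampling with default settings.
#' @return A `binary_dataset`.
#' @export
generate_dataset <- function(network, n = 1989L, seed = 1L, cap = 20L) {
  stopifnot(inherits(network, "ising_network"))
  p <- length(network$item_labels)
  samples <- if (p <= cap) sample_exact(network, n, seed, cap = cap)
             else sample_gibbs(network, n, seed)
  binary_dataset(samples$draws, network$community)
}

#' Expand a binary dataset to synthetic Likert responses
#'
#' The constructed inverse of [binarize_likert()]: absent symptoms (0)
#' become the lowest scale point, present symptoms (1) draw a severity from
#' \{2,3,4,5\} with the given category probabilities. The severity draw is
#' deliberate noise — the pipeline discards it again at binarization — so
#' `binarize_likert(expand_to_likert(b))` reproduces `b` exactly.
#'
#' @param binary A `binary_dataset`.
#' @param seed Integer seed for the severity draws.
#' @param category_probs Probabilities over \{2,3,4,5\} (must sum to 1;
#'   default uniform).
#' @return A `likert_dataset` on the 1-5 scale.
#' @export
expand_to_likert <- function(binary, seed = 1L,
                             category_probs = rep(0.25, 4)) {
  stopifnot(inherits(binary, "binary_dataset"))
  if (length(category_probs) != 4 || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-8) {
    stop("category_probs must be 4 nonnegative values summing to 1", call. = FALSE)
  }
  v <- binary$values
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  active <- which(v == 1)
  out <- v
  out[v == 0] <- 1
  out[active] <- sample(2:5, length(active), replace = TRUE, prob = category_probs)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  likert_dataset(out, binary$community)
}

#' Edge and parameter recovery of an estimate against ground truth
#'
#' @param truth,estimate `ising_network`s over the same item labels.
#' @return A one-row tibble:
#'   \describe{
#'     \item{edge_sensitivity}{true edges recovered nonzero with the correct
#'       sign / true edges.}
#'     \item{edge_specificity}{truly absent pairs estimated as 0 / truly
#'       absent pairs.}
#'     \item{weight_correlation}{Pearson correlation of true and estimated
#'       weights over the union support (pairs nonzero in either network).}
#'     \item{threshold_correlation}{Pearson correlation of the threshold
#'       vectors.}
#'   }
#'   Undefined quantities (empty denominators, zero variance) are NA.
#' @export
recovery_metrics <- function(truth, estimate) {
  stopifnot(inherits(truth, "ising_network"), inherits(estimate, "ising_network"))
  if (!identical(truth$item_labels, estimate$item_labels)) {
    stop("truth and estimate must share item labels", call. = FALSE)
  }
  ut <- upper.tri(truth$weights)
  wt <- truth$weights[ut]
  we <- estimate$weights[ut]
  true_edge <- wt != 0
  detected <- true_edge & we != 0 & sign(we) == sign(wt)
  absent <- !true_edge
  support <- (wt != 0) | (we != 0)
  safe_cor <- function(a, b) {
    if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) NA_real_
    else cor(a, b)
  }
  tibble::tibble(
    edge_sensitivity = if (any(true_edge)) sum(detected) / sum(true_edge) else NA_real_,
    edge_specificity = if (any(absent)) sum(absent & we == 0) / sum(absent) else NA_real_,
    weight_correlation = safe_cor(wt[support], we[support]),
    threshold_correlation = safe_cor(unname(truth$thresholds), unname(estimate$thresholds))
  )
}
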
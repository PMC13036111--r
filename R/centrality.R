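#' One-step expected influence
#'
#' EI(i) = signed sum of the weights incident to node i. Unlike strength it
#' lets negative edges cancel positive ones, which is the relevant notion
#' when node states are coded \{0,1\} and activation spreads along signed
#' edges.
#'
#' @param network An `ising_network`.
#' @return Named numeric vector of per-node expected influence.
#' @export
expected_influence <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  rowSums(network$weights)
}

# Shortest-path distances (edge length 1/|w|) and shortest-path counts for
# every source. Counts follow Brandes' predecessor accumulation: a node u
# precedes v on a shortest path from s iff d(s,u) + len(u,v) = d(s,v).
shortest_path_counts <- function(weights, tol = 1e-9) {
  p <- nrow(weights)
  A <- abs(weights)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- ifelse(A > 0, 1 / A, Inf)
  D <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  } else {
    d <- matrix(Inf, p, p); diag(d) <- 0; d
  }
  sigma <- matrix(0, p, p)
  for (s in seq_len(p)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(is.finite(len[, v]) &
                      abs(D[s, ] + len[, v] - D[s, v]) <= tol * (1 + D[s, v]))
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  list(D = D, sigma = sigma, tol = tol)
}

#' Bridge centrality indices against a fixed community partition
#'
#' Quantifies how strongly each symptom connects its own community to the
#' rest of the network, relative to a partition fixed by instrument (not
#' detected from data):
#' \describe{
#'   \item{bridge_strength}{sum of `|weight|` over edges leaving the node's
#'     community.}
#'   \item{bridge_expected_influence}{the same sum, signed.}
#'   \item{bridge_betweenness}{number of shortest paths between node pairs
#'     from different communities that pass through the node (edge length
#'     `1/|weight|`; when several equal-length shortest paths exist the count
#'     is split fractionally among them; each unordered pair counted once).}
#'   \item{bridge_closeness}{inverse of the mean shortest-path distance from
#'     the node to all nodes outside its community (0 if any of them is
#'     unreachable).}
#' }
#' Each index is also returned z-standardized across nodes (`z_` columns; a
#' constant column standardizes to 0).
#'
#' @param network An `ising_network`.
#' @param partition Community assignment; defaults to the network's own map.
#'   At least two communities are required.
#' @return A `bridge_centrality` tibble: `item`, `community`,
#'   `expected_influence`, the four bridge indices, and `z_`-prefixed
#'   standardized columns.
#' @export
bridge_indices <- function(network, partition = network$community) {
  stopifnot(inherits(network, "ising_network"))
  labels <- network$item_labels
  partition <- normalize_community(partition, labels)
  if (length(unique(partition)) < 2) {
    stop("bridge centrality needs at least two communities", call. = FALSE)
  }
  W <- network$weights
  p <- length(labels)
  cross <- outer(partition, partition, "!=")
  bs <- rowSums(abs(W) * cross)
  bei <- rowSums(W * cross)

  sp <- shortest_path_counts(W)
  D <- sp$D; sigma <- sp$sigma; tol <- sp$tol
  bb <- numeric(p)
  pairs <- which(upper.tri(cross) & cross, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    s <- pairs[r, 1]; t <- pairs[r, 2]
    if (!is.finite(D[s, t])) next
    through <- setdiff(which(abs(D[s, ] + D[, t] - D[s, t]) <= tol * (1 + D[s, t])), c(s, t))
    for (v in through) {
      bb[v] <- bb[v] + sigma[s, v] * sigma[t, v] / sigma[s, t]
    }
  }
  bc <- vapply(seq_len(p), function(i) {
    d <- D[i, partition != partition[i]]
    m <- mean(d)
    if (is.finite(m) && m > 0) 1 / m else 0
  }, numeric(1))

  res <- tibble::tibble(
    item = labels,
    community = unname(partition),
    expected_influence = unname(rowSums(W)),
    bridge_strength = unname(bs),
    bridge_expected_influence = unname(bei),
    bridge_betweenness = unname(bb),
    bridge_closeness = unname(bc)
  )
  zcols <- c("expected_influence", "bridge_strength", "bridge_expected_influence",
             "bridge_betweenness", "bridge_closeness")
  for (col in zcols) {
    x <- res[[col]]
    s <- sd(x)
    res[[paste0("z_", col)]] <- if (is.na(s) || s == 0) rep(0, p) else (x - mean(x)) / s
  }
  class(res) <- c("bridge_centrality", class(res))
  res
}

#' Dot plot of standardized bridge centrality
#'
#' @param object A `bridge_centrality` tibble.
#' @param ... Unused.
#' @return A ggplot object, one panel per index, items on the y axis.
#' @export
autoplot.bridge_centrality <- function(object, ...) {
  long <- object |>
    dplyr::select("item", "community", dplyr::starts_with("z_")) |>
    tidyr::pivot_longer(dplyr::starts_with("z_"), names_to = "index",
                        names_prefix = "z_", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$item,
                                     colour = .data$community)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~index, nrow = 1) +
    ggplot2::labs(x = "z score", y = NULL) +
    ggplot2::theme_minimal()
}

index_column <- function(index) {
  choices <- c("expected_influence", "bridge_strength", "bridge_expected_influence",
               "bridge_betweenness", "bridge_closeness")
  match.arg(index, choices)
}

#' Case-dropping bootstrap stability of a centrality index
#'
#' Repeatedly drops a proportion of persons, re-estimates the whole network
#' on the subsample, recomputes the chosen index and records its Spearman
#' rank correlation with the full-sample index. Re-estimation per subsample
#' is deliberate — that is what case-dropping stability means — and is the
#' expensive part.
#'
#' @param binary A `binary_dataset`.
#' @param index Index name (one of the `bridge_indices()` columns).
#' @param drop_proportions Grid of drop proportions in (0, 1); default 0.05
#'   to 0.75 in steps of 0.05.
#' @param B Bootstrap replicates per proportion (default 500; reduce for
#'   quick checks).
#' @param seed Integer master seed; replicate subsamples are drawn from
#'   derived child seeds so the whole table is reproducible.
#' @param partition Community partition (default: the dataset's map).
#' @param gamma,rule Estimator settings passed to [estimate_network()].
#' @return A `stability_result` tibble `(index, proportion, replicate,
#'   correlation, failed)`. Replicates where estimation fails or the
#'   correlation is undefined (constant index) are marked `failed` and
#'   excluded from the CS computation.
#' @export
case_drop_bootstrap <- function(binary, index = "bridge_expected_influence",
                                drop_proportions = seq(0.05, 0.75, by = 0.05),
                                B = 500L, seed = 1L,
                                partition = binary$community,
                                gamma = 0.25, rule = "AND") {
  stopifnot(inherits(binary, "binary_dataset"), B >= 1,
            all(drop_proportions > 0 & drop_proportions < 1))
  index <- index_column(index)
  n <- binary$n_persons
  full <- bridge_indices(estimate_network(binary, gamma = gamma, rule = rule),
                         partition)[[index]]
  grid <- tidyr::expand_grid(proportion = drop_proportions, replicate = seq_len(B))
  seeds <- derive_seeds(seed, nrow(grid))
  res <- purrr::pmap(list(grid$proportion, grid$replicate, seeds), function(q, b, s) {
    keep_n <- ceiling((1 - q) * n)
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(s)
    rows <- sample.int(n, keep_n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    sub <- binary$values[rows, , drop = FALSE]
    val <- tryCatch({
      subdat <- binary_dataset(sub, binary$community)
      idx <- bridge_indices(estimate_network(subdat, gamma = gamma, rule = rule),
                            partition)[[index]]
      suppressWarnings(cor(idx, full, method = "spearman"))
    }, error = function(e) NA_real_)
    tibble::tibble(correlation = val, failed = is.na(val))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out <- dplyr::mutate(out, index = index, .before = 1)
  class(out) <- c("stability_result", class(out))
  out
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion q such that, at every tested
#' proportion up to and including q, at least `prob` of the successful
#' replicates correlate at least `cor_threshold` with the full-sample index.
#' If even the smallest proportion fails, the CS coefficient is 0. Note the
#' "every proportion up to q" clause: an isolated pass beyond a failing
#' proportion does not count.
#'
#' @param stability A `stability_result` from [case_drop_bootstrap()].
#' @param cor_threshold Correlation level to maintain (default 0.7).
#' @param prob Required fraction of replicates at or above it (default 0.95).
#' @return A single number in \{0\} or `drop_proportions`.
#' @export
cs_coefficient <- function(stability, cor_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(stability, "stability_result"))
  summ <- stability |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$proportion) |>
    dplyr::summarise(ok = mean(.data$correlation >= cor_threshold) >= prob,
                     .groups = "drop")
  all_props <- sort(unique(stability$proportion))
  qualified <- summ$ok[match(all_props, summ$proportion)]
  qualified[is.na(qualified)] <- FALSE  # proportions with no successful replicate
  run <- cumprod(qualified) == 1
  if (!any(run)) 0 else max(all_props[run])
}
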
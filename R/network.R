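#' Construct an Ising network
#'
#' The pairwise binary Markov random field used throughout: states are coded
#' \{0,1\} ("active"/"inactive"), each item has a threshold tau on the
#' log-odds scale (its autonomous activation tendency) and each unordered
#' item pair a symmetric edge weight omega (the conditional log-odds
#' association given all other items). The state convention matters: the same
#' parameters mean something different under the physics \{-1,+1\} coding.
#'
#' @param thresholds Named numeric vector tau (names = item labels), finite.
#' @param weights Symmetric numeric p x p matrix omega with zero diagonal.
#' @param community Community assignment as in [likert_dataset()].
#' @return An object of class `ising_network`.
#' @export
ising_network <- function(thresholds, weights, community) {
  p <- length(thresholds)
  if (p == 0L) stop("an Ising network needs at least one item", call. = FALSE)
  labels <- names(thresholds)
  if (is.null(labels) && !is.null(colnames(weights))) labels <- colnames(weights)
  if (is.null(labels)) stop("thresholds must be named with item labels", call. = FALSE)
  if (anyDuplicated(labels)) stop("item labels must be unique", call. = FALSE)
  thresholds <- setNames(as.numeric(thresholds), labels)
  if (any(!is.finite(thresholds))) stop("thresholds must be finite", call. = FALSE)
  weights <- as.matrix(weights)
  if (!identical(dim(weights), c(p, p))) {
    stop("weights must be a ", p, " x ", p, " matrix", call. = FALSE)
  }
  if (any(abs(weights - t(weights)) > 0)) {
    stop("weight matrix must be exactly symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal", call. = FALSE)
  dimnames(weights) <- list(labels, labels)
  community <- normalize_community(community, labels)
  structure(
    list(item_labels = labels, thresholds = thresholds, weights = weights,
         community = community),
    class = "ising_network"
  )
}

#' @export
print.ising_network <- function(x, ...) {
  p <- length(x$item_labels)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<ising_network> %d items, %d edges\n", p, ne))
  cat("communities:", paste(sprintf("%s (%d)", names(table(x$community)),
                                    table(x$community)), collapse = ", "), "\n")
  invisible(x)
}

#' Write an Ising network to JSON
#'
#' Serializes labels, thresholds, the full weight matrix and the community
#' map as keyed JSON at full double precision, so that
#' [read_ising_network()] restores the network field-for-field.
#'
#' @param network An `ising_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ising_network <- function(network, path) {
  stopifnot(inherits(network, "ising_network"))
  # reals as %.17g strings: 17 significant digits round-trip IEEE doubles
  # exactly, which plain JSON number serialization does not guarantee
  obj <- list(
    item_labels = network$item_labels,
    thresholds = sprintf("%.17g", unname(network$thresholds)),
    weights = matrix(sprintf("%.17g", unname(network$weights)),
                     nrow(network$weights)),
    community = as.list(network$community)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an Ising network from JSON
#'
#' @param path Path written by [write_ising_network()].
#' @return An `ising_network`. Asymmetric weights, a nonzero diagonal or a
#'   malformed file are errors.
#' @export
read_ising_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed network file: ", conditionMessage(e), call. = FALSE))
  required <- c("item_labels", "thresholds", "weights", "community")
  if (!all(required %in% names(obj))) {
    stop("malformed network file: missing fields ",
         paste(setdiff(required, names(obj)), collapse = ", "), call. = FALSE)
  }
  ising_network(
    thresholds = setNames(as.numeric(obj$thresholds), obj$item_labels),
    weights = matrix(as.numeric(as.matrix(obj$weights)),
                     length(obj$item_labels), length(obj$item_labels)),
    community = setNames(as.character(unlist(obj$community)), names(obj$community))
  )
}

#' Edge list of an Ising network
#'
#' @param x An `ising_network`.
#' @param display_threshold Keep only edges with `|weight|` strictly above
#'   this value (default 0: all nonzero edges).
#' @param ... Unused.
#' @return A tibble `(item_a, item_b, weight, bridge)` with one row per
#'   unordered pair with a retained edge; `bridge` flags cross-community
#'   edges.
#' @export
tidy.ising_network <- function(x, display_threshold = 0, ...) {
  p <- length(x$item_labels)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  w <- x$weights[idx]
  keep <- abs(w) > display_threshold
  tibble::tibble(
    item_a = x$item_labels[idx[keep, 1]],
    item_b = x$item_labels[idx[keep, 2]],
    weight = w[keep],
    bridge = unname(x$community[idx[keep, 1]] != x$community[idx[keep, 2]])
  )
}

#' One-row summary of an Ising network
#'
#' @param x An `ising_network`.
#' @param ... Unused.
#' @export
glance.ising_network <- function(x, ...) {
  edges <- tidy(x)
  p <- length(x$item_labels)
  tibble::tibble(
    n_items = p,
    n_communities = length(unique(x$community)),
    n_edges = nrow(edges),
    n_bridge_edges = sum(edges$bridge),
    density = nrow(edges) / (p * (p - 1) / 2),
    mean_abs_weight = if (nrow(edges)) mean(abs(edges$weight)) else 0,
    mean_threshold = mean(x$thresholds)
  )
}

#' Heatmap of an Ising weight matrix
#'
#' @param object An `ising_network`.
#' @param ... Unused.
#' @return A ggplot object: items ordered by community, tile fill = edge
#'   weight.
#' @export
autoplot.ising_network <- function(object, ...) {
  ord <- order(factor(object$community), object$item_labels)
  labels <- object$item_labels[ord]
  df <- tidyr::expand_grid(item_a = labels, item_b = labels) |>
    dplyr::mutate(weight = object$weights[cbind(.data$item_a, .data$item_b)])
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$item_a, levels = labels),
    y = factor(.data$item_b, levels = rev(labels)),
    fill = .data$weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
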
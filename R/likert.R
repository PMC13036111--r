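#' Construct a Likert dataset
#'
#' Bundles a person-by-item table of Likert responses with item labels and a
#' community assignment for each item (e.g. which instrument the item comes
#' from). This is the entry container for the whole pipeline: Likert data are
#' binarized with [binarize_likert()], the binary data feed network
#' estimation, and the community map defines the partition used by the bridge
#' centrality and intervention modules.
#'
#' @param data A data frame or integer matrix, rows = persons, columns =
#'   items. Column names are taken as item labels.
#' @param community Either a named character vector (`item label ->
#'   community`) or a two-column data frame `(item, community)` covering every
#'   item.
#' @param scale_min,scale_max Integer bounds of the response scale. Cells
#'   outside the bounds are an error, not clamped.
#' @return An object of class `likert_dataset`: a list with `values` (integer
#'   matrix), `item_labels`, `community` (named character vector) and the
#'   scale bounds.
#' @export
likert_dataset <- function(data, community, scale_min = 1L, scale_max = 5L) {
  values <- as.matrix(data)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("item", seq_len(ncol(values)))
  }
  storage.mode(values) <- "double"
  labels <- colnames(values)
  if (anyDuplicated(labels)) stop("item labels must be unique", call. = FALSE)
  if (anyNA(values)) stop("likert_dataset cannot contain missing cells; drop incomplete rows first", call. = FALSE)
  if (any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer value at row %d, item '%s'", bad[1], labels[bad[2]]), call. = FALSE)
  }
  if (any(values < scale_min | values > scale_max)) {
    bad <- which(values < scale_min | values > scale_max, arr.ind = TRUE)[1, ]
    stop(sprintf("value %g at row %d, item '%s' outside the %d-%d scale",
                 values[bad[1], bad[2]], bad[1], labels[bad[2]],
                 scale_min, scale_max), call. = FALSE)
  }
  community <- normalize_community(community, labels)
  structure(
    list(values = values, item_labels = labels, community = community,
         scale_min = as.integer(scale_min), scale_max = as.integer(scale_max)),
    class = "likert_dataset"
  )
}

normalize_community <- function(community, labels) {
  if (is.data.frame(community)) {
    community <- setNames(as.character(community[[2]]), as.character(community[[1]]))
  }
  if (is.null(names(community)) || !is.character(community)) {
    stop("community must be a named character vector or a two-column data frame", call. = FALSE)
  }
  unknown <- setdiff(names(community), labels)
  if (length(unknown)) {
    stop("community map names unknown items: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(labels, names(community))
  if (length(missing)) {
    stop("items without a community assignment: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  community[labels]
}

#' Load a person-by-item Likert table from delimited text
#'
#' Reads a CSV of integer responses, removes incomplete rows (listwise
#' deletion, mirroring the exclusion of incomplete questionnaires at intake)
#' and reports how many were dropped.
#'
#' @param path Path to a CSV file with one column per item and a header row
#'   of item labels.
#' @param community_map Community assignment passed on to [likert_dataset()]:
#'   a named character vector, a two-column data frame, or a path to a
#'   two-column CSV `(item, community)`.
#' @param scale_min,scale_max Response-scale bounds (default 1-5).
#' @param quiet Suppress the dropped-rows message.
#' @return A `likert_dataset` with attributes `rows_read` and `rows_dropped`.
#' @export
load_likert_csv <- function(path, community_map, scale_min = 1L, scale_max = 5L,
                            quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  if (is.character(community_map) && length(community_map) == 1L &&
      is.null(names(community_map)) && file.exists(community_map)) {
    community_map <- readr::read_csv(community_map, col_types = readr::cols(.default = readr::col_character()),
                                     progress = FALSE)
  }
  rows_read <- nrow(raw)
  complete <- stats::complete.cases(raw)
  rows_dropped <- sum(!complete)
  kept <- raw[complete, , drop = FALSE]
  if (!quiet && rows_dropped > 0) {
    message(sprintf("dropped %d of %d rows with missing cells", rows_dropped, rows_read))
  }
  out <- likert_dataset(kept, community_map, scale_min = scale_min, scale_max = scale_max)
  attr(out, "rows_read") <- rows_read
  attr(out, "rows_dropped") <- rows_dropped
  out
}

#' Binarize Likert responses into symptom presence
#'
#' Applies the presence coding used throughout: the lowest scale point
#' ("almost never") is coded 0 (symptom not present) and every higher
#' response is coded 1 (present). The cut is configurable via `present_min`.
#'
#' @param data A `likert_dataset`.
#' @param present_min Smallest Likert value coded as present (default
#'   `scale_min + 1`, i.e. 1 -> 0 and 2-5 -> 1 on a 1-5 scale).
#' @return A `binary_dataset`: values in \{0,1\} with the same item labels,
#'   column order and community map as the input.
#' @export
binarize_likert <- function(data, present_min = NULL) {
  stopifnot(inherits(data, "likert_dataset"))
  if (is.null(present_min)) present_min <- data$scale_min + 1L
  values <- (data$values >= present_min) * 1
  binary_dataset(values, data$community)
}

#' Construct a binary symptom dataset
#'
#' @param data Matrix or data frame with cells in \{0,1\}; column names are
#'   item labels.
#' @param community Community assignment as in [likert_dataset()].
#' @return An object of class `binary_dataset` with fields `values`,
#'   `item_labels`, `community`, `n_persons`.
#' @export
binary_dataset <- function(data, community) {
  values <- as.matrix(data)
  if (is.null(colnames(values))) colnames(values) <- paste0("item", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(values %in% c(0, 1))) {
    stop("binary_dataset values must all be 0 or 1", call. = FALSE)
  }
  labels <- colnames(values)
  if (anyDuplicated(labels)) stop("item labels must be unique", call. = FALSE)
  community <- normalize_community(community, labels)
  structure(
    list(values = values, item_labels = labels, community = community,
         n_persons = nrow(values)),
    class = "binary_dataset"
  )
}

#' Per-item descriptive statistics
#'
#' Mean and sample standard deviation (denominator n-1) of the raw Likert
#' responses, and the endorsement rate (proportion coded present) after
#' binarization — the data layer of a descriptives table.
#'
#' @param likert A `likert_dataset`.
#' @param binary The matching `binary_dataset`; defaults to
#'   `binarize_likert(likert)`.
#' @return A tibble with columns `item`, `community`, `mean`, `sd`,
#'   `endorsement`.
#' @export
item_descriptives <- function(likert, binary = binarize_likert(likert)) {
  stopifnot(inherits(likert, "likert_dataset"), inherits(binary, "binary_dataset"))
  if (!identical(likert$item_labels, binary$item_labels) ||
      nrow(likert$values) != nrow(binary$values)) {
    stop("likert and binary datasets must have matching items and rows", call. = FALSE)
  }
  tibble::tibble(
    item = likert$item_labels,
    community = unname(likert$community),
    mean = unname(colMeans(likert$values)),
    sd = unname(apply(likert$values, 2, sd)),
    endorsement = unname(colMeans(binary$values))
  )
}

#' @export
print.likert_dataset <- function(x, ...) {
  cat(sprintf("<likert_dataset> %d persons x %d items (scale %d-%d)\n",
              nrow(x$values), length(x$item_labels), x$scale_min, x$scale_max))
  cat("communities:", paste(sprintf("%s (%d)", names(table(x$community)),
                                    table(x$community)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("<binary_dataset> %d persons x %d items\n",
              x$n_persons, length(x$item_labels)))
  invisible(x)
}

#' @export
as_tibble.likert_dataset <- function(x, ...) tibble::as_tibble(x$values)

#' @export
as_tibble.binary_dataset <- function(x, ...) tibble::as_tibble(x$values)
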
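#' L1-penalized logistic regression path for one node
#'
#' Regresses one item on all other items with a lasso penalty along a
#' descending lambda grid (the eLasso building block). The intercept is
#' unpenalized; the fit is deterministic given the data and grid.
#'
#' @param binary A `binary_dataset`.
#' @param node Item label of the response.
#' @param lambda Optional descending penalty grid. By default 100
#'   log-spaced values from lambda_max (smallest penalty with an all-zero
#'   solution) down to `1e-3 * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and lower end relative to
#'   lambda_max, used when `lambda` is NULL.
#' @return A `nodewise_fit`: list with `node`, `predictors`, `lambda`,
#'   `intercept`, `coef` (predictors x lambda matrix), `k` (nonzero
#'   coefficient counts), `loglik`, `n`.
#' @export
nodewise_logistic_path <- function(binary, node, lambda = NULL,
                                   nlambda = 100L, lambda_min_ratio = 1e-3) {
  stopifnot(inherits(binary, "binary_dataset"))
  if (!node %in% binary$item_labels) stop("unknown node: ", node, call. = FALSE)
  y <- binary$values[, node]
  x <- binary$values[, setdiff(binary$item_labels, node), drop = FALSE]
  constant <- c(node[length(unique(y)) < 2],
                colnames(x)[apply(x, 2, function(v) length(unique(v)) < 2)])
  if (length(constant)) {
    stop("degenerate (constant) items: ", paste(constant, collapse = ", "), call. = FALSE)
  }
  predictors <- colnames(x)
  if (ncol(x) == 1L) {
    # glmnet requires >= 2 columns; a zero column never enters the model
    x <- cbind(x, .pad = 0)
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda,
                        nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                        standardize = TRUE)
  beta <- as.matrix(fit$beta)[predictors, , drop = FALSE]
  # deviance() for binomial glmnet is 2*(ll_saturated - ll); saturated ll = 0
  # for ungrouped binary data, so ll = -deviance/2.
  dev <- (1 - fit$dev.ratio) * fit$nulldev
  structure(
    list(node = node, predictors = rownames(beta), lambda = fit$lambda,
         intercept = as.numeric(fit$a0), coef = beta,
         k = as.integer(fit$df), loglik = -dev / 2, n = length(y)),
    class = "nodewise_fit"
  )
}

#' EBIC model selection along a penalty path
#'
#' Selects the lambda index minimizing the extended BIC,
#' `-2*loglik + k*log(n) + 2*gamma*k*log(p - 1)`, where k is the number of
#' nonzero coefficients and p - 1 the number of candidate predictors. Ties
#' are broken toward the larger penalty (sparser model). `gamma = 0` reduces
#' to the ordinary BIC.
#'
#' @param fit A `nodewise_fit`.
#' @param gamma Sparsity hyperparameter (default 0.25).
#' @param n,p Sample size and total item count; default taken from the fit.
#' @return The selected index into `fit$lambda`, with the EBIC values as
#'   attribute `"ebic"`.
#' @export
ebic_select <- function(fit, gamma = 0.25, n = fit$n, p = length(fit$predictors) + 1L) {
  stopifnot(inherits(fit, "nodewise_fit"))
  if (length(fit$lambda) == 0) stop("empty penalty grid", call. = FALSE)
  ebic <- -2 * fit$loglik + fit$k * log(n) + 2 * gamma * fit$k * log(p - 1)
  # lambda is descending, so the first minimum is the sparsest one
  idx <- which.min(ebic)
  attr(idx, "ebic") <- ebic
  idx
}

#' Estimate an Ising network by regularized nodewise logistic regression
#'
#' The eLasso procedure: each item is regressed on all others with an L1
#' penalty, the penalty is chosen per node by EBIC, and the two coefficient
#' estimates for each pair are symmetrized into a single edge weight.
#' Thresholds are the selected (penalized) intercepts. Edges are conditional
#' log-odds associations, not correlations, even though applied network
#' papers sometimes describe them in partial-correlation language.
#'
#' @param binary A `binary_dataset`; every item must take both values.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule Symmetrization rule: `"AND"` (default) keeps an edge only if
#'   both directed coefficients are nonzero; `"OR"` keeps it if either is
#'   (the missing one treated as 0). Either way the weight is the mean of the
#'   two coefficients.
#' @param nlambda,lambda_min_ratio Penalty grid controls, see
#'   [nodewise_logistic_path()].
#' @return An `ising_network` carrying the dataset's community map.
#' @export
estimate_network <- function(binary, gamma = 0.25, rule = c("AND", "OR"),
                             nlambda = 100L, lambda_min_ratio = 1e-3) {
  stopifnot(inherits(binary, "binary_dataset"))
  rule <- match.arg(rule)
  labels <- binary$item_labels
  p <- length(labels)
  if (p < 2) stop("network estimation needs at least two items", call. = FALSE)
  constant <- labels[apply(binary$values, 2, function(v) length(unique(v)) < 2)]
  if (length(constant)) {
    stop("degenerate (constant) items: ", paste(constant, collapse = ", "), call. = FALSE)
  }
  tau <- setNames(numeric(p), labels)
  B <- matrix(0, p, p, dimnames = list(labels, labels))  # B[i, j]: effect of i in node j's regression
  for (node in labels) {
    fit <- nodewise_logistic_path(binary, node, nlambda = nlambda,
                                  lambda_min_ratio = lambda_min_ratio)
    idx <- ebic_select(fit, gamma = gamma, n = fit$n, p = p)
    tau[node] <- fit$intercept[idx]
    B[fit$predictors, node] <- fit$coef[, idx]
  }
  keep <- if (rule == "AND") (B != 0) & (t(B) != 0) else (B != 0) | (t(B) != 0)
  W <- ifelse(keep, (B + t(B)) / 2, 0)
  diag(W) <- 0
  ising_network(tau, W, binary$community)
}
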
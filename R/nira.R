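#' Perturb one symptom's threshold
#'
#' Builds an intervention scenario by shifting a single node's threshold by
#' a multiple of the standard deviation of the whole threshold vector
#' (sample SD, denominator p-1): down for an alleviating intervention
#' (making the symptom less likely to activate on its own), up for an
#' aggravating one. All other parameters are untouched.
#'
#' @param network An `ising_network` with at least 2 items (the SD must be
#'   defined).
#' @param target Item label to perturb.
#' @param direction `"alleviating"` (threshold decreased) or
#'   `"aggravating"` (increased).
#' @param sd_multiplier Shift size in threshold SDs (default 2).
#' @param sd_reference The SD used as the shift unit; defaults to the sample
#'   SD of the input network's threshold vector. Pass the unperturbed
#'   network's SD explicitly when chaining perturbations, since perturbing a
#'   threshold changes the vector's SD.
#' @return An `intervention_scenario`: list with `target`, `direction`,
#'   `sd_multiplier`, `delta` (the signed shift applied) and
#'   `perturbed_network`.
#' @export
perturb_threshold <- function(network, target,
                              direction = c("alleviating", "aggravating"),
                              sd_multiplier = 2,
                              sd_reference = NULL) {
  stopifnot(inherits(network, "ising_network"))
  direction <- match.arg(direction)
  if (!target %in% network$item_labels) stop("unknown target: ", target, call. = FALSE)
  if (length(network$item_labels) < 2) {
    stop("threshold SD undefined for a single-item network", call. = FALSE)
  }
  if (is.null(sd_reference)) sd_reference <- sd(network$thresholds)
  shift <- sd_multiplier * sd_reference
  delta <- if (direction == "alleviating") -shift else shift
  perturbed <- network
  perturbed$thresholds[target] <- perturbed$thresholds[target] + delta
  structure(
    list(target = target, direction = direction, sd_multiplier = sd_multiplier,
         delta = delta, perturbed_network = perturbed),
    class = "intervention_scenario"
  )
}

#' Simulate sum scores under an intervention scenario
#'
#' Draws `n_sim` observations from the scenario's perturbed network (exact
#' sampling when the item count is within the enumeration cap, Gibbs
#' otherwise) and returns the outcome sum score of each draw.
#'
#' @param scenario An `intervention_scenario` (or an `ising_network`, taken
#'   as an unperturbed baseline).
#' @param outcome_items Item labels the sum score counts over.
#' @param n_sim Number of simulated observations (default 5000).
#' @param seed Integer seed.
#' @param cap Enumeration cap for exact sampling.
#' @param burn_in,thin Gibbs settings used beyond the cap.
#' @return Integer vector of `n_sim` sum scores.
#' @export
simulate_scenario <- function(scenario, outcome_items, n_sim = 5000L, seed = 1L,
                              cap = 20L, burn_in = 1000L, thin = 1L) {
  network <- if (inherits(scenario, "intervention_scenario")) {
    scenario$perturbed_network
  } else {
    stopifnot(inherits(scenario, "ising_network"))
    scenario
  }
  p <- length(network$item_labels)
  samples <- if (p <= cap) {
    sample_exact(network, n_sim, seed, cap = cap)
  } else {
    sample_gibbs(network, n_sim, seed, burn_in = burn_in, thin = thin)
  }
  sum_scores(samples, outcome_items)
}

#' Compare perturbed sum scores against baseline
#'
#' For each scenario: Welch two-sample t-test of perturbed versus baseline
#' sum scores, mean difference (perturbed - baseline) with its 95% CI,
#' Benjamini-Hochberg FDR adjustment across scenarios within each
#' direction, and rank by absolute mean difference within direction (1 =
#' largest projected effect). If both vectors have zero variance the t
#' statistic is undefined and is reported as NA with p = 1.
#'
#' @param baseline Integer vector of baseline sum scores.
#' @param scenarios List of lists, each with `target`, `direction`, `sums`.
#' @return A `nira_result` tibble: `target`, `direction`, `baseline_mean`,
#'   `perturbed_mean`, `mean_difference`, `conf_low`, `conf_high`, `t`,
#'   `df`, `p_value`, `p_adjusted`, `rank`.
#' @export
compare_scenarios <- function(baseline, scenarios) {
  rows <- purrr::map(scenarios, function(sc) {
    sums <- sc$sums
    if (sd(sums) == 0 && sd(baseline) == 0) {
      d <- mean(sums) - mean(baseline)
      tibble::tibble(target = sc$target, direction = sc$direction,
                     baseline_mean = mean(baseline), perturbed_mean = mean(sums),
                     mean_difference = d, conf_low = d, conf_high = d,
                     t = NA_real_, df = NA_real_, p_value = 1)
    } else {
      tt <- t.test(sums, baseline)
      tibble::tibble(target = sc$target, direction = sc$direction,
                     baseline_mean = mean(baseline), perturbed_mean = mean(sums),
                     mean_difference = mean(sums) - mean(baseline),
                     conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value)
    }
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"),
                  rank = rank(-abs(.data$mean_difference), ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$direction, .data$rank)
  class(out) <- c("nira_result", class(out))
  out
}

#' Simulated network intervention analysis
#'
#' The full intervention-simulation loop: simulate a baseline from the
#' estimated network, then for every candidate symptom and direction
#' perturb that symptom's threshold by `sd_multiplier` threshold-SDs,
#' re-simulate, and compare outcome sum scores against baseline
#' ([compare_scenarios()]). The symptom with the largest absolute change in
#' mean sum score ranks first as the projected intervention target. The
#' baseline is simulated once per run and shared across comparisons; every
#' simulation uses its own child seed derived from `master_seed`.
#'
#' @param network An `ising_network`.
#' @param candidate_items Symptoms to perturb (e.g. one community's items).
#' @param outcome_items Symptoms whose sum score is the outcome. The default
#'   is every item — the sum score then reflects the overall state of the
#'   network, the procedure's usual convention. A subset (e.g. the other
#'   community's items, to isolate cross-community spill-over) is equally
#'   valid and may be disjoint from the candidates.
#' @param directions Subset of `c("alleviating", "aggravating")`.
#' @param n_sim Observations per simulation (default 5000).
#' @param sd_multiplier Threshold shift in SDs (default 2).
#' @param master_seed Integer seed governing the whole run.
#' @param cap,burn_in,thin Sampler settings, see [simulate_scenario()].
#' @return A `nira_result` tibble (see [compare_scenarios()]); the baseline
#'   sum scores and per-scenario sums are attached as attributes
#'   `baseline_sums` and `scenario_sums`.
#' @export
run_nira <- function(network, candidate_items,
                     outcome_items = network$item_labels,
                     directions = c("alleviating", "aggravating"),
                     n_sim = 5000L, sd_multiplier = 2, master_seed = 1L,
                     cap = 20L, burn_in = 1000L, thin = 1L) {
  stopifnot(inherits(network, "ising_network"),
            length(candidate_items) > 0, length(outcome_items) > 0)
  directions <- match.arg(directions, several.ok = TRUE)
  unknown <- setdiff(c(candidate_items, outcome_items), network$item_labels)
  if (length(unknown)) stop("unknown items: ", paste(unknown, collapse = ", "), call. = FALSE)
  grid <- tidyr::expand_grid(direction = directions, target = candidate_items)
  seeds <- derive_seeds(master_seed, nrow(grid) + 1L)
  baseline <- simulate_scenario(network, outcome_items, n_sim = n_sim,
                                seed = seeds[1], cap = cap,
                                burn_in = burn_in, thin = thin)
  scenarios <- purrr::pmap(list(grid$target, grid$direction, seeds[-1]),
                           function(target, direction, seed) {
    sc <- perturb_threshold(network, target, direction, sd_multiplier)
    list(target = target, direction = direction,
         sums = simulate_scenario(sc, outcome_items, n_sim = n_sim, seed = seed,
                                  cap = cap, burn_in = burn_in, thin = thin))
  })
  out <- compare_scenarios(baseline, scenarios)
  attr(out, "baseline_sums") <- baseline
  attr(out, "scenario_sums") <- setNames(
    purrr::map(scenarios, "sums"),
    paste(grid$direction, grid$target, sep = ":")
  )
  out
}

#' One-row summary of an intervention run
#'
#' @param x A `nira_result`.
#' @param alpha Significance level applied to the FDR-adjusted p-values.
#' @param ... Unused.
#' @return A tibble with, per direction, the top-ranked target, its mean
#'   difference and adjusted p, and the number of significant scenarios.
#' @export
glance.nira_result <- function(x, alpha = 0.05, ...) {
  x |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      top_target = .data$target[.data$rank == 1],
      top_mean_difference = .data$mean_difference[.data$rank == 1],
      top_p_adjusted = .data$p_adjusted[.data$rank == 1],
      n_significant = sum(.data$p_adjusted < alpha),
      .groups = "drop"
    )
}

#' Dot-and-interval plot of projected intervention effects
#'
#' @param object A `nira_result`.
#' @param ... Unused.
#' @return A ggplot: perturbed mean sum score with 95% CI of the difference
#'   re-centred on the perturbed mean, one panel per direction, targets
#'   ordered by rank, baseline mean as a dashed reference line.
#' @export
autoplot.nira_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      target = stats::reorder(.data$target, -.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$perturbed_mean, y = .data$target)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$baseline_mean),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$baseline_mean + .data$conf_low,
      xmax = .data$baseline_mean + .data$conf_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~direction, scales = "free_x") +
    ggplot2::labs(x = "mean outcome sum score", y = NULL) +
    ggplot2::theme_minimal()
}
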
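# metrics whose zero-lag self-comparison row is identically trivial and is
# therefore excluded from phase-lag-averaged objectives
.comparison_metrics <- c("rdm", "dotp", "delta_dotp")

# per-individual, per-montage phase-lag-aggregated objective values
.objective_table <- function(records, metric, candidates, aggregate,
                             direction) {
  sub <- dplyr::filter(records, .data$metric == !!metric,
                       .data$montage_id %in% candidates)
  if (metric %in% .comparison_metrics) {
    sub <- dplyr::filter(sub, .data$phase_lag != 0)
  }
  agg_fun <- if (aggregate == "mean") mean else
    if (direction == "minimize") max else min
  obj <- dplyr::summarise(
    dplyr::group_by(sub, .data$individual_id, .data$montage_id),
    objective = agg_fun(.data$value), n_lags = dplyr::n(),
    .groups = "drop"
  )
  n_lag <- unique(obj$n_lags)
  if (length(n_lag) != 1L ||
      nrow(obj) != length(unique(obj$individual_id)) * length(candidates)) {
    stop("records are missing (individual, montage, phase lag) cells for ",
         "metric '", metric, "'")
  }
  obj$n_lags <- NULL
  obj
}

#' Select the best montage per individual
#'
#' For every individual, picks the candidate montage optimizing the
#' phase-lag-aggregated value of one metric (mean over lags by default;
#' the zero-lag self-comparison rows of rdm / dotp / delta_dotp are
#' excluded as identically trivial). Ties break deterministically by
#' montage id order.
#'
#' @param records metric table from [cohort_metrics()].
#' @param metric objective metric name (e.g. `"delta_dotp"`, `"rdm"`).
#' @param region_set region set the objective is evaluated on (default
#'   `"M1s"`, the stimulation targets).
#' @param direction `"minimize"` (default for rdm / delta_dotp) or
#'   `"maximize"` (default for peaks and areas).
#' @param candidates candidate montage ids; default all in `records`.
#' @param aggregate `"mean"` over phase lags (default) or `"worst"`
#'   (max when minimizing, min when maximizing).
#' @return An object of class `montage_selection`: tibble with one row per
#'   individual (`individual_id`, `montage_id`, `objective`) plus
#'   attributes `metric`, `direction`, `candidates`.
#' @export
select_best_montage <- function(records, metric, region_set = "M1s",
                                direction = NULL, candidates = NULL,
                                aggregate = c("mean", "worst")) {
  aggregate <- match.arg(aggregate)
  if (is.null(direction)) {
    direction <- if (metric %in% c("rdm", "delta_dotp")) "minimize"
    else "maximize"
  }
  direction <- match.arg(direction, c("minimize", "maximize"))
  records <- dplyr::filter(records, .data$region_set %in% !!region_set)
  if (is.null(candidates)) candidates <- sort(unique(records$montage_id))
  obj <- .objective_table(records, metric, candidates, aggregate,
                          direction)
  obj <- dplyr::arrange(obj, .data$individual_id, .data$montage_id)
  pick <- dplyr::slice(
    dplyr::group_by(obj, .data$individual_id),
    if (direction == "minimize") which.min(.data$objective)
    else which.max(.data$objective)
  )
  pick <- dplyr::ungroup(pick)
  structure(pick, metric = metric, direction = direction,
            candidates = candidates, region_set = region_set,
            class = c("montage_selection", class(pick)))
}

#' Fraction of individuals best served by each candidate montage
#'
#' The group-level overview that motivates (or not) individualization: if
#' one montage is best for nearly everyone, a fixed choice suffices.
#'
#' @param selection a `montage_selection`.
#' @return tibble with `montage_id`, `n`, `fraction` (percent), sorted
#'   descending.
#' @export
selection_fractions <- function(selection) {
  tab <- dplyr::count(tibble::as_tibble(selection), .data$montage_id,
                      name = "n")
  tab$fraction <- 100 * tab$n / sum(tab$n)
  dplyr::arrange(tab, dplyr::desc(.data$n), .data$montage_id)
}

#' Individualized vs best fixed montage
#'
#' Compares per-individual montage selection against the single fixed
#' montage with the best population-average objective: the mean objective
#' (over individuals and phase lags) and its inter-individual CV
#' (computed per lag across individuals, then averaged over lags) under
#' both strategies. By construction the individualized mean can never be
#' worse than the fixed-best mean.
#'
#' @inheritParams select_best_montage
#' @return An object of class `individualization_summary`: list with
#'   `mean_fixed_best`, `mean_individualized`, `cv_fixed_best`,
#'   `cv_individualized`, `fixed_best_montage`, `selection` (the
#'   `montage_selection`) and `fractions`.
#' @export
individualized_summary <- function(records, metric, region_set = "M1s",
                                   direction = NULL, candidates = NULL,
                                   aggregate = c("mean", "worst")) {
  aggregate <- match.arg(aggregate)
  sel <- select_best_montage(records, metric, region_set, direction,
                             candidates, aggregate)
  direction <- attr(sel, "direction")
  candidates <- attr(sel, "candidates")
  sub <- dplyr::filter(records, .data$region_set %in% !!region_set,
                       .data$metric == !!metric,
                       .data$montage_id %in% candidates)
  if (metric %in% .comparison_metrics) {
    sub <- dplyr::filter(sub, .data$phase_lag != 0)
  }
  by_montage <- dplyr::summarise(
    dplyr::group_by(sub, .data$montage_id),
    mean_obj = mean(.data$value), .groups = "drop"
  )
  fixed_best <- by_montage$montage_id[
    if (direction == "minimize") which.min(by_montage$mean_obj)
    else which.max(by_montage$mean_obj)
  ]
  fixed_rows <- dplyr::filter(sub, .data$montage_id == fixed_best)
  ind_rows <- dplyr::inner_join(
    sub, tibble::as_tibble(sel)[c("individual_id", "montage_id")],
    by = c("individual_id", "montage_id")
  )
  cv_lagavg <- function(rows) {
    # lags where every individual scores exactly 0 (e.g. delta_dotp of a
    # perfectly separated montage) have no defined CV and are skipped
    safe_cv <- function(v) if (mean(v) == 0) NA_real_ else
      coefficient_of_variation(v)
    per_lag <- dplyr::summarise(
      dplyr::group_by(rows, .data$phase_lag),
      cv = safe_cv(.data$value), .groups = "drop"
    )
    mean(per_lag$cv, na.rm = TRUE)
  }
  structure(
    list(metric = metric, direction = direction,
         fixed_best_montage = fixed_best,
         mean_fixed_best = mean(fixed_rows$value),
         mean_individualized = mean(ind_rows$value),
         cv_fixed_best = cv_lagavg(fixed_rows),
         cv_individualized = cv_lagavg(ind_rows),
         selection = sel, fractions = selection_fractions(sel)),
    class = "individualization_summary"
  )
}

#' @export
print.individualization_summary <- function(x, ...) {
  cat("Montage individualization (", x$metric, ", ", x$direction, ")\n",
      "  fixed best montage:  ", x$fixed_best_montage,
      "  mean ", format(x$mean_fixed_best, digits = 3),
      ", CV ", format(x$cv_fixed_best, digits = 3), "%\n",
      "  individualized:      mean ",
      format(x$mean_individualized, digits = 3),
      ", CV ", format(x$cv_individualized, digits = 3), "%\n", sep = "")
  invisible(x)
}
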
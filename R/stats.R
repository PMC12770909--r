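# run code with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Hermans-Rasson second-form kernel evaluated at angle differences (rad)
.whr_kernel <- function(delta) {
  d <- abs(delta) %% (2 * pi)
  abs(pi - d) - pi / 2 + 2.895 * (abs(sin(d)) - 2 / pi)
}

#' Weighted Hermans-Rasson statistic
#'
#' Circular-uniformity statistic for angles carrying non-negative weights:
#' \deqn{T = \sum_i \sum_j w_i w_j [\, |\pi - |\theta_i - \theta_j|| - \pi/2
#'           + 2.895 (|\sin(\theta_i - \theta_j)| - 2/\pi) \,]}
#' The kernel depends only on angle differences, so T is invariant to a
#' common rotation of all angles. Significance is obtained by permutation
#' ([phase_modulation_test()]), not from an asymptotic null, so the
#' statistic is a pure ranking device.
#'
#' @param angles angles in radians.
#' @param weights non-negative weights, same length.
#' @return scalar statistic.
#' @export
whr_statistic <- function(angles, weights) {
  if (length(angles) != length(weights)) stop("length mismatch")
  if (length(angles) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(angles)) || any(!is.finite(weights))) {
    stop("angles and weights must be finite")
  }
  k <- .whr_kernel(outer(angles, angles, `-`))
  as.numeric(crossprod(weights, k %*% weights))
}

#' Permutation test for phase-lag modulation of one metric
#'
#' Tests whether a metric is modulated across phase lags for one
#' (metric, montage, region set) cell. The observed weighted Hermans-Rasson
#' statistic uses the phase lags as angles and the metric values, min-max
#' scaled to `[0, 1]` over the cell, as weights, pooling all individuals.
#' The null distribution is built by permuting the phase-lag labels
#' *within each individual* independently (preserving each individual's
#' value multiset) and recomputing the statistic;
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)`.
#'
#' @param records tibble with columns `individual_id`, `phase_lag`,
#'   `value`, covering every individual at every lag exactly once.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the permutation stream is private and the
#'   caller's RNG state is untouched.
#' @return An object of class `tacs_phase_test`: list with `statistic`,
#'   `p_raw`, `n_perm`, `seed`, `n_individuals`, `n_lags`.
#' @export
phase_modulation_test <- function(records, n_perm = 10000, seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  lag_levels <- sort(unique(records$phase_lag))
  nl <- length(lag_levels)
  inds <- unique(records$individual_id)
  ni <- length(inds)
  if (nrow(records) != ni * nl ||
      anyDuplicated(records[c("individual_id", "phase_lag")])) {
    stop("records must cover every individual x phase lag exactly once")
  }
  rng <- range(records$value)
  w <- if (rng[2] > rng[1]) {
    (records$value - rng[1]) / (rng[2] - rng[1])
  } else {
    rep(0.5, nrow(records))
  }
  # W[i, l]: scaled value of individual i at lag l
  ii <- match(records$individual_id, inds)
  ll <- match(records$phase_lag, lag_levels)
  W <- matrix(NA_real_, ni, nl)
  W[cbind(ii, ll)] <- w
  k8 <- .whr_kernel(outer(lag_levels, lag_levels, `-`))
  # T = s' K s with per-lag weight sums: identical to the O(n^2) double sum
  # because the kernel only depends on which lags a pair of rows carries
  t_of <- function(s) as.numeric(crossprod(s, k8 %*% s))
  t_obs <- t_of(colSums(W))
  t_perm <- .with_seed(seed, {
    s_mat <- matrix(0, n_perm, nl)
    for (i in seq_len(ni)) {
      idx <- vapply(seq_len(n_perm), function(r) sample.int(nl),
                    integer(nl))
      s_mat <- s_mat + matrix(W[i, idx], n_perm, nl, byrow = TRUE)
    }
    # each row of W enters every permutation once: value multisets preserved
    rowSums((s_mat %*% k8) * s_mat)
  })
  # relative slack so the observed arrangement, when regenerated by a
  # permutation, always counts despite floating-point path differences
  p_raw <- (1 + sum(t_perm >= t_obs - 1e-9 * (1 + abs(t_obs)))) /
    (1 + n_perm)
  structure(
    list(statistic = t_obs, p_raw = p_raw, n_perm = as.integer(n_perm),
         seed = seed, n_individuals = ni, n_lags = nl),
    class = "tacs_phase_test"
  )
}

#' @export
print.tacs_phase_test <- function(x, ...) {
  cat("Weighted Hermans-Rasson permutation test\n",
      "T = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_raw, digits = 4),
      " (", x$n_perm, " permutations, ", x$n_individuals,
      " individuals x ", x$n_lags, " lags)\n", sep = "")
  invisible(x)
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm correction (monotone, capped at 1), as applied across
#' montages within each metric and region set.
#'
#' @param p_values raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_correct <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n-1 denominator) over the mean, times 100.
#' The inter-individual variability measure: computed across individuals
#' for each (metric, montage, phase lag), then averaged across lags (see
#' [metric_cv()]).
#'
#' @param values numeric vector; mean must be nonzero.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 3))  # 70.71
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(values) / m * 100
}

#' Run phase-lag modulation tests over a metric table
#'
#' Applies [phase_modulation_test()] to every (metric, region set, montage)
#' cell of a long metric table and Holm-adjusts p-values across montages
#' within each metric and region set. Peak metrics enter as the
#' max-over-time values and the comparison metrics as time-averages, which
#' is how [compute_metrics()] already reports them.
#'
#' @param records metric table from [compute_metrics()] /
#'   [cohort_metrics()] (columns `individual_id`, `montage_id`,
#'   `phase_lag`, `region_set`, `metric`, `value`).
#' @param metrics metrics to test; default all present.
#' @param n_perm permutations per test.
#' @param seed integer seed; each cell gets an independent substream.
#' @param alpha significance level recorded in the summary.
#' @return An object of class `tacs_phase_tests` with a `table` tibble
#'   (metric, montage_id, region_set, statistic, p_raw, p_adjusted,
#'   n_permutations, seed); use [generics::tidy()] / [generics::glance()].
#' @export
test_phase_modulation <- function(records, metrics = NULL, n_perm = 10000,
                                  seed = NULL, alpha = 0.05) {
  if (is.null(metrics)) metrics <- unique(records$metric)
  cells <- dplyr::distinct(
    dplyr::filter(records, .data$metric %in% metrics),
    .data$metric, .data$region_set, .data$montage_id
  )
  cells <- dplyr::arrange(cells, .data$metric, .data$region_set,
                          .data$montage_id)
  res <- purrr::pmap_dfr(cells, function(metric, region_set, montage_id) {
    sub <- records[records$metric == metric &
                     records$region_set == region_set &
                     records$montage_id == montage_id, ]
    cell_seed <- if (is.null(seed)) NULL else {
      (seed + 7919L * (which(cells$metric == metric &
                               cells$region_set == region_set &
                               cells$montage_id == montage_id)[1L])) %%
        .Machine$integer.max
    }
    tst <- phase_modulation_test(sub, n_perm = n_perm, seed = cell_seed)
    tibble::tibble(metric = metric, montage_id = montage_id,
                   region_set = region_set, statistic = tst$statistic,
                   p_raw = tst$p_raw)
  })
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$metric, .data$region_set),
    p_adjusted = holm_correct(.data$p_raw)
  )
  res <- dplyr::ungroup(res)
  res$n_permutations <- as.integer(n_perm)
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  structure(list(table = res, alpha = alpha, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "tacs_phase_tests")
}

#' @export
print.tacs_phase_tests <- function(x, ...) {
  cat("Phase-lag modulation tests (", nrow(x$table), " cells, ",
      x$n_perm, " permutations)\n", sep = "")
  print(x$table, n = 20)
  invisible(x)
}

#' Inter-individual variability of each metric
#'
#' CV across individuals for every (metric, montage, region set, phase
#' lag), then averaged across phase lags, in percent.
#'
#' @inheritParams test_phase_modulation
#' @return tibble with one row per (metric, montage_id, region_set) and a
#'   `cv` column in percent.
#' @export
metric_cv <- function(records) {
  # the zero-lag self-comparison rows of rdm / delta_dotp are identically 0
  # across individuals (mean 0, CV undefined); they are skipped in the
  # per-lag CVs and the remaining lags averaged
  safe_cv <- function(v) if (mean(v) == 0) NA_real_ else
    coefficient_of_variation(v)
  per_lag <- dplyr::summarise(
    dplyr::group_by(records, .data$metric, .data$montage_id,
                    .data$region_set, .data$phase_lag),
    cv = safe_cv(.data$value), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_lag, .data$metric, .data$montage_id,
                    .data$region_set),
    cv = mean(.data$cv, na.rm = TRUE), .groups = "drop"
  )
}
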
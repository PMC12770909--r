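#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single phase-modulation test
#'
#' @param x a `tacs_phase_test`.
#' @param ... unused.
#' @return one-row tibble with `statistic`, `p_raw`, `n_permutations`,
#'   `n_individuals`, `n_lags`.
#' @method tidy tacs_phase_test
#' @export
tidy.tacs_phase_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_raw = x$p_raw,
                 n_permutations = x$n_perm,
                 n_individuals = x$n_individuals, n_lags = x$n_lags)
}

#' Tidy a table of phase-modulation tests
#'
#' @param x a `tacs_phase_tests` object from [test_phase_modulation()].
#' @param ... unused.
#' @return the per-cell test table (metric, montage_id, region_set,
#'   statistic, p_raw, p_adjusted, n_permutations, seed).
#' @method tidy tacs_phase_tests
#' @export
tidy.tacs_phase_tests <- function(x, ...) x$table

#' One-row summary of a table of phase-modulation tests
#'
#' @inheritParams tidy.tacs_phase_tests
#' @return tibble with the number of cells tested, number significant
#'   after Holm correction at `alpha`, `alpha`, `n_permutations`, `seed`.
#' @method glance tacs_phase_tests
#' @export
glance.tacs_phase_tests <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$table),
    n_significant = sum(x$table$p_adjusted < x$alpha),
    alpha = x$alpha,
    n_permutations = x$n_perm,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Tidy an individualization summary
#'
#' @param x an `individualization_summary`.
#' @param ... unused.
#' @return two-row tibble comparing the fixed-best and individualized
#'   strategies (mean objective and inter-individual CV).
#' @method tidy individualization_summary
#' @export
tidy.individualization_summary <- function(x, ...) {
  tibble::tibble(
    strategy = c("fixed_best", "individualized"),
    montage = c(x$fixed_best_montage, "per-individual"),
    mean = c(x$mean_fixed_best, x$mean_individualized),
    cv = c(x$cv_fixed_best, x$cv_individualized)
  )
}
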
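#' Two-sided field-value cleanup mask
#'
#' Field post-processing applies two thresholds before any metric is
#' computed: values above the 99.9th percentile are *excluded* (numerical
#' outliers of the forward solve), and values below 2% of that percentile
#' are *set to zero* (negligible contributions whose direction is
#' unreliable). Excluded nodes leave the metric node set entirely; zeroed
#' nodes stay in the set with value 0, so their area still counts in
#' area-weighted denominators.
#'
#' The percentile uses linear interpolation between order statistics
#' (`stats::quantile` type 7). Masking is scale-invariant and idempotent on
#' the surviving values.
#'
#' @param values non-negative per-node scalars (field magnitudes or absolute
#'   normal components), at least 10 of them.
#' @param pct upper percentile (default 99.9).
#' @param floor_frac zeroing floor as a fraction of the upper threshold
#'   (default 0.02).
#' @return An object of class `threshold_mask`: list with logical vectors
#'   `excluded` and `zeroed` (disjoint), and scalars `upper` and `lower`.
#' @examples
#' m <- threshold_mask(c(rep(1, 999), 100))
#' which(m$excluded)   # the outlier
#' @export
threshold_mask <- function(values, pct = 99.9, floor_frac = 0.02) {
  if (length(values) < 10L) stop("need at least 10 values")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("`values` must be finite and non-negative")
  }
  upper <- unname(stats::quantile(values, pct / 100, type = 7))
  if (upper == 0) {
    warning("all values are zero; empty mask")
    return(structure(
      list(excluded = rep(FALSE, length(values)),
           zeroed = rep(FALSE, length(values)),
           upper = 0, lower = 0),
      class = "threshold_mask"
    ))
  }
  lower <- floor_frac * upper
  excluded <- values > upper
  zeroed <- !excluded & values < lower
  structure(
    list(excluded = excluded, zeroed = zeroed, upper = upper, lower = lower),
    class = "threshold_mask"
  )
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat("<threshold_mask> ", sum(x$excluded), " excluded, ", sum(x$zeroed),
      " zeroed of ", length(x$excluded), " nodes (upper ",
      format(x$upper, digits = 4), ", floor ",
      format(x$lower, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Apply a threshold mask to a per-node series
#'
#' Rows of excluded nodes are dropped; rows of zeroed nodes are set to 0.
#'
#' @param series numeric matrix (nodes x time steps) or vector.
#' @param mask a `threshold_mask` on the same node set.
#' @return list with `series` (masked matrix over kept nodes) and `kept`
#'   (integer indices of retained nodes in the original node set).
#' @export
apply_mask <- function(series, mask) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  if (nrow(series) != length(mask$excluded)) stop("node count mismatch")
  series[mask$zeroed, ] <- 0
  kept <- which(!mask$excluded)
  list(series = series[kept, , drop = FALSE], kept = kept)
}

#' Export a threshold mask as a tidy table
#'
#' @param mask a `threshold_mask`.
#' @return tibble with 0-based `node_index` and `status` in
#'   kept / excluded / zeroed, the on-disk mask exchange format.
#' @export
mask_table <- function(mask) {
  status <- rep("kept", length(mask$excluded))
  status[mask$zeroed] <- "zeroed"
  status[mask$excluded] <- "excluded"
  tibble::tibble(node_index = seq_along(status) - 1L, status = status)
}
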
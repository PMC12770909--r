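#' @keywords internal
.col_norms <- function(m) sqrt(colSums(m^2))

# steps retained by the degenerate-step guard: both series' norms must be
# at least `tol` times that series' own maximum step norm
.retained_steps <- function(n0, nphi, tol = 1e-8) {
  if (max(n0) == 0 || max(nphi) == 0) return(integer(0))
  which(n0 >= tol * max(n0) & nphi >= tol * max(nphi))
}

#' Peak E-field magnitude over a region
#'
#' The maximum Euclidean field norm over all kept region nodes and all time
#' steps, the standard estimate of delivered field strength.
#'
#' @param field a `tacs_field`.
#' @param mask optional `threshold_mask` (computed on the magnitude
#'   envelope); excluded nodes are dropped, zeroed nodes count as 0.
#' @param region integer node indices; default all nodes.
#' @return scalar, V/m.
#' @export
peak_magnitude <- function(field, mask = NULL, region = NULL) {
  m <- field_magnitudes(field)
  if (is.null(region)) region <- seq_len(nrow(m))
  if (!is.null(mask)) {
    m[mask$zeroed, ] <- 0
    region <- setdiff(region, which(mask$excluded))
  }
  if (length(region) == 0L) stop("region empty after masking")
  max(m[region, , drop = FALSE])
}

#' Peak cortex-normal field component over a region
#'
#' The maximum *absolute* signed normal component over kept region nodes and
#' time steps — the "effective" peak in the direction of pyramidal dendrites
#' — together with the inward peak (maximum of the negated signed
#' component; inward-directed fields depolarize the soma).
#'
#' @inheritParams peak_magnitude
#' @param normals unit outward normals on the field's node set.
#' @param mask optional `threshold_mask` computed on the absolute
#'   normal-component envelope.
#' @return named numeric vector `c(absolute = ..., inward = ...)`, V/m.
#' @export
peak_normal_component <- function(field, normals, mask = NULL,
                                  region = NULL) {
  s <- normal_series(field, normals)
  if (is.null(region)) region <- seq_len(nrow(s))
  if (!is.null(mask)) {
    s[mask$zeroed, ] <- 0
    region <- setdiff(region, which(mask$excluded))
  }
  if (length(region) == 0L) stop("region empty after masking")
  sr <- s[region, , drop = FALSE]
  c(absolute = max(abs(sr)), inward = max(-sr))
}

#' Relative difference measure between two normal-component series
#'
#' Quantifies spatial *redistribution* of the field between the zero-lag
#' condition and a lagged condition. In `timewise` mode, for each
#' non-degenerate time step the element-wise absolute normal components are
#' Euclidean-normalized and the norm of their difference is taken, then
#' averaged over retained steps:
#' \deqn{RDM(t) = \| \,|E_{n0}(t)| / \|E_{n0}(t)\| -
#'                   |E_{n\phi}(t)| / \|E_{n\phi}(t)\|\, \|}
#' In `envelope` mode the same formula is applied once to the per-node time
#' envelopes of the absolute normal component, which compares where the
#' field *can* reach over a cycle rather than its instant-by-instant
#' pattern. 0 means identical spatial distributions; with the element-wise
#' absolute values the attainable maximum (fully disjoint supports) is
#' `sqrt(2)`.
#'
#' @param series_zero,series_phi numeric matrices (nodes x time steps) of
#'   signed normal components on the same node subset and time grid.
#' @param mode `"timewise"` (default) or `"envelope"`.
#' @param tol degenerate-step guard: steps where either series' norm falls
#'   below `tol` times that series' maximum step norm are dropped.
#' @return scalar in `[0, sqrt(2)]`.
#' @export
rdm <- function(series_zero, series_phi, mode = c("timewise", "envelope"),
                tol = 1e-8) {
  mode <- match.arg(mode)
  a <- abs(as.matrix(series_zero))
  b <- abs(as.matrix(series_phi))
  if (!identical(dim(a), dim(b))) {
    stop("series must share node subset and time grid")
  }
  if (mode == "envelope") {
    ea <- do.call(pmax, lapply(seq_len(ncol(a)), function(k) a[, k]))
    eb <- do.call(pmax, lapply(seq_len(ncol(b)), function(k) b[, k]))
    na <- sqrt(sum(ea^2)); nb <- sqrt(sum(eb^2))
    if (na == 0 || nb == 0) stop("zero envelope norm")
    return(sqrt(sum((ea / na - eb / nb)^2)))
  }
  n0 <- .col_norms(a)
  nphi <- .col_norms(b)
  keep <- .retained_steps(n0, nphi, tol)
  if (length(keep) == 0L) stop("all time steps degenerate")
  vals <- vapply(keep, function(k) {
    sqrt(sum((a[, k] / n0[k] - b[, k] / nphi[k])^2))
  }, numeric(1))
  mean(vals)
}

#' Normal-component dot product between two conditions
#'
#' Per-time-step cosine similarity of the *signed* normal-component vectors
#' of the zero-lag and lagged conditions, averaged over non-degenerate
#' steps. 1 means the fields point the same way at every analysed node,
#' -1 that they are globally opposed.
#'
#' @inheritParams rdm
#' @return scalar in `[-1, 1]`.
#' @export
dotp <- function(series_zero, series_phi, tol = 1e-8) {
  a <- as.matrix(series_zero)
  b <- as.matrix(series_phi)
  if (!identical(dim(a), dim(b))) {
    stop("series must share node subset and time grid")
  }
  n0 <- .col_norms(a)
  nphi <- .col_norms(b)
  keep <- .retained_steps(n0, nphi, tol)
  if (length(keep) == 0L) stop("all time steps degenerate")
  vals <- vapply(keep, function(k) {
    sum(a[, k] * b[, k]) / (n0[k] * nphi[k])
  }, numeric(1))
  mean(pmin(1, pmax(-1, vals)))
}

#' Ideal dot product for perfectly separated fields
#'
#' The dot product that two spatially disjoint stimulation sites would
#' produce at a given phase lag, computed by brute force: two single-node
#' "sites" carry the lag-fixed and lag-shifted power (`p1`, `p2`), the
#' time-resolved fields at lag 0 and at `phase_lag` are built by
#' [superpose()], and [dotp()] is evaluated on them. This is the reference
#' against which the observed dot product is compared (see
#' [delta_dotp()]).
#'
#' @param p1 summed squared field of the lag-fixed site (er1 - ec1).
#' @param p2 summed squared field of the lag-shifted site (er2).
#' @param phase_lag phase lag in radians.
#' @param f frequency in Hz used to evaluate the sinusoids.
#' @param times time grid; default the standard 24-step half-offset cycle.
#' @return scalar in `[-1, 1]`.
#' @examples
#' ideal_dotp(1, 1, pi)   # 0: balanced sites in antiphase
#' @export
ideal_dotp <- function(p1, p2, phase_lag, f = 20,
                       times = make_time_grid(24, f)) {
  if (p1 < 0 || p2 < 0) stop("powers must be non-negative")
  if (p1 + p2 == 0) stop("zero total power")
  er1 <- rbind(c(sqrt(p1), 0, 0), c(0, 0, 0))
  er2 <- rbind(c(0, 0, 0), c(sqrt(p2), 0, 0))
  zero <- matrix(0, 2, 3)
  bs <- basis_fields(er1, zero, er2, io = 1, f = f)
  normals <- rbind(c(1, 0, 0), c(1, 0, 0))
  s0 <- normal_series(superpose(bs, 0, times), normals)
  sphi <- normal_series(superpose(bs, phase_lag, times), normals)
  dotp(s0, sphi)
}

#' Deviation of the observed dot product from the ideal
#'
#' The absolute difference between the dot product ideal separated fields
#' would give and the one actually obtained; 0 means the montage behaves
#' like two independent sites.
#'
#' @param observed,ideal dot-product values in `[-1, 1]`.
#' @return scalar `>= 0`.
#' @export
delta_dotp <- function(observed, ideal) {
  if (abs(observed) > 1 + 1e-12 || abs(ideal) > 1 + 1e-12) {
    stop("dot products must lie in [-1, 1]")
  }
  abs(ideal - observed)
}

#' Effective area of stimulation
#'
#' The area of a target region where the absolute normal component reaches
#' at least `frac` (default 50%) of the per-time-step peak over the whole
#' reference sheet (surrounding grey matter including both targets),
#' averaged over all time steps. A focality measure in mm^2.
#'
#' @param series numeric matrix (nodes x time steps) of signed normal
#'   components over the *reference* node set.
#' @param target logical or integer index into the rows of `series`
#'   selecting the target region (a subset of the reference set).
#' @param node_areas per-row areas in mm^2.
#' @param frac peak fraction defining "effective" (default 0.5).
#' @return scalar area, mm^2.
#' @export
effective_area <- function(series, target, node_areas, frac = 0.5) {
  series <- abs(as.matrix(series))
  if (nrow(series) == 0L) stop("empty reference set")
  if (length(node_areas) != nrow(series)) stop("area/node count mismatch")
  if (is.logical(target)) target <- which(target)
  if (length(target) && (min(target) < 1L || max(target) > nrow(series))) {
    stop("`target` must index rows of `series`")
  }
  per_step <- vapply(seq_len(ncol(series)), function(k) {
    peak <- max(series[, k])
    sum(node_areas[target][series[target, k] >= frac * peak])
  }, numeric(1))
  mean(per_step)
}
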
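#' Basis field set for dual-site stimulation
#'
#' The time-resolved ds-tACS field for any phase lag is a sinusoidally
#' weighted sum of three static basis fields, each obtained from a
#' single-channel (tDCS-like) solve against a common return electrode:
#' `er1` (return vs. surround electrodes of site 1), `ec1` (return vs.
#' central electrode of site 1) and `er2` (return vs. surround electrodes
#' of site 2). Basis fields are stored per unit channel current, so any
#' central-vs-surround current ratio of the montage is already baked in.
#'
#' @param er1,ec1,er2 numeric matrices, one 3-vector per node (V/m per mA).
#' @param io current amplitude in mA. The default 2 mA corresponds to a
#'   4 mA maximum peak-to-peak current.
#' @param f stimulation frequency in Hz (default 20).
#' @param montage_id,individual_id identifying strings carried into all
#'   downstream metric tables.
#' @return An object of class `basis_fields`.
#' @export
basis_fields <- function(er1, ec1, er2, io = 2, f = 20,
                         montage_id = "montage", individual_id = "ind") {
  er1 <- unname(as.matrix(er1))
  ec1 <- unname(as.matrix(ec1))
  er2 <- unname(as.matrix(er2))
  n <- nrow(er1)
  if (nrow(ec1) != n || nrow(er2) != n) {
    stop("er1, ec1 and er2 must share one node set")
  }
  if (ncol(er1) != 3L || ncol(ec1) != 3L || ncol(er2) != 3L) {
    stop("basis fields must be N x 3 matrices")
  }
  if (!is.finite(io) || io <= 0) stop("`io` must be > 0")
  if (!is.finite(f) || f <= 0) stop("`f` must be > 0")
  structure(
    list(er1 = er1, ec1 = ec1, er2 = er2, io = io, f = f,
         montage_id = as.character(montage_id),
         individual_id = as.character(individual_id)),
    class = "basis_fields"
  )
}

#' @export
print.basis_fields <- function(x, ...) {
  cat("<basis_fields> ", nrow(x$er1), " nodes | Io = ", x$io,
      " mA, f = ", x$f, " Hz | individual ", x$individual_id,
      ", montage ", x$montage_id, "\n", sep = "")
  invisible(x)
}

#' Default phase-lag grid
#'
#' Eight phase lags from 0 to 7/4 pi in pi/4 steps, equally sampling one
#' stimulation cycle.
#'
#' @return numeric vector of 8 angles in radians.
#' @export
default_phase_lags <- function() seq(0, 7, by = 1) * pi / 4

#' Time grid over one stimulation cycle
#'
#' `n_steps` equally spaced times spanning one period `1/f`, offset by half
#' a step: `t_k = (k + 1/2) / (n_steps * f)` for `k = 0 .. n_steps - 1`.
#' The half-step offset keeps `sin(2 pi f t)` away from exact zeros on the
#' default grid, so normalized comparison metrics are defined at every step
#' of the zero-lag condition.
#'
#' @param n_steps number of time steps (default 24).
#' @param f frequency in Hz.
#' @return numeric vector of times in seconds.
#' @examples
#' make_time_grid(4, 1)   # 0.125 0.375 0.625 0.875
#' @export
make_time_grid <- function(n_steps = 24, f = 20) {
  if (!is.finite(n_steps) || n_steps < 2) stop("`n_steps` must be >= 2")
  if (!is.finite(f) || f <= 0) stop("`f` must be > 0")
  (seq_len(n_steps) - 0.5) / (n_steps * f)
}

#' Superpose basis fields into the time-resolved ds-tACS field
#'
#' For phase lag `phi` and times `t`, the field at node `p` is
#' \deqn{E(p,t) = I_o [ (E_{R1}(p) - E_{C1}(p)) \sin(2\pi f t)
#'                     + E_{R2}(p) \sin(2\pi f t + \phi) ]}
#' i.e. the phase lag is applied to the second site's basis field only.
#'
#' @param basis a `basis_fields` object.
#' @param phase_lag phase lag in radians, in `[0, 2 pi)`.
#' @param times time points in seconds; default [make_time_grid()] with the
#'   basis set's frequency.
#' @return An object of class `tacs_field`: list with `vectors` (an
#'   N x 3 x T array, V/m), `times`, `phase_lag`, `montage_id`,
#'   `individual_id`, `f`, `io`.
#' @export
superpose <- function(basis, phase_lag,
                      times = make_time_grid(24, basis$f)) {
  stopifnot(inherits(basis, "basis_fields"))
  if (!is.finite(phase_lag)) stop("`phase_lag` must be finite")
  n <- nrow(basis$er1)
  tt <- length(times)
  s1 <- sin(2 * pi * basis$f * times)
  s2 <- sin(2 * pi * basis$f * times + phase_lag)
  fixed <- basis$er1 - basis$ec1
  vectors <- array(0, dim = c(n, 3L, tt))
  for (k in seq_len(tt)) {
    vectors[, , k] <- basis$io * (fixed * s1[k] + basis$er2 * s2[k])
  }
  if (!all(is.finite(vectors))) stop("non-finite field values produced")
  structure(
    list(vectors = vectors, times = times, phase_lag = phase_lag,
         montage_id = basis$montage_id, individual_id = basis$individual_id,
         f = basis$f, io = basis$io),
    class = "tacs_field"
  )
}

#' @export
print.tacs_field <- function(x, ...) {
  cat("<tacs_field> ", dim(x$vectors)[1L], " nodes x ", dim(x$vectors)[3L],
      " time steps | phase lag ", format(x$phase_lag / pi, digits = 3),
      " pi\n", sep = "")
  invisible(x)
}

#' Per-node field magnitudes at every time step
#'
#' @param field a `tacs_field`.
#' @return numeric matrix, nodes x time steps, of Euclidean norms (V/m).
#' @export
field_magnitudes <- function(field) {
  v <- field$vectors
  d <- dim(v)
  m <- sqrt(v[, 1L, , drop = FALSE]^2 + v[, 2L, , drop = FALSE]^2 +
              v[, 3L, , drop = FALSE]^2)
  matrix(m, nrow = d[1L], ncol = d[3L])
}

#' Signed normal-component series of a time-resolved field
#'
#' @param field a `tacs_field`.
#' @param normals unit outward normals on the field's node set.
#' @return numeric matrix, nodes x time steps, of signed normal components.
#' @export
normal_series <- function(field, normals) {
  v <- field$vectors
  d <- dim(v)
  if (d[1L] != nrow(normals)) stop("node count mismatch")
  s <- v[, 1L, , drop = FALSE] * normals[, 1L] +
    v[, 2L, , drop = FALSE] * normals[, 2L] +
    v[, 3L, , drop = FALSE] * normals[, 3L]
  matrix(s, nrow = d[1L], ncol = d[3L])
}

#' Field envelope: per-node maximum magnitude over one cycle
#'
#' @param field a `tacs_field` (at least one time step).
#' @return numeric vector, one value per node (V/m).
#' @export
envelope <- function(field) {
  m <- field_magnitudes(field)
  do.call(pmax, lapply(seq_len(ncol(m)), function(k) m[, k]))
}
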
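#' Compute all E-field metrics for one individual and montage
#'
#' Runs the full per-condition pipeline: superpose the basis fields at
#' every phase lag over one stimulation cycle, build per-condition
#' threshold masks (on the time envelope of the magnitude and of the
#' absolute normal component, one mask per family), and compute the six
#' metric families:
#'
#' * `peak_magnitude` (V/m) and `peak_normal` (V/m) over the target
#'   (`"M1s"`) and `"surrounding"` sheets — maxima over kept nodes and all
#'   time steps;
#' * `rdm`, `dotp`, `delta_dotp` (dimensionless) comparing each lag with
#'   the zero-lag condition on the nodes kept by both conditions' masks;
#' * `effective_area` (mm^2) for `"M1_left"` and `"M1_right"` separately,
#'   referenced to the peak over the surrounding sheet including both
#'   targets.
#'
#' For `delta_dotp` the ideal separated-field dot product is evaluated with
#' the post-threshold normal-component powers of the two sites
#' (`P1 = sum ncomp(er1 - ec1)^2`, `P2 = sum ncomp(er2)^2` over the
#' comparison node set), so a montage whose sites genuinely do not overlap
#' scores exactly 0.
#'
#' @param sheet a `cortical_sheet` with region sets `"M1_left"`,
#'   `"M1_right"` and `"surrounding"`.
#' @param basis a `basis_fields` object on the sheet's node set.
#' @param phase_lags phase lags in radians (default the 8 standard lags
#'   `k * pi / 4`).
#' @param n_steps time steps per cycle (default 24).
#' @param rdm_mode `"timewise"` (literal per-step formula) or
#'   `"envelope"` (cycle-envelope comparison).
#' @param pct,floor_frac threshold parameters, see [threshold_mask()].
#' @param area_frac peak fraction for [effective_area()] (default 0.5).
#' @return A tibble of class `tacs_metrics`, one row per (phase lag,
#'   region set, metric): columns `individual_id`, `montage_id`,
#'   `phase_lag`, `region_set`, `metric`, `value`, `units`.
#' @export
compute_metrics <- function(sheet, basis,
                            phase_lags = default_phase_lags(),
                            n_steps = 24, rdm_mode = "timewise",
                            pct = 99.9, floor_frac = 0.02,
                            area_frac = 0.5) {
  stopifnot(inherits(sheet, "cortical_sheet"),
            inherits(basis, "basis_fields"))
  if (nrow(basis$er1) != nrow(sheet$nodes)) {
    stop("basis fields and sheet disagree on node count")
  }
  if (!rdm_mode %in% c("timewise", "envelope")) {
    stop("unknown rdm_mode: '", rdm_mode,
         "' (use \"timewise\" or \"envelope\")")
  }
  needed <- c("M1_left", "M1_right", "surrounding")
  miss <- setdiff(needed, names(sheet$region_sets))
  if (length(miss)) stop("sheet lacks region set(s): ",
                         paste(miss, collapse = ", "))
  times <- make_time_grid(n_steps, basis$f)

  m1l <- region_nodes(sheet, "M1_left")
  m1r <- region_nodes(sheet, "M1_right")
  m1s <- union(m1l, m1r)
  surr <- region_nodes(sheet, "surrounding")
  ref <- union(m1s, surr)
  regions <- list(M1s = m1s, surrounding = surr)

  # one condition per lag: normal series, magnitudes, per-family masks
  lags <- unique(c(0, phase_lags))
  cond <- lapply(lags, function(phi) {
    fld <- superpose(basis, phi, times)
    mag <- field_magnitudes(fld)
    ns <- normal_series(fld, sheet$normals)
    env_mag <- do.call(pmax, lapply(seq_len(ncol(mag)), function(k) mag[, k]))
    env_nrm <- do.call(pmax, lapply(seq_len(ncol(ns)),
                                    function(k) abs(ns[, k])))
    list(phi = phi, mag = mag, ns = ns,
         mask_mag = threshold_mask(env_mag, pct, floor_frac),
         mask_nrm = threshold_mask(env_nrm, pct, floor_frac))
  })
  zero <- cond[[match(0, lags)]]

  # site normal components for the ideal-DotP power ratio
  site1_nc <- normal_component(basis$er1 - basis$ec1, sheet$normals)
  site2_nc <- normal_component(basis$er2, sheet$normals)

  rows <- purrr::map_dfr(phase_lags, function(phi) {
    cc <- cond[[match(phi, lags)]]
    out <- list()
    for (rs in names(regions)) {
      rn <- regions[[rs]]
      # peaks on this condition's own masks
      mag <- cc$mag
      mag[cc$mask_mag$zeroed, ] <- 0
      keep_m <- setdiff(rn, which(cc$mask_mag$excluded))
      if (!length(keep_m)) stop("region ", rs, " empty after masking")
      pk_mag <- max(mag[keep_m, , drop = FALSE])

      ns <- cc$ns
      ns[cc$mask_nrm$zeroed, ] <- 0
      keep_n <- setdiff(rn, which(cc$mask_nrm$excluded))
      if (!length(keep_n)) stop("region ", rs, " empty after masking")
      pk_nrm <- max(abs(ns[keep_n, , drop = FALSE]))

      # zero-lag comparison on nodes kept by both conditions
      ns0 <- zero$ns
      ns0[zero$mask_nrm$zeroed, ] <- 0
      sub <- intersect(
        setdiff(rn, which(zero$mask_nrm$excluded)),
        setdiff(rn, which(cc$mask_nrm$excluded))
      )
      s0 <- ns0[sub, , drop = FALSE]
      sp <- ns[sub, , drop = FALSE]
      r <- rdm(s0, sp, mode = rdm_mode)
      d <- dotp(s0, sp)
      both_zeroed <- zero$mask_nrm$zeroed | cc$mask_nrm$zeroed
      z1 <- site1_nc[sub]; z2 <- site2_nc[sub]
      z1[both_zeroed[sub]] <- 0
      z2[both_zeroed[sub]] <- 0
      idl <- ideal_dotp(sum(z1^2), sum(z2^2), phi, f = basis$f,
                        times = times)
      dd <- delta_dotp(d, idl)

      out[[rs]] <- tibble::tibble(
        phase_lag = phi,
        region_set = rs,
        metric = c("peak_magnitude", "peak_normal", "rdm", "dotp",
                   "delta_dotp"),
        value = c(pk_mag, pk_nrm, r, d, dd),
        units = c("V/m", "V/m", "", "", "")
      )
    }
    # effective area per target, referenced to the pooled sheet
    ns <- cc$ns
    ns[cc$mask_nrm$zeroed, ] <- 0
    ref_keep <- setdiff(ref, which(cc$mask_nrm$excluded))
    ea <- vapply(list(M1_left = m1l, M1_right = m1r), function(tn) {
      effective_area(ns[ref_keep, , drop = FALSE],
                     match(intersect(tn, ref_keep), ref_keep),
                     sheet$areas[ref_keep], frac = area_frac)
    }, numeric(1))
    out$area <- tibble::tibble(
      phase_lag = phi,
      region_set = c("M1_left", "M1_right"),
      metric = "effective_area",
      value = as.numeric(ea),
      units = "mm^2"
    )
    dplyr::bind_rows(out)
  })
  res <- dplyr::mutate(rows,
                       individual_id = basis$individual_id,
                       montage_id = basis$montage_id,
                       .before = 1L)
  class(res) <- c("tacs_metrics", class(res))
  res
}

#' Compute metrics for a whole cohort
#'
#' Maps [compute_metrics()] over every individual and candidate montage of
#' a synthetic (or file-loaded) cohort and binds the long tables.
#'
#' @param cohort a list of individuals as produced by [make_cohort()]:
#'   each element has `sheet` and a named list `basis` of `basis_fields`.
#' @param ... passed on to [compute_metrics()].
#' @return A `tacs_metrics` tibble over all individuals and montages.
#' @export
cohort_metrics <- function(cohort, ...) {
  res <- purrr::map_dfr(cohort, function(ind) {
    purrr::map_dfr(ind$basis, function(bs) {
      compute_metrics(ind$sheet, bs, ...)
    })
  })
  class(res) <- c("tacs_metrics", class(res))
  res
}
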
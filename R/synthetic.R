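.normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Icosphere triangulation
#'
#' Subdivided icosahedron projected onto a sphere, with outward-consistent
#' winding. The standard closed test surface for field metrics.
#'
#' @param subdivisions number of 4-fold subdivision passes (>= 0).
#' @param radius sphere radius in mm.
#' @return list with `nodes` (N x 3) and `triangles` (M x 3, 1-based).
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- .normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    ukey <- unique(key)
    eidx <- match(key, ukey)
    ue <- edges[match(ukey, key), , drop = FALSE]
    mid <- .normalize_rows((v[ue[, 1], , drop = FALSE] +
                              v[ue[, 2], , drop = FALSE]) / 2)
    midx <- nrow(v) + seq_len(nrow(mid))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- midx[eidx[seq_len(nf)]]
    m23 <- midx[eidx[nf + seq_len(nf)]]
    m31 <- midx[eidx[2 * nf + seq_len(nf)]]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  dimnames(v) <- NULL
  list(nodes = v * radius, triangles = f)
}

#' Synthetic montage specification
#'
#' Describes a two-site high-definition montage on a spherical cortical
#' sheet: the two site centres (roughly the two M1 hand knobs), the
#' angular spread of the central-electrode lobe, the surround geometry
#' (3x1 / 4x1 arrays or a continuous ring at a given angular radius), how
#' strongly the two sites' fields overlap, the site-2/site-1 power ratio,
#' and whether fields are `"overlapping"` (realistic) or `"separated"`
#' (supports truncated to disjoint caps — the ideal two-site limit used by
#' the spherical benchmark).
#'
#' @param site_centres 2 x 3 matrix of unit direction vectors (site 1 =
#'   right target, site 2 = left target).
#' @param central_spread angular sigma of the central lobe, radians.
#' @param surround_type `"3x1"`, `"4x1"` or `"ring"`.
#' @param surround_angle angular radius of the surround array, radians.
#' @param overlap in `[0, 0.95]`: the diffuse fraction of every lobe.
#'   Each lobe is a focal Gaussian plus a 3x-wider diffuse Gaussian
#'   weighted by `overlap`, so the two sites' fields coexist on
#'   intermediate nodes (0 = tight lobes, essentially no overlap).
#' @param amplitude_ratio site-2 / site-1 total field power ratio.
#' @param mode `"overlapping"` or `"separated"`.
#' @param tangential_frac relative strength of the tangential (lobe
#'   gradient) field component.
#' @param target_radius angular radius of the M1 label caps, radians.
#' @param surround_extent angular radius around either site within which
#'   unlabelled nodes become "surrounding" grey matter.
#' @param site_amps length-2 per-site amplitude multipliers (used by the
#'   cohort generator for inter-individual variation).
#' @return list of class `montage_spec`.
#' @export
synthetic_montage_spec <- function(
    site_centres = rbind(c(0.55, 0.15, 0.82), c(-0.55, 0.15, 0.82)),
    central_spread = 0.12, surround_type = "4x1", surround_angle = 0.25,
    overlap = 0.3, amplitude_ratio = 1,
    mode = c("overlapping", "separated"),
    tangential_frac = 0.3, target_radius = 0.15, surround_extent = 0.7,
    site_amps = c(1, 1)) {
  mode <- match.arg(mode)
  if (!surround_type %in% c("3x1", "4x1", "ring")) {
    stop("unknown surround_type: ", surround_type)
  }
  if (overlap < 0) stop("`overlap` must be >= 0")
  if (amplitude_ratio <= 0) stop("`amplitude_ratio` must be > 0")
  site_centres <- .normalize_rows(as.matrix(site_centres))
  structure(
    list(site_centres = site_centres, central_spread = central_spread,
         surround_type = surround_type, surround_angle = surround_angle,
         overlap = overlap, amplitude_ratio = amplitude_ratio,
         mode = mode, tangential_frac = tangential_frac,
         target_radius = target_radius, surround_extent = surround_extent,
         site_amps = site_amps),
    class = "montage_spec"
  )
}

#' Spherical cortical sheet with target and surround labels
#'
#' Builds an icosphere and labels two circular caps around the site
#' centres as `M1_left` / `M1_right` (labels 2 and 1) and an annular band
#' around both sites as `surrounding` (label 3); remaining nodes stay
#' unlabelled.
#'
#' @param radius sphere radius in mm (default 80, head-sized).
#' @param subdivisions icosphere subdivision passes (default 3, 642 nodes).
#' @param spec a `montage_spec`.
#' @return a `cortical_sheet`.
#' @export
make_sphere_sheet <- function(radius = 80, subdivisions = 3,
                              spec = synthetic_montage_spec()) {
  if (subdivisions < 2) stop("`subdivisions` must be >= 2")
  sep <- acos(pmin(1, pmax(-1,
                           sum(spec$site_centres[1, ] * spec$site_centres[2, ]))))
  if (sep < 2 * spec$target_radius) {
    stop("site centres too close: target caps would overlap")
  }
  ico <- icosphere(subdivisions, radius)
  u <- .normalize_rows(ico$nodes)
  ang1 <- acos(pmin(1, pmax(-1, as.numeric(u %*% spec$site_centres[1, ]))))
  ang2 <- acos(pmin(1, pmax(-1, as.numeric(u %*% spec$site_centres[2, ]))))
  labels <- integer(nrow(u))
  labels[ang1 < spec$target_radius] <- 1L   # right target (site 1)
  labels[ang2 < spec$target_radius] <- 2L   # left target (site 2)
  labels[labels == 0L &
           (ang1 < spec$surround_extent | ang2 < spec$surround_extent)] <- 3L
  cortical_sheet(ico$nodes, ico$triangles, labels,
                 region_sets = list(M1_right = 1L, M1_left = 2L,
                                    surrounding = 3L))
}

# azimuthal frame on the sphere around a centre direction
.tangent_frame <- function(centre) {
  ref <- if (abs(centre[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * centre) * centre
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(centre[2] * t1[3] - centre[3] * t1[2],
          centre[3] * t1[1] - centre[1] * t1[3],
          centre[1] * t1[2] - centre[2] * t1[1])
  rbind(t1, t2)
}

# Gaussian lobe field on the sphere: normal component `polarity * g`,
# plus a tangential component along the surface gradient of g
.lobe_field <- function(u, normals, centre, sigma, polarity,
                        tangential_frac) {
  ct <- pmin(1, pmax(-1, as.numeric(u %*% centre)))
  theta <- acos(ct)
  g <- exp(-theta^2 / (2 * sigma^2))
  nf <- normals * (polarity * g)
  # unit tangent at each node pointing towards the lobe centre
  tw <- matrix(centre, nrow(u), 3, byrow = TRUE) - u * ct
  tl <- sqrt(rowSums(tw^2))
  tw <- tw / pmax(tl, 1e-12)
  tf <- tw * (tangential_frac * (theta / sigma) * g)
  nf + tf
}

# surround electrode directions for a site
.surround_centres <- function(centre, type, angle, azimuth0 = 0) {
  n <- switch(type, "3x1" = 3L, "4x1" = 4L, "ring" = 12L)
  fr <- .tangent_frame(centre)
  az <- azimuth0 + 2 * pi * (seq_len(n) - 1) / n
  ctr <- matrix(centre, n, 3, byrow = TRUE)
  pts <- cos(angle) * ctr +
    sin(angle) * (cos(az) %o% fr[1, ] + sin(az) %o% fr[2, ])
  .normalize_rows(pts)
}

#' Synthetic basis fields for a two-site montage
#'
#' Phenomenological stand-in for the three single-channel forward solves:
#' normal-dominant Gaussian lobes with opposite-polarity surrounds.
#' `ec1` is an inward-normal lobe under the site-1 central electrode;
#' `er1` is the set of outward-normal lobes under the site-1 surround
#' electrodes, rescaled so its area-weighted normal integral balances
#' `ec1`'s; `er2` is the composite central-plus-surround pattern of site
#' 2, scaled so its total power is `amplitude_ratio` times the power of
#' the site-1 drive (`er1 - ec1`). Tangential components follow the lobe
#' gradients. In `"separated"` mode each site's field is truncated to a
#' cap of less than half the inter-site separation, so the two supports
#' share no node. Fields are scaled so the site-1 drive peaks at
#' 0.1 V/m per mA of channel current.
#'
#' @param sheet a labelled `cortical_sheet` from [make_sphere_sheet()].
#' @param spec a `montage_spec`.
#' @param seed optional integer; when given, the surround arrays get a
#'   random common azimuthal rotation (electrode placement variability).
#' @param io,f,montage_id,individual_id passed to [basis_fields()].
#' @return a `basis_fields` object.
#' @export
make_basis_fields <- function(sheet, spec, seed = NULL, io = 2, f = 20,
                              montage_id = "montage",
                              individual_id = "ind") {
  stopifnot(inherits(spec, "montage_spec"))
  u <- .normalize_rows(sheet$nodes)
  nrm <- sheet$normals
  c1 <- spec$site_centres[1, ]
  c2 <- spec$site_centres[2, ]
  sig_c <- spec$central_spread
  sig_s <- sig_c * 1.3
  az0 <- if (is.null(seed)) 0 else
    .with_seed(seed, stats::runif(1, 0, 2 * pi))

  # real HD fields are a focal lobe riding on a diffuse component that
  # spreads far beyond the array; `overlap` is the diffuse fraction
  # (0 = tight lobes only), with the diffuse scale 3x the focal one
  beta <- min(spec$overlap, 0.95)
  lobe <- function(centre, sigma, polarity) {
    focal <- .lobe_field(u, nrm, centre, sigma, polarity,
                         spec$tangential_frac)
    if (beta == 0) return(focal)
    broad <- .lobe_field(u, nrm, centre, 3 * sigma, polarity,
                         spec$tangential_frac)
    (1 - beta) * focal + beta * broad
  }

  site_parts <- function(centre) {
    central <- lobe(centre, sig_c, -1)
    sc <- .surround_centres(centre, spec$surround_type,
                            spec$surround_angle, az0)
    surround <- Reduce(`+`, lapply(seq_len(nrow(sc)), function(j) {
      lobe(sc[j, ], sig_s, +1)
    })) / nrow(sc)
    # balance the surround so its area-weighted normal flux cancels the
    # central lobe's
    ic <- sum(sheet$areas * normal_component(central, nrm))
    is <- sum(sheet$areas * normal_component(surround, nrm))
    if (is != 0) surround <- surround * (-ic / is)
    list(central = central, surround = surround)
  }
  s1 <- site_parts(c1)
  s2 <- site_parts(c2)

  ec1 <- spec$site_amps[1] * s1$central
  er1 <- spec$site_amps[1] * s1$surround
  er2 <- spec$site_amps[2] * (s2$central + s2$surround)

  if (spec$mode == "separated") {
    sep <- acos(pmin(1, pmax(-1, sum(c1 * c2))))
    cap <- 0.48 * sep
    a1 <- acos(pmin(1, pmax(-1, as.numeric(u %*% c1))))
    a2 <- acos(pmin(1, pmax(-1, as.numeric(u %*% c2))))
    ec1[a1 >= cap, ] <- 0
    er1[a1 >= cap, ] <- 0
    er2[a2 >= cap, ] <- 0
  }

  drive1 <- er1 - ec1
  peak1 <- max(sqrt(rowSums(drive1^2)))
  if (peak1 == 0) stop("degenerate montage spec: site-1 drive vanishes")
  scale1 <- 0.1 / peak1
  ec1 <- ec1 * scale1
  er1 <- er1 * scale1
  p1 <- sum((er1 - ec1)^2)
  p2 <- sum(er2^2)
  if (p2 == 0) stop("degenerate montage spec: site-2 field vanishes")
  er2 <- er2 * sqrt(spec$amplitude_ratio * p1 / p2)

  basis_fields(er1, ec1, er2, io = io, f = f,
               montage_id = montage_id, individual_id = individual_id)
}

#' Default candidate montage family
#'
#' Nine montage variants spanning small-to-wide 3x1 and 4x1 arrays and
#' four ring diameters, the candidate set for montage individualization.
#'
#' @return tibble with `montage_id`, `surround_type`, `surround_angle`.
#' @export
default_montages <- function() {
  tibble::tibble(
    montage_id = c("3x1a", "3x1b", "3x1c", "4x1a", "4x1b",
                   "ring_a", "ring_b", "ring_c", "ring_d"),
    surround_type = c("3x1", "3x1", "3x1", "4x1", "4x1",
                      "ring", "ring", "ring", "ring"),
    surround_angle = c(0.18, 0.24, 0.30, 0.20, 0.26,
                       0.16, 0.20, 0.26, 0.32)
  )
}

#' Generate a synthetic cohort of individuals
#'
#' Emulates inter-individual variability of head anatomy and field
#' strength: each individual gets site centres jittered in the tangent
#' plane (sd `site_jitter_sd` radians), lognormal per-site amplitude
#' factors (sdlog `amp_sdlog`), a relabelled sheet around the jittered
#' targets, and one `basis_fields` per candidate montage. Identical
#' `(spec, montages, seed)` give a bit-identical cohort; the caller's RNG
#' state is untouched.
#'
#' @param spec base `montage_spec` (site geometry, overlap, mode ...).
#' @param n_individuals cohort size (default 18).
#' @param seed integer seed (default 1).
#' @param site_jitter_sd angular sd of per-individual site displacement,
#'   radians (default 0.04; 0 gives identical individuals).
#' @param amp_sdlog sdlog of the per-site lognormal amplitude factors
#'   (default 0.2).
#' @param montages candidate montage table, see [default_montages()].
#' @param radius,subdivisions sphere geometry, see [make_sphere_sheet()].
#' @param io,f stimulation parameters for every generated basis set.
#' @return list of individuals; each element is a list with
#'   `individual_id`, `sheet` and `basis` (named list of `basis_fields`,
#'   one per montage).
#' @export
make_cohort <- function(spec = synthetic_montage_spec(),
                        n_individuals = 18, seed = 1,
                        site_jitter_sd = 0.04, amp_sdlog = 0.2,
                        montages = default_montages(),
                        radius = 80, subdivisions = 3, io = 2, f = 20) {
  if (n_individuals < 1) stop("`n_individuals` must be >= 1")
  .with_seed(seed, {
    lapply(seq_len(n_individuals), function(i) {
      id <- sprintf("ind%02d", i)
      centres <- spec$site_centres
      for (s in 1:2) {
        fr <- .tangent_frame(centres[s, ])
        d <- stats::rnorm(2, 0, site_jitter_sd)
        centres[s, ] <- centres[s, ] + d[1] * fr[1, ] + d[2] * fr[2, ]
      }
      centres <- .normalize_rows(centres)
      amps <- stats::rlnorm(2, 0, amp_sdlog)
      # electrode-placement (azimuth) variability is part of the anatomical
      # jitter: a zero-jitter cohort is fully degenerate
      ind_seed <- sample.int(.Machine$integer.max, 1)
      if (site_jitter_sd == 0) ind_seed <- NULL
      ind_spec <- spec
      ind_spec$site_centres <- centres
      ind_spec$site_amps <- spec$site_amps * amps
      sheet <- make_sphere_sheet(radius, subdivisions, ind_spec)
      basis <- lapply(seq_len(nrow(montages)), function(m) {
        ms <- ind_spec
        ms$surround_type <- montages$surround_type[m]
        ms$surround_angle <- montages$surround_angle[m]
        make_basis_fields(sheet, ms, seed = ind_seed, io = io, f = f,
                          montage_id = montages$montage_id[m],
                          individual_id = id)
      })
      names(basis) <- montages$montage_id
      list(individual_id = id, sheet = sheet, basis = basis)
    })
  })
}
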
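# shared fixtures: built once per test run, all generated in code

# flat single-triangle patch
flat_patch <- function() {
  cortical_sheet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1L, 2L, 3L), nrow = 1))
}

# small labelled sphere sheet (162 nodes) for fast pipeline tests
small_sheet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_sphere_sheet(subdivisions = 2)
    cache
  }
})

# standard sheet at the default resolution (642 nodes)
std_sheet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_sphere_sheet()
    cache
  }
})

# random dense basis fields on a sheet (no spatial structure; for
# linearity / symmetry properties)
rand_basis <- function(sheet, seed, io = 2, f = 20) {
  n <- nrow(sheet$nodes)
  withr::with_seed(seed, {
    basis_fields(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3), n),
                 matrix(rnorm(n * 3), n), io = io, f = f)
  })
}

# long metric table built directly from a per-(individual, montage) value
# matrix, replicated over lags (for individualization unit tests)
records_from_matrix <- function(vals, metric = "delta_dotp",
                                lags = default_phase_lags()) {
  inds <- rownames(vals)
  mons <- colnames(vals)
  out <- expand.grid(individual_id = inds, montage_id = mons,
                     phase_lag = lags, stringsAsFactors = FALSE)
  out$region_set <- "M1s"
  out$metric <- metric
  out$value <- vals[cbind(out$individual_id, out$montage_id)]
  out$value[out$phase_lag == 0] <- 0
  out$units <- ""
  tibble::as_tibble(out)
}
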
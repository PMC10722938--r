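# Shared fixtures, built in code.

tiny_atlas <- function(n = 16L) generate_atlas(phantom_spec(grid_shape = rep(n, 3L)))

# Wrap a binary 3D mask as a single-compartment atlas (label = PAT).
mask_atlas <- function(mask3, spacing = c(1, 1, 1), label = "PAT") {
  labs <- array(0L, dim(mask3))
  labs[mask3] <- kneevbr:::COMPARTMENT_LABELS[[label]]
  structure(list(labels = labs,
                 label_names = kneevbr:::COMPARTMENT_LABELS,
                 spacing_mm = spacing),
            class = "compartment_atlas")
}

# Noiseless single-voxel-per-row echo series for V (S0, T) pairs.
decay_series <- function(S0, Tms, echo_times = c(0, 10, 40, 80)) {
  V <- length(S0)
  dat <- array(0, c(V, 1, 1, length(echo_times)))
  for (e in seq_along(echo_times)) dat[, 1, 1, e] <- S0 * exp(-echo_times[e] / Tms)
  echo_series(dat, echo_times)
}

# Build a cohort_stack directly from a subjects x voxels value matrix,
# bypassing the imaging stages (for statistics-only tests).
values_stack <- function(values, records, grid = NULL) {
  V <- ncol(values)
  if (is.null(grid)) grid <- c(V, 1L, 1L)
  maps <- lapply(seq_len(nrow(values)), function(i) {
    m <- kneevbr:::new_relaxation_map(grid, c(1, 1, 1), "T1rho", c(1, 200))
    vol <- array(NA_real_, grid)
    vol[seq_len(V)] <- values[i, ]
    m$time_ms <- vol
    msk <- array(FALSE, grid); msk[seq_len(V)] <- TRUE
    m$mask <- msk; m$converged <- msk
    m
  })
  build_cohort_stack(maps, records, covariates = character(0))
}

basic_records <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = rnorm(n, 19, 1), sex = sample(c("M", "F"), n, TRUE),
    bmi = rnorm(n, 24, 2), site = sample(paste0("site", 1:3), n, TRUE),
    grade_patellar_tendinosis = rep_len(c(0L, 1L), n),
    stringsAsFactors = FALSE))
}
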
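# Synthetic knee-phantom cohort generator.
#
# Everything downstream (fitting, registration, SPM statistics, thickness)
# is exercised on phantoms produced here: a labeled 6-compartment atlas in
# a common reference space, per-subject ground-truth T1rho/T2 fields with
# known injected group effects, multi-echo magnitude signals with Gaussian
# or Rician noise, and subject records (covariates, MRI abnormality grades,
# KOOS items/subscales) calibrated to the published cohort table.

#' Phantom specification
#'
#' Describes the reference grid and the parametric geometry of the six
#' cartilage compartments (LFC, LT, MFC, MT, TRO, PAT).
#'
#' @param grid_shape Voxels per axis (sagittal, coronal, axial).
#' @param spacing_mm Voxel spacing in mm per axis.
#' @param compartment_geometry Named list (one entry per compartment) of
#'   shapes; see [default_knee_geometry()]. Each entry is either a slab
#'   (`shape = "slab"`, `center` mm, `half_size` mm) or a cylindrical shell
#'   section with axis along the sagittal direction (`shape = "cyl_shell"`,
#'   `center` mm in (y, z), `x_range` mm, `r_inner`/`r_outer` mm, optional
#'   `theta_range` radians in the y-z plane).
#' @param seed Integer seed carried with the spec (geometry itself is
#'   deterministic; the seed feeds downstream generators).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         spacing_mm = c(1, 1, 1),
                         compartment_geometry = default_knee_geometry(grid_shape, spacing_mm),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, length(spacing_mm) == 3L,
            all(grid_shape >= 4L), all(spacing_mm > 0))
  missing_labels <- setdiff(compartment_names(), names(compartment_geometry))
  if (length(missing_labels)) {
    stopf("phantom_spec: missing compartment geometry for %s",
          paste(missing_labels, collapse = ", "))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.double(spacing_mm),
                 compartment_geometry = compartment_geometry,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default idealized compartment geometry
#'
#' Six disjoint slabs stacked along the axial direction, each spanning most
#' of the in-plane extent with a 4 mm thickness. This is an idealized
#' atlas-space stand-in, not a realistic knee mesh: downstream statistics
#' only require disjoint labeled regions of realistic voxel counts.
#'
#' @param grid_shape,spacing_mm As in [phantom_spec()].
#' @return Named list of slab geometries.
#' @export
default_knee_geometry <- function(grid_shape = c(32L, 32L, 32L),
                                  spacing_mm = c(1, 1, 1)) {
  ext <- (grid_shape - 1) * spacing_mm   # physical extent, mm
  nz <- grid_shape[3]
  # 6 axial bands with one-voxel gaps; thickness = max(4 voxels, 2 voxels)
  thick_vox <- max(2L, min(4L, floor((nz - 7L) / 6L)))
  starts <- round(seq(1, nz - thick_vox, length.out = 6))
  geom <- list()
  nm <- compartment_names()
  for (k in seq_along(nm)) {
    # slab covers voxel rows starts[k] .. starts[k] + thick_vox - 1
    z0 <- (starts[k] - 1) * spacing_mm[3]
    z1 <- (starts[k] + thick_vox - 2) * spacing_mm[3]
    geom[[nm[k]]] <- list(
      shape = "slab",
      center = c(ext[1] / 2, ext[2] / 2, (z0 + z1) / 2),
      half_size = c(ext[1] * 0.45, ext[2] * 0.45, (z1 - z0) / 2)
    )
  }
  geom
}

# Voxel-center coordinates (mm) for a grid; 1-based index i sits at (i-1)*d.
grid_coords <- function(grid_shape, spacing_mm) {
  list(x = (seq_len(grid_shape[1]) - 1) * spacing_mm[1],
       y = (seq_len(grid_shape[2]) - 1) * spacing_mm[2],
       z = (seq_len(grid_shape[3]) - 1) * spacing_mm[3])
}

rasterize_geometry <- function(geom, grid_shape, spacing_mm) {
  co <- grid_coords(grid_shape, spacing_mm)
  if (geom$shape == "slab") {
    inx <- abs(co$x - geom$center[1]) <= geom$half_size[1] + 1e-9
    iny <- abs(co$y - geom$center[2]) <= geom$half_size[2] + 1e-9
    inz <- abs(co$z - geom$center[3]) <= geom$half_size[3] + 1e-9
    return(outer(outer(inx, iny, "&"), inz, "&"))
  }
  if (geom$shape == "cyl_shell") {
    dy <- co$y - geom$center[1]
    dz <- co$z - geom$center[2]
    r <- sqrt(outer(dy^2, dz^2, "+"))
    ring <- r >= geom$r_inner - 1e-9 & r <= geom$r_outer + 1e-9
    if (!is.null(geom$theta_range)) {
      dyg <- matrix(dy, nrow = length(dy), ncol = length(dz))
      dzg <- matrix(dz, nrow = length(dy), ncol = length(dz), byrow = TRUE)
      th <- atan2(dzg, dyg)
      ring <- ring & th >= geom$theta_range[1] & th <= geom$theta_range[2]
    }
    inx <- co$x >= geom$x_range[1] - 1e-9 & co$x <= geom$x_range[2] + 1e-9
    mask <- array(FALSE, grid_shape)
    for (i in which(inx)) mask[i, , ] <- ring
    return(mask)
  }
  stopf("unknown geometry shape '%s'", geom$shape)
}

#' Generate the labeled compartment atlas
#'
#' Rasterizes each compartment's parametric geometry onto the reference
#' grid. Labels follow the fixed dictionary LFC=1, LT=2, MFC=3, MT=4,
#' TRO=5, PAT=6; background is 0.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `compartment_atlas`: list with `labels`
#'   (integer 3D array), `label_names`, `spacing_mm`.
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- array(0L, spec$grid_shape)
  masks <- lapply(spec$compartment_geometry[compartment_names()],
                  rasterize_geometry, grid_shape = spec$grid_shape,
                  spacing_mm = spec$spacing_mm)
  nm <- compartment_names()
  for (a in seq_along(nm)) {
    for (b in seq_along(nm)) {
      if (a < b && any(masks[[a]] & masks[[b]])) {
        stopf("generate_atlas: compartment shells overlap: %s and %s",
              nm[a], nm[b])
      }
    }
  }
  for (k in seq_along(nm)) {
    if (!any(masks[[k]])) stopf("generate_atlas: compartment %s is empty", nm[k])
    labels[masks[[k]]] <- COMPARTMENT_LABELS[[nm[k]]]
  }
  structure(list(labels = labels,
                 label_names = COMPARTMENT_LABELS,
                 spacing_mm = spec$spacing_mm),
            class = "compartment_atlas")
}

#' Default ground-truth compartment relaxation times
#'
#' Field-typical healthy articular-cartilage values at 3 T (ms).
#' @return data.frame with columns compartment, t1rho_ms, t2_ms.
#' @export
default_compartment_means <- function() {
  data.frame(
    compartment = compartment_names(),
    t1rho_ms = c(42, 40, 43, 40, 44, 45),
    t2_ms    = c(33, 30, 34, 30, 34, 35),
    stringsAsFactors = FALSE
  )
}

#' Injected group-effect specification
#'
#' Describes a localized relaxation-time difference between knees with and
#' without an MRI-graded abnormality, and an optional coupling of a KOOS
#' subscale to the resulting regional relaxation deviation.
#'
#' Sign convention matches the reported average percentage difference
#' (APD): `true_percentage_difference` = 100 x (reference mean - affected
#' mean) / reference mean, so a NEGATIVE value means HIGHER relaxation
#' times in knees with the abnormality.
#'
#' @param target_compartments Character subset of compartment names.
#' @param affected_fraction Fraction (0-1) of each target compartment's
#'   voxels carrying the shift (a contiguous sub-region).
#' @param group_variable Record column holding the driving grade, e.g.
#'   `"grade_patellar_tendinosis"`; knees with grade >= `grade_threshold`
#'   are "with abnormality".
#' @param true_percentage_difference Signed percent, see above.
#' @param between_subject_sd_pct Between-subject SD of compartment means,
#'   percent of the compartment mean (applies to all subjects).
#' @param outcome_subscale KOOS subscale coupled to the regional mean
#'   relaxation deviation (`"Symptoms"`, `"Pain"`, `"ADL"`, `"SportRec"`,
#'   `"QOL"`, or NA for no coupling).
#' @param outcome_slope KOOS points per ms of regional mean relaxation
#'   deviation (negative: higher relaxation, worse outcome).
#' @param outcome_noise_sd KOOS points; NULL means "auto": chosen so the
#'   marginal subscale SD still meets its calibration target.
#' @param modality Which truth field carries the shift: "both" (default),
#'   "T1rho" or "T2".
#' @param grade_threshold Minimum grade counting as "with abnormality".
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(target_compartments = "MT",
                        affected_fraction = 0.25,
                        group_variable = "grade_patellar_tendinosis",
                        true_percentage_difference = -10,
                        between_subject_sd_pct = 2,
                        outcome_subscale = NA_character_,
                        outcome_slope = 0,
                        outcome_noise_sd = NULL,
                        modality = "both",
                        grade_threshold = 1L) {
  unknown <- setdiff(target_compartments, compartment_names())
  if (length(unknown)) {
    stopf("effect_spec: unknown compartment label(s): %s",
          paste(unknown, collapse = ", "))
  }
  stopifnot(affected_fraction >= 0, affected_fraction <= 1,
            is.finite(true_percentage_difference),
            between_subject_sd_pct >= 0,
            modality %in% c("both", "T1rho", "T2"))
  structure(list(target_compartments = target_compartments,
                 affected_fraction = affected_fraction,
                 group_variable = group_variable,
                 true_percentage_difference = true_percentage_difference,
                 between_subject_sd_pct = between_subject_sd_pct,
                 outcome_subscale = outcome_subscale,
                 outcome_slope = outcome_slope,
                 outcome_noise_sd = outcome_noise_sd,
                 modality = modality,
                 grade_threshold = as.integer(grade_threshold)),
            class = "effect_spec")
}

# Deterministic contiguous affected sub-region: the first `fraction` of a
# compartment's voxels ordered along the coronal (y) axis, then z, then x.
affected_region_indices <- function(atlas, label_name, fraction) {
  idx <- which(atlas$labels == COMPARTMENT_LABELS[[label_name]])
  if (fraction <= 0 || !length(idx)) return(integer(0))
  co <- arrayInd(idx, dim(atlas$labels))
  ord <- order(co[, 2], co[, 3], co[, 1])
  n_aff <- ceiling(fraction * length(idx))
  idx[ord[seq_len(n_aff)]]
}

#' Generate a subject's ground-truth relaxation fields
#'
#' Each compartment takes its population mean times a subject-level
#' multiplicative offset (drawn at `between_subject_sd_pct`); if `effect`
#' names a grade the subject carries at or above threshold, voxels in the
#' affected sub-region are additionally shifted by
#' `-true_percentage_difference/100 x reference mean` (so a -10 percent
#' difference raises a 40 ms compartment to 44 ms in the affected region).
#'
#' @param atlas A `compartment_atlas`.
#' @param compartment_means data.frame as [default_compartment_means()].
#' @param effect An [effect_spec()] or NULL.
#' @param subject One-row data.frame / list with the grade column named by
#'   the effect (ignored when `effect` is NULL).
#' @param seed Integer seed for the subject-level offsets.
#' @param offsets_pct Optional 6 x 2 matrix (compartment x modality
#'   c("T1rho","T2")) of percent offsets, overriding the random draw (used
#'   by [generate_cohort()] to keep records and fields consistent).
#' @return Object of class `truth_field`: `t1rho_ms`, `t2_ms`, `s0` 3D
#'   arrays (0 outside cartilage), plus the offsets used.
#' @export
generate_truth <- function(atlas, compartment_means = default_compartment_means(),
                           effect = NULL, subject = NULL, seed = 1L,
                           offsets_pct = NULL, s0 = 100) {
  stopifnot(inherits(atlas, "compartment_atlas"))
  nm <- compartment_names()
  cm <- compartment_means[match(nm, compartment_means$compartment), ]
  if (anyNA(cm$t1rho_ms) || anyNA(cm$t2_ms) ||
      any(cm$t1rho_ms <= 0) || any(cm$t2_ms <= 0)) {
    stopf("generate_truth: compartment means must be positive for all 6 labels")
  }
  sd_pct <- if (is.null(effect)) 0 else effect$between_subject_sd_pct
  if (is.null(offsets_pct)) {
    offsets_pct <- with_seed(seed, matrix(stats::rnorm(12L, 0, sd_pct), 6L, 2L,
                                          dimnames = list(nm, c("T1rho", "T2"))))
  }
  shp <- dim(atlas$labels)
  t1 <- array(0, shp); t2 <- array(0, shp); s0v <- array(0, shp)
  for (k in seq_along(nm)) {
    idx <- which(atlas$labels == COMPARTMENT_LABELS[[nm[k]]])
    t1[idx] <- cm$t1rho_ms[k] * (1 + offsets_pct[k, "T1rho"] / 100)
    t2[idx] <- cm$t2_ms[k] * (1 + offsets_pct[k, "T2"] / 100)
    s0v[idx] <- s0
  }
  if (!is.null(effect)) {
    if (is.null(subject) || is.null(subject[[effect$group_variable]])) {
      stopf("generate_truth: subject lacks grade variable '%s'", effect$group_variable)
    }
    if (subject[[effect$group_variable]] >= effect$grade_threshold) {
      for (lab in effect$target_compartments) {
        k <- match(lab, nm)
        aff <- affected_region_indices(atlas, lab, effect$affected_fraction)
        shift_pct <- -effect$true_percentage_difference / 100
        if (effect$modality %in% c("both", "T1rho")) {
          t1[aff] <- t1[aff] + shift_pct * cm$t1rho_ms[k]
        }
        if (effect$modality %in% c("both", "T2")) {
          t2[aff] <- t2[aff] + shift_pct * cm$t2_ms[k]
        }
      }
    }
  }
  structure(list(t1rho_ms = t1, t2_ms = t2, s0 = s0v,
                 offsets_pct = offsets_pct,
                 spacing_mm = atlas$spacing_mm),
            class = "truth_field")
}

#' Default echo schedules (ms)
#'
#' Spin-lock times for T1rho and T2-preparation echo times for the
#' combined MAPSS acquisition.
#' @param modality `"T1rho"` or `"T2"`.
#' @return Numeric vector of echo times in ms.
#' @export
default_echo_times <- function(modality = c("T1rho", "T2")) {
  modality <- match.arg(modality)
  if (modality == "T1rho") c(0, 10, 40, 80) else c(0, 12.87, 25.69, 51.39)
}

#' Construct a multi-echo series object
#'
#' @param data 4D magnitude array (x, y, z, echo).
#' @param echo_times_ms Strictly increasing, >= 3 values.
#' @param modality `"T1rho"` or `"T2"`.
#' @param spacing_mm Spatial voxel spacing.
#' @param meta Free-form acquisition metadata list.
#' @return Object of class `echo_series`.
#' @export
echo_series <- function(data, echo_times_ms, modality = "T1rho",
                        spacing_mm = c(1, 1, 1), meta = list()) {
  if (length(dim(data)) != 4L) stopf("echo_series: data must be 4D")
  ne <- length(echo_times_ms)
  if (ne < 3L) stopf("echo_series: need >= 3 echoes, got %d (2-parameter fit plus quality is under-determined)", ne)
  if (dim(data)[4] != ne) stopf("echo_series: 4th dim (%d) != number of echo times (%d)", dim(data)[4], ne)
  if (any(echo_times_ms < 0) || any(diff(echo_times_ms) <= 0)) {
    stopf("echo_series: echo times must be non-negative and strictly increasing")
  }
  structure(list(data = data, echo_times_ms = as.double(echo_times_ms),
                 modality = modality, spacing_mm = as.double(spacing_mm),
                 meta = meta),
            class = "echo_series")
}

#' Simulate a multi-echo magnitude series from a truth field
#'
#' Per voxel v and echo time t: `S = S0(v) * exp(-t / T(v)) + noise`.
#' Background voxels (T = 0) contain noise only. Rician noise takes the
#' magnitude of a complex Gaussian perturbation of the noiseless signal.
#'
#' @param truth A `truth_field`.
#' @param modality `"T1rho"` or `"T2"` (selects the truth field).
#' @param echo_times_ms Defaults to the modality's acquisition schedule.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param noise_sd Noise SD in amplitude units (default 2, i.e. SNR 50 at
#'   the default S0 = 100).
#' @param seed Integer seed.
#' @return An [echo_series()].
#' @export
simulate_echo_series <- function(truth, modality = c("T1rho", "T2"),
                                 echo_times_ms = NULL,
                                 noise_model = c("gaussian", "rician"),
                                 noise_sd = 2, seed = 1L) {
  modality <- match.arg(modality)
  noise_model <- match.arg(noise_model)
  if (is.null(echo_times_ms)) echo_times_ms <- default_echo_times(modality)
  if (length(echo_times_ms) < 3L) {
    stopf("simulate_echo_series: need >= 3 echoes for a determined fit")
  }
  tmap <- if (modality == "T1rho") truth$t1rho_ms else truth$t2_ms
  shp <- dim(tmap)
  ne <- length(echo_times_ms)
  data <- array(0, c(shp, ne))
  inside <- tmap > 0
  for (e in seq_len(ne)) {
    sl <- array(0, shp)
    sl[inside] <- truth$s0[inside] * exp(-echo_times_ms[e] / tmap[inside])
    data[, , , e] <- sl
  }
  if (noise_sd > 0) {
    n_tot <- length(data)
    if (noise_model == "gaussian") {
      data <- data + with_seed(seed, array(stats::rnorm(n_tot, 0, noise_sd), dim(data)))
    } else {
      eps <- with_seed(seed, stats::rnorm(2 * n_tot, 0, noise_sd))
      data <- sqrt((data + eps[seq_len(n_tot)])^2 + eps[n_tot + seq_len(n_tot)]^2)
    }
  }
  echo_series(data, echo_times_ms, modality = modality,
              spacing_mm = truth$spacing_mm,
              meta = list(noise_model = noise_model, noise_sd = noise_sd,
                          spin_lock_hz = if (modality == "T1rho") 500 else NULL))
}
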
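# Cohort-level synthetic data: subject records (grades, covariates, KOOS)
# and, on top of them, per-knee truth fields and multi-echo volumes.

#' Default MRI-abnormality grade prevalences
#'
#' Exact count fractions from the published cohort of 75 knees:
#' bone marrow edema 62/11/2, patellar tendinosis 28/32/14/1,
#' quadriceps tendinosis 46/29.
#' @return Named list of probability vectors (grade 0 first).
#' @export
default_grade_prevalence <- function() {
  list(
    grade_bone_marrow_edema = c(62, 11, 2) / 75,
    grade_patellar_tendinosis = c(28, 32, 14, 1) / 75,
    grade_quadriceps_tendinosis = c(46, 29) / 75
  )
}

#' Default covariate model
#'
#' Age 18.69 +/- 0.84 y, BMI 23.78 +/- 2.56 kg/m2, 35/75 male, 3
#' acquisition sites (uniform).
#' @return Named list of covariate-model parameters.
#' @export
default_covariate_model <- function() {
  list(age_mean = 18.69, age_sd = 0.84,
       bmi_mean = 23.78, bmi_sd = 2.56,
       p_male = 35 / 75,
       n_sites = 3L)
}

#' Generate synthetic subject records (no volumes)
#'
#' Draws MRI abnormality grades at the configured prevalences, covariates
#' from the covariate model, per-subject compartment relaxation offsets,
#' and KOOS item responses whose scored subscales meet the published
#' mean/SD calibration targets. Effects with an `outcome_subscale` couple
#' that subscale to the subject's regional mean relaxation deviation of
#' the effect's target compartments (`latent = baseline + slope * dev +
#' noise`; a negative slope means higher relaxation, worse outcome). When
#' `outcome_noise_sd` is NULL the noise SD is set so the marginal subscale
#' SD still meets its calibration target.
#'
#' @param n_knees Number of knees (rows).
#' @param effects List of [effect_spec()]s (may be empty).
#' @param grade_prevalence Named list of probability vectors, each summing
#'   to 1 (grade 0 first).
#' @param covariate_model See [default_covariate_model()].
#' @param compartment_means See [default_compartment_means()].
#' @param between_subject_sd_pct Between-subject SD of compartment means
#'   (percent); defaults to the first effect's value, else 2.
#' @param seed Integer seed; identical arguments + seed reproduce the
#'   records bit-exactly.
#' @return data.frame with one row per knee: identifiers, covariates,
#'   grades, KOOS items (`koos_<subscale>_q<i>`) and scored subscales
#'   (`koos_symptoms`, ...). Attribute `offsets_pct` carries the
#'   n x 6 x 2 array of compartment offsets (percent) consumed by
#'   [generate_cohort()].
#' @export
generate_subjects <- function(n_knees,
                              effects = list(),
                              grade_prevalence = default_grade_prevalence(),
                              covariate_model = default_covariate_model(),
                              compartment_means = default_compartment_means(),
                              between_subject_sd_pct = NULL,
                              seed = 1L) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (nm in names(grade_prevalence)) {
    if (abs(sum(grade_prevalence[[nm]]) - 1) > 1e-8) {
      stopf("generate_subjects: prevalences for %s sum to %.6f, not 1",
            nm, sum(grade_prevalence[[nm]]))
    }
  }
  sd_pct <- between_subject_sd_pct %||%
    (if (length(effects)) effects[[1]]$between_subject_sd_pct else 2)
  cmn <- compartment_names()
  cm <- compartment_means[match(cmn, compartment_means$compartment), ]
  info <- koos_subscale_info()

  with_seed(seed, {
    rec <- data.frame(
      subject_id = sprintf("knee%04d", seq_len(n_knees)),
      player_id = sprintf("player%04d", ceiling(seq_len(n_knees) / 2)),
      knee_side = rep_len(c("left", "right"), n_knees),
      stringsAsFactors = FALSE
    )
    rec$age <- stats::rnorm(n_knees, covariate_model$age_mean, covariate_model$age_sd)
    rec$sex <- ifelse(stats::runif(n_knees) < covariate_model$p_male, "M", "F")
    rec$bmi <- stats::rnorm(n_knees, covariate_model$bmi_mean, covariate_model$bmi_sd)
    rec$site <- paste0("site", sample.int(covariate_model$n_sites, n_knees, replace = TRUE))
    for (nm in names(grade_prevalence)) {
      p <- grade_prevalence[[nm]]
      rec[[nm]] <- sample.int(length(p), n_knees, replace = TRUE, prob = p) - 1L
    }

    # Subject-level compartment offsets (percent), per modality.
    offsets <- array(stats::rnorm(n_knees * 6L * 2L, 0, sd_pct),
                     dim = c(n_knees, 6L, 2L),
                     dimnames = list(NULL, cmn, c("T1rho", "T2")))

    # Regional mean relaxation deviation (ms) per effect per subject:
    # offset contribution plus, for affected knees, the injected shift
    # diluted by the affected fraction of the compartment.
    dev_by_subscale <- stats::setNames(
      rep(list(rep(0, n_knees)), nrow(info)), info$subscale)
    slope_by_subscale <- stats::setNames(rep(0, nrow(info)), info$subscale)
    noise_override <- stats::setNames(rep(NA_real_, nrow(info)), info$subscale)
    for (ef in effects) {
      if (is.na(ef$outcome_subscale) || ef$outcome_slope == 0) next
      mod <- if (ef$modality == "T1rho") "T1rho" else "T2"
      mcol <- if (mod == "T1rho") cm$t1rho_ms else cm$t2_ms
      affected <- rec[[ef$group_variable]] >= ef$grade_threshold
      dev <- rep(0, n_knees)
      for (lab in ef$target_compartments) {
        k <- match(lab, cmn)
        dev <- dev + mcol[k] * offsets[, k, mod] / 100
        dev <- dev + affected * (-ef$true_percentage_difference / 100) *
          mcol[k] * ef$affected_fraction
      }
      dev <- dev / length(ef$target_compartments)
      s <- ef$outcome_subscale
      dev_by_subscale[[s]] <- dev_by_subscale[[s]] + dev
      slope_by_subscale[[s]] <- slope_by_subscale[[s]] + ef$outcome_slope
      if (!is.null(ef$outcome_noise_sd)) noise_override[[s]] <- ef$outcome_noise_sd
    }

    items_all <- NULL
    assign_all <- character(0)
    for (i in seq_len(nrow(info))) {
      s <- info$subscale[i]
      lat <- koos_latent_params(info$target_mean[i], info$target_sd[i], info$n_items[i])
      slope <- slope_by_subscale[[s]]
      dev <- dev_by_subscale[[s]]
      contrib <- slope * dev
      var_contrib <- if (length(contrib) > 1L) stats::var(contrib) else 0
      noise_sd <- if (!is.na(noise_override[[s]])) noise_override[[s]] else {
        sqrt(max(lat[["sigma"]]^2 - var_contrib, (0.2 * lat[["sigma"]])^2))
      }
      latent <- lat[["mu"]] + contrib + stats::rnorm(n_knees, 0, noise_sd)
      items <- koos_items_from_target(latent, info$n_items[i])
      colnames(items) <- sprintf("koos_%s_q%d", tolower(s), seq_len(info$n_items[i]))
      items_all <- cbind(items_all, items)
      assign_all <- c(assign_all, rep(s, info$n_items[i]))
    }
    scores <- score_koos(items_all, assign_all)
    for (j in seq_len(ncol(items_all))) rec[[colnames(items_all)[j]]] <- items_all[, j]
    for (s in colnames(scores)) rec[[paste0("koos_", tolower(s))]] <- scores[, s]
    attr(rec, "offsets_pct") <- offsets
    attr(rec, "item_subscale") <- assign_all
    rec
  })
}

#' Generate a full phantom cohort (records + truth fields + echo series)
#'
#' Builds subject records via [generate_subjects()], then a per-knee
#' [generate_truth()] field (shared by both modalities) and per-modality
#' [simulate_echo_series()]. When `out_dir` is given, writes one 4D NIfTI
#' per knee per modality (with a JSON echo-time sidecar), the atlas, and
#' the records CSV, and returns the file manifest; otherwise returns the
#' bundle in memory.
#'
#' @inheritParams generate_subjects
#' @param atlas A `compartment_atlas`.
#' @param noise_model,noise_sd Echo-noise settings (see
#'   [simulate_echo_series()]).
#' @param modalities Subset of `c("T1rho", "T2")`.
#' @param out_dir Optional output directory.
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `records`, `atlas`, and either `truths`/`echoes`
#'   (in-memory mode) or `files` (disk mode).
#' @export
generate_cohort <- function(n_knees, atlas,
                            compartment_means = default_compartment_means(),
                            effects = list(),
                            grade_prevalence = default_grade_prevalence(),
                            covariate_model = default_covariate_model(),
                            noise_model = "gaussian", noise_sd = 2,
                            modalities = c("T1rho", "T2"),
                            seed = 1L, out_dir = NULL, force = FALSE) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  records <- generate_subjects(n_knees, effects = effects,
                               grade_prevalence = grade_prevalence,
                               covariate_model = covariate_model,
                               compartment_means = compartment_means,
                               seed = seed)
  offsets <- attr(records, "offsets_pct")
  knee_seeds <- derive_seeds(seed + 1L, n_knees * (1L + length(modalities)))
  primary_effect <- if (length(effects)) effects[[1]] else NULL

  to_disk <- !is.null(out_dir)
  files <- character(0)
  if (to_disk) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
      stopf("generate_cohort: output dir %s is non-empty (use force = TRUE)", out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  truths <- if (!to_disk) vector("list", n_knees) else NULL
  echoes <- if (!to_disk) vector("list", n_knees) else NULL

  for (i in seq_len(n_knees)) {
    truth <- generate_truth(atlas, compartment_means,
                            effect = primary_effect, subject = records[i, ],
                            offsets_pct = offsets[i, , ])
    # additional effects layered on the same field
    if (length(effects) > 1L) {
      for (ef in effects[-1L]) {
        extra <- generate_truth(atlas, compartment_means, effect = ef,
                                subject = records[i, ],
                                offsets_pct = offsets[i, , ])
        base <- generate_truth(atlas, compartment_means, effect = NULL,
                               offsets_pct = offsets[i, , ])
        truth$t1rho_ms <- truth$t1rho_ms + (extra$t1rho_ms - base$t1rho_ms)
        truth$t2_ms <- truth$t2_ms + (extra$t2_ms - base$t2_ms)
      }
    }
    series_i <- list()
    for (m in seq_along(modalities)) {
      mod <- modalities[m]
      es <- simulate_echo_series(truth, modality = mod,
                                 noise_model = noise_model, noise_sd = noise_sd,
                                 seed = knee_seeds[(i - 1L) * (1L + length(modalities)) + m])
      if (to_disk) {
        prefix <- file.path(out_dir, sprintf("%s_%s", records$subject_id[i], mod))
        files <- c(files, write_echo_series(es, prefix))
      } else {
        series_i[[mod]] <- es
      }
    }
    if (!to_disk) {
      truths[[i]] <- truth
      echoes[[i]] <- series_i
    }
  }

  if (to_disk) {
    atlas_path <- file.path(out_dir, "atlas.nii")
    write_nifti(array(as.double(atlas$labels), dim(atlas$labels)), atlas_path,
                spacing_mm = atlas$spacing_mm, datatype = 8L)
    csv_path <- file.path(out_dir, "subjects.csv")
    rec_out <- records
    attributes(rec_out)[c("offsets_pct", "item_subscale")] <- NULL
    utils::write.csv(format(rec_out, digits = 15, trim = TRUE, scientific = FALSE),
                     csv_path, row.names = FALSE, quote = FALSE)
    files <- c(files, atlas_path, csv_path)
    list(records = records, atlas = atlas, files = files)
  } else {
    list(records = records, atlas = atlas, truths = truths, echoes = echoes)
  }
}

#' Write / read an echo series as NIfTI + JSON sidecar
#'
#' @param series An [echo_series()].
#' @param path_prefix Output prefix; writes `<prefix>.nii` and
#'   `<prefix>.json`.
#' @return Character vector of the two paths written.
#' @export
write_echo_series <- function(series, path_prefix) {
  nii <- paste0(path_prefix, ".nii")
  js <- paste0(path_prefix, ".json")
  write_nifti(series$data, nii, spacing_mm = series$spacing_mm,
              t_units_ms = series$echo_times_ms)
  jsonlite::write_json(list(echo_times_ms = series$echo_times_ms,
                            modality = series$modality,
                            spacing_mm = series$spacing_mm,
                            meta = series$meta),
                       js, auto_unbox = TRUE, digits = NA, null = "null")
  c(nii, js)
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(path_prefix) {
  nii <- paste0(path_prefix, ".nii")
  js <- paste0(path_prefix, ".json")
  if (!file.exists(js)) stopf("read_echo_series: missing echo metadata sidecar %s", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  vol <- read_nifti(nii)
  echo_series(vol$data, meta$echo_times_ms, modality = meta$modality,
              spacing_mm = meta$spacing_mm, meta = as.list(meta$meta))
}
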
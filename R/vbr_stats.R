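# Voxel-wise statistical parametric mapping in atlas space.
#
# Per-voxel covariate-adjusted group differences (OLS with a group dummy),
# Pearson partial correlations against patient-reported outcomes or
# ordinal grades, P <= alpha thresholding with connected-component
# clustering, and compartment summaries (PSV, APD, average r, average P)
# under the reporting sign convention: NEGATIVE average percentage
# difference = HIGHER relaxation times in knees WITH the abnormality.

#' Stack atlas-space relaxation maps into a cohort matrix
#'
#' @param maps List of `relaxation_map`s on the atlas grid (one per
#'   subject, same order as `records`).
#' @param records data.frame of subject records (one row per knee).
#' @param min_coverage_fraction Voxels fitted (per [fit_quality_mask()]'s
#'   convention stored in each map's `mask & converged`) in at least this
#'   fraction of subjects enter the common mask (default 1 = strict
#'   intersection).
#' @param covariates Covariate columns checked for completeness; subjects
#'   with missing values are excluded with a message.
#' @param quality_masks Optional list of logical arrays overriding each
#'   map's own fitted-voxel mask.
#' @return Object of class `cohort_stack`: `values` (subjects x voxels,
#'   ms, NA where unfitted), `common_mask` (logical 3D), `voxel_index`
#'   (linear indices of mask voxels), `records`, `grid_dim`, `spacing_mm`.
#' @export
build_cohort_stack <- function(maps, records, min_coverage_fraction = 1,
                               covariates = c("age", "sex", "bmi", "site"),
                               quality_masks = NULL) {
  n <- length(maps)
  if (n != nrow(records)) stopf("build_cohort_stack: %d maps vs %d records", n, nrow(records))
  shp <- dim(maps[[1]]$time_ms)
  for (m in maps) {
    if (!identical(dim(m$time_ms), shp)) stopf("build_cohort_stack: maps on different grids")
  }
  have_cov <- intersect(covariates, names(records))
  keep <- rep(TRUE, n)
  if (length(have_cov)) {
    keep <- stats::complete.cases(records[, have_cov, drop = FALSE])
    if (any(!keep)) {
      message(sprintf("build_cohort_stack: excluding %d subject(s) with missing covariates: %s",
                      sum(!keep), paste(records$subject_id[!keep], collapse = ", ")))
    }
  }
  maps <- maps[keep]; records <- records[keep, , drop = FALSE]
  n <- length(maps)
  if (n < 4L) stopf("build_cohort_stack: only %d usable subjects (< 4): model unidentifiable", n)

  fitted_masks <- if (!is.null(quality_masks)) quality_masks[keep] else
    lapply(maps, function(m) m$mask & m$converged)
  coverage <- Reduce(`+`, lapply(fitted_masks, function(x) array(as.integer(x), shp)))
  common_mask <- coverage >= ceiling(min_coverage_fraction * n) & coverage > 0
  vox <- which(common_mask)
  values <- matrix(NA_real_, n, length(vox))
  for (i in seq_len(n)) {
    v <- maps[[i]]$time_ms[vox]
    v[!fitted_masks[[i]][vox]] <- NA_real_
    values[i, ] <- v
  }
  structure(list(values = values, common_mask = array(common_mask, shp),
                 voxel_index = vox, records = records,
                 grid_dim = shp, spacing_mm = maps[[1]]$spacing_mm),
            class = "cohort_stack")
}

# Build the covariate design matrix (no group/outcome column). Site is
# one-hot with the first level as reference and is dropped (with a
# message) for single-site cohorts; sex is binary.
covariate_design <- function(records, covariates) {
  n <- nrow(records)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.null(v)) stopf("unknown covariate '%s' (available: %s)",
                          cv, paste(names(records), collapse = ", "))
    if (cv %in% c("sex", "site") || is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) < 2L) {
        message(sprintf("covariate '%s' has a single level; dropped", cv))
        next
      }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, stats::setNames(matrix(as.numeric(v), n, 1), NULL))
      colnames(X)[ncol(X)] <- cv
    }
  }
  X
}

assert_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  q
}

new_spm_result <- function(stack, effect, p, kind, covariates) {
  structure(list(effect = effect, p = p,
                 sig_mask = NULL, clusters = NULL,
                 analysis_kind = kind, covariates_used = covariates,
                 voxel_index = stack$voxel_index,
                 common_mask = stack$common_mask,
                 grid_dim = stack$grid_dim,
                 spacing_mm = stack$spacing_mm,
                 degenerate = NULL),
            class = "spm_result")
}

#' Voxel-wise covariate-adjusted group difference
#'
#' Per voxel, ordinary least squares of relaxation time on an intercept,
#' a binary group indicator (grade >= `grade_threshold` = "with
#' abnormality") and the covariates; p is the two-sided t-test on the
#' group coefficient. The effect map is the adjusted percentage
#' difference `100 * (m_without - m_with) / m_without` evaluated at the
#' covariate means, so a negative value means higher relaxation times in
#' knees with the abnormality. Voxels with zero residual variance are
#' degenerate: effect as computed, p = 1, flagged.
#'
#' @param stack A `cohort_stack`.
#' @param group_variable Grade column in the records.
#' @param covariates Covariate columns (default age/sex/bmi/site).
#' @param grade_threshold Dichotomization threshold (default 1).
#' @return An `spm_result` (`analysis_kind = "difference"`).
#' @export
voxelwise_group_difference <- function(stack, group_variable,
                                       covariates = c("age", "sex", "bmi", "site"),
                                       grade_threshold = 1L) {
  rec <- stack$records
  g <- rec[[group_variable]]
  if (is.null(g)) stopf("unknown group variable '%s'", group_variable)
  grp <- as.numeric(g >= grade_threshold)
  if (all(grp == 0) || all(grp == 1)) {
    stopf("voxelwise_group_difference: both groups must be nonempty for '%s'", group_variable)
  }
  Xc <- covariate_design(rec, covariates)
  X <- cbind(Xc[, 1, drop = FALSE], group = grp, Xc[, -1, drop = FALSE])
  assert_full_rank(X)
  n <- nrow(X); p_cols <- ncol(X); df <- n - p_cols
  if (df < 1L) stopf("voxelwise_group_difference: %d subjects too few for %d parameters", n, p_cols)

  Y <- stack$values
  # Mean-impute sporadic NAs inside the common mask (coverage < 1 mode);
  # with the default strict mask there are none.
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
  }
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se_g <- sqrt(pmax(sigma2 * XtX_inv[2, 2], 0))
  tstat <- beta[2, ] / se_g
  pval <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- sigma2 <= .Machine$double.eps * 100
  pval[degenerate] <- 1

  # Adjusted group means at the covariate means.
  xbar <- colMeans(X)
  x0 <- xbar; x0["group"] <- 0
  m_without <- as.vector(x0 %*% beta)
  m_with <- m_without + beta[2, ]
  effect <- 100 * (m_without - m_with) / m_without
  out <- new_spm_result(stack, effect, pval, "difference",
                        c(group_variable, covariates))
  out$degenerate <- degenerate
  out
}

#' Voxel-wise Pearson partial correlation
#'
#' Per voxel, the partial correlation between relaxation time and a
#' per-subject outcome controlling for covariates: both are residualized
#' on the covariates (+ intercept) and the residual vectors correlated.
#' p from `t = r * sqrt((n - k - 2) / (1 - r^2))` with k = number of
#' covariate columns (0 covariates reduces to the plain Pearson r).
#'
#' @param stack A `cohort_stack`.
#' @param outcome Either a record column name or a numeric vector
#'   (length = subjects): KOOS subscale, single item, or ordinal grade
#'   (treated as numeric).
#' @param covariates Covariate columns (may be empty).
#' @return An `spm_result` (`analysis_kind = "correlation"`, `effect` =
#'   partial r).
#' @export
voxelwise_partial_correlation <- function(stack, outcome,
                                          covariates = c("age", "sex", "bmi", "site")) {
  rec <- stack$records
  o <- if (is.character(outcome) && length(outcome) == 1L) {
    v <- rec[[outcome]]
    if (is.null(v)) stopf("unknown outcome '%s'", outcome)
    as.numeric(v)
  } else as.numeric(outcome)
  if (length(o) != nrow(rec)) stopf("outcome length %d != %d subjects", length(o), nrow(rec))
  if (stats::var(o) <= 0) stopf("voxelwise_partial_correlation: outcome has zero variance")
  X <- covariate_design(rec, covariates)
  qrX <- assert_full_rank(X)
  k <- ncol(X) - 1L
  n <- nrow(X)
  if (n - k - 2L < 1L) stopf("voxelwise_partial_correlation: n - k - 2 = %d < 1", n - k - 2L)

  Y <- stack$values
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
  }
  ry <- qr.resid(qrX, Y)
  ro <- qr.resid(qrX, o)
  num <- as.vector(crossprod(ry, ro))
  den <- sqrt(colSums(ry^2) * sum(ro^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  df <- n - k - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[is.na(r)] <- 1
  out <- new_spm_result(stack, r, pval, "correlation", covariates)
  out$outcome_n <- n
  out
}

# Connected components of a logical 3D array at 6- or 26-connectivity.
# Returns an integer array of component labels (0 = background).
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, ]
  } else if (connectivity != 26L) {
    stopf("connected_components: connectivity must be 6 or 26")
  }
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  comp <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    frontier <- start
    labels[start] <- comp
    while (length(frontier)) {
      ci <- arrayInd(frontier, d)
      nbr <- NULL
      for (r in seq_len(nrow(offs))) {
        cand <- cbind(ci[, 1] + offs$dx[r], ci[, 2] + offs$dy[r], ci[, 3] + offs$dz[r])
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
        if (any(ok)) {
          lin <- cand[ok, 1] + (cand[ok, 2] - 1L) * d[1] + (cand[ok, 3] - 1L) * d[1] * d[2]
          nbr <- c(nbr, lin[mask[lin] & labels[lin] == 0L])
        }
      }
      nbr <- unique(nbr)
      if (length(nbr)) labels[nbr] <- comp
      frontier <- nbr
    }
  }
  labels
}

#' Threshold a p map and extract significance clusters
#'
#' `sig_mask = {p <= alpha}`; connected components at the stated
#' connectivity; components below `min_cluster_voxels` are removed from
#' the mask. Per-cluster size and mean p are recorded.
#'
#' @param spm An `spm_result`.
#' @param alpha Significance threshold (default 0.05).
#' @param connectivity 26 (default) or 6.
#' @param min_cluster_voxels Minimum component size kept (default 1).
#' @return The `spm_result` with `sig_mask` (logical 3D) and `clusters`
#'   (data.frame: cluster, size, mean_p) filled.
#' @export
threshold_and_cluster <- function(spm, alpha = 0.05, connectivity = 26L,
                                  min_cluster_voxels = 1L) {
  stopifnot(inherits(spm, "spm_result"))
  sig <- array(FALSE, spm$grid_dim)
  sig[spm$voxel_index[spm$p <= alpha]] <- TRUE
  labs <- connected_components(sig, connectivity)
  p_vol <- array(NA_real_, spm$grid_dim)
  p_vol[spm$voxel_index] <- spm$p
  ncomp <- max(labs)
  keep_rows <- list()
  ci <- 0L
  for (cmp in seq_len(ncomp)) {
    vox <- which(labs == cmp)
    if (length(vox) < min_cluster_voxels) {
      sig[vox] <- FALSE
      next
    }
    ci <- ci + 1L
    keep_rows[[ci]] <- data.frame(cluster = ci, size = length(vox),
                                  mean_p = mean(p_vol[vox]))
  }
  spm$sig_mask <- sig
  spm$clusters <- if (ci) do.call(rbind, keep_rows) else
    data.frame(cluster = integer(0), size = integer(0), mean_p = numeric(0))
  spm$alpha <- alpha
  spm
}

#' Compartment summaries: PSV, APD / average r, average P
#'
#' Per compartment c: `PSV = 100 * |sig & c| / |c|`; the mean effect over
#' significant voxels is the APD (difference analyses) or the average r
#' (correlation analyses); `average P` is the mean p over significant
#' voxels. Empty intersections leave the means NA.
#'
#' @param spm A thresholded `spm_result` (run [threshold_and_cluster()]
#'   first).
#' @param atlas A `compartment_atlas` on the same grid.
#' @return data.frame: compartment, n_voxels, n_sig_voxels, psv_pct,
#'   apd_pct or avg_r (by analysis kind), avg_p.
#' @export
summarize_by_compartment <- function(spm, atlas) {
  stopifnot(inherits(spm, "spm_result"), inherits(atlas, "compartment_atlas"))
  if (is.null(spm$sig_mask)) stopf("summarize_by_compartment: run threshold_and_cluster() first")
  if (!identical(dim(atlas$labels), spm$grid_dim)) {
    stopf("summarize_by_compartment: atlas grid does not match the SPM grid")
  }
  eff_vol <- array(NA_real_, spm$grid_dim); eff_vol[spm$voxel_index] <- spm$effect
  p_vol <- array(NA_real_, spm$grid_dim); p_vol[spm$voxel_index] <- spm$p
  out <- data.frame(compartment = compartment_names(),
                    n_voxels = NA_integer_, n_sig_voxels = NA_integer_,
                    psv_pct = NA_real_, effect_mean = NA_real_, avg_p = NA_real_)
  for (i in seq_len(nrow(out))) {
    lab <- COMPARTMENT_LABELS[[out$compartment[i]]]
    comp <- atlas$labels == lab
    nvox <- sum(comp)
    sig <- comp & spm$sig_mask
    nsig <- sum(sig)
    out$n_voxels[i] <- nvox
    out$n_sig_voxels[i] <- nsig
    out$psv_pct[i] <- if (nvox) 100 * nsig / nvox else NA_real_
    if (nsig) {
      out$effect_mean[i] <- mean(eff_vol[sig], na.rm = TRUE)
      out$avg_p[i] <- mean(p_vol[sig], na.rm = TRUE)
    }
  }
  names(out)[names(out) == "effect_mean"] <-
    if (spm$analysis_kind == "difference") "apd_pct" else "avg_r"
  out
}

#' Display transform of the p map: 10 x log10(1 / p)
#'
#' @param spm An `spm_result`.
#' @return 3D array (NA outside the common mask); p = 0 is clipped to the
#'   smallest positive double (with a message).
#' @export
neglog_p_map <- function(spm) {
  p <- spm$p
  if (any(p <= 0, na.rm = TRUE)) {
    message("neglog_p_map: clipping p = 0 to the smallest positive double")
    p[p <= 0] <- .Machine$double.xmin
  }
  vol <- array(NA_real_, spm$grid_dim)
  vol[spm$voxel_index] <- 10 * log10(1 / p)
  vol
}

#' Permutation p-values for the group contrast
#'
#' Freedman-Lane-free simple relabeling: the group indicator is permuted
#' across subjects (covariate rows kept attached to their subjects) and
#' the group t-statistic recomputed; `p = (1 + #{|t*| >= |t|}) /
#' (n_perm + 1)`.
#'
#' @inheritParams voxelwise_group_difference
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return An `spm_result` with permutation p-values (effect map as in
#'   [voxelwise_group_difference()]).
#' @export
voxelwise_group_permutation <- function(stack, group_variable,
                                        covariates = c("age", "sex", "bmi", "site"),
                                        grade_threshold = 1L,
                                        n_perm = 999L, seed = 1L) {
  rec <- stack$records
  grp <- as.numeric(rec[[group_variable]] >= grade_threshold)
  Xc <- covariate_design(rec, covariates)
  Y <- stack$values
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
  }
  tstat_for <- function(g) {
    X <- cbind(Xc[, 1, drop = FALSE], group = g, Xc[, -1, drop = FALSE])
    XtX_inv <- solve(crossprod(X))
    beta <- XtX_inv %*% crossprod(X, Y)
    res <- Y - X %*% beta
    df <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / df
    beta[2, ] / sqrt(pmax(sigma2 * XtX_inv[2, 2], .Machine$double.xmin))
  }
  t_obs <- abs(tstat_for(grp))
  count <- rep(1L, length(t_obs))
  perms <- with_seed(seed, replicate(n_perm, sample(grp), simplify = FALSE))
  for (g in perms) {
    count <- count + (abs(tstat_for(g)) >= t_obs)
  }
  pval <- count / (n_perm + 1)
  par_spm <- voxelwise_group_difference(stack, group_variable, covariates, grade_threshold)
  out <- new_spm_result(stack, par_spm$effect, pval, "difference",
                        c(group_variable, covariates))
  out$n_perm <- n_perm
  out
}

#' Run a battery of contrasts and produce report tables
#'
#' One SPM + compartment summary per contrast per modality, mirroring the
#' published table layout (difference contrasts: compartment rows with
#' PSV %, APD %, average P; correlation contrasts: PSV correlated %,
#' average r, average P). No cross-contrast multiplicity adjustment.
#'
#' @param stacks Named list of `cohort_stack`s, e.g.
#'   `list(T1rho = ..., T2 = ...)`.
#' @param contrasts List of contrast descriptors:
#'   `list(kind = "difference", variable = "grade_...")` or
#'   `list(kind = "correlation", outcome = "koos_symptoms")`.
#' @param atlas The `compartment_atlas`.
#' @param alpha Significance threshold (default 0.05).
#' @param covariates Adjustment covariates.
#' @param connectivity,min_cluster_voxels Clustering parameters.
#' @return List: `results` (nested: modality -> contrast -> list(spm,
#'   summary)), `table` (long data.frame across all contrasts).
#' @export
run_contrast_battery <- function(stacks, contrasts, atlas, alpha = 0.05,
                                 covariates = c("age", "sex", "bmi", "site"),
                                 connectivity = 26L, min_cluster_voxels = 1L) {
  results <- list()
  rows <- list()
  for (mod in names(stacks)) {
    stack <- stacks[[mod]]
    results[[mod]] <- list()
    for (ct in contrasts) {
      nm <- ct$variable %||% ct$outcome
      avail <- names(stack$records)
      if (!nm %in% avail && is.character(nm)) {
        stopf("run_contrast_battery: unknown field '%s'; available: %s",
              nm, paste(grep("^(grade_|koos_)", avail, value = TRUE), collapse = ", "))
      }
      spm <- if (ct$kind == "difference") {
        voxelwise_group_difference(stack, nm, covariates,
                                   grade_threshold = ct$grade_threshold %||% 1L)
      } else {
        voxelwise_partial_correlation(stack, nm, covariates)
      }
      spm <- threshold_and_cluster(spm, alpha, connectivity, min_cluster_voxels)
      summ <- summarize_by_compartment(spm, atlas)
      results[[mod]][[nm]] <- list(spm = spm, summary = summ)
      eff_col <- if (ct$kind == "difference") "apd_pct" else "avg_r"
      rows[[length(rows) + 1L]] <- data.frame(
        modality = mod, contrast = nm, kind = ct$kind,
        compartment = summ$compartment, psv_pct = summ$psv_pct,
        effect = summ[[eff_col]], avg_p = summ$avg_p,
        n_sig_voxels = summ$n_sig_voxels)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(modality = character(0), contrast = character(0),
               kind = character(0), compartment = character(0),
               psv_pct = numeric(0), effect = numeric(0),
               avg_p = numeric(0), n_sig_voxels = integer(0))
  list(results = results, table = table)
}
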
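# Per-voxel mono-exponential relaxation mapping: S(t) = S0 * exp(-t / T).
#
# Two estimators: a closed-form log-linear least-squares fit (exact on
# noiseless data; also the initializer) and a vectorized Levenberg-
# Marquardt nonlinear least-squares fit run simultaneously over all
# masked voxels (closed-form 2x2 normal equations per voxel).

new_relaxation_map <- function(shp, spacing_mm, modality, bounds) {
  structure(list(time_ms = array(NA_real_, shp),
                 s0 = array(NA_real_, shp),
                 r_squared = array(NA_real_, shp),
                 converged = array(FALSE, shp),
                 mask = array(FALSE, shp),
                 spacing_mm = spacing_mm, modality = modality,
                 bounds = bounds),
            class = "relaxation_map")
}

# Signal-space R^2 against the mean-signal null, given observed (V x E)
# and fitted (V x E) matrices. Zero total variance gives NA.
signal_r_squared <- function(S, M) {
  ss_res <- rowSums((S - M)^2)
  ss_tot <- rowSums((S - rowMeans(S))^2)
  r2 <- 1 - ss_res / ss_tot
  r2[ss_tot <= 0] <- NA_real_
  r2
}

#' Closed-form log-linear relaxation fit
#'
#' Ordinary least squares of `log(S)` on echo time per voxel: slope
#' `= -1/T`, intercept `= log(S0)`. Exact on noiseless data; used as the
#' initializer and the independent oracle for the Levenberg-Marquardt fit.
#' Voxels with any non-positive signal, or a non-negative slope (no
#' decay), are flagged unfitted rather than raising an error.
#'
#' @param series An [echo_series()].
#' @param mask Logical 3D array of voxels to fit (default: all voxels).
#' @param bounds Admissible `(T_min, T_max)` in ms.
#' @return A `relaxation_map`: `time_ms`, `s0`, `r_squared` (signal-space,
#'   against the mean-signal null), `converged`, `mask`.
#' @export
loglinear_fit <- function(series, mask = NULL, bounds = c(1, 200)) {
  stopifnot(inherits(series, "echo_series"))
  shp <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, shp)
  t <- series$echo_times_ms
  idx <- which(mask)
  out <- new_relaxation_map(shp, series$spacing_mm, series$modality, bounds)
  out$mask <- array(as.logical(mask), shp)
  if (!length(idx)) return(out)
  S <- matrix(series$data, ncol = length(t))[idx, , drop = FALSE]
  pos <- rowSums(S <= 0 | !is.finite(S)) == 0L
  if (any(pos)) {
    Y <- log(S[pos, , drop = FALSE])
    tc <- t - mean(t)
    denom <- sum(tc^2)
    slope <- as.vector(Y %*% tc) / denom
    intercept <- rowMeans(Y) - slope * mean(t)
    Tv <- rep(NA_real_, sum(pos))
    fitted_ok <- slope < 0
    Tv[fitted_ok] <- -1 / slope[fitted_ok]
    s0 <- exp(intercept)
    Mfit <- s0 * exp(outer(-1 / ifelse(fitted_ok, Tv, Inf), t))  # flat when no decay
    r2 <- signal_r_squared(S[pos, , drop = FALSE], Mfit)
    sub <- idx[pos]
    out$time_ms[sub] <- Tv
    out$s0[sub] <- s0
    out$r_squared[sub] <- r2
    out$converged[sub] <- fitted_ok & is.finite(Tv)
  }
  out
}

#' Levenberg-Marquardt mono-exponential fit
#'
#' Minimizes `sum_t (S_obs(t) - S0 * exp(-t/T))^2` per masked voxel by a
#' vectorized Levenberg-Marquardt iteration (per-voxel damping, closed
#' form 2x2 steps), initialized from [loglinear_fit()] (signals floored
#' at a small epsilon for the log initializer only; LM itself sees raw
#' values). T is clamped to `bounds` during iteration; voxels ending on a
#' bound remain flagged by [fit_quality_mask()].
#'
#' @param series An [echo_series()].
#' @param mask Logical 3D array; must contain at least one voxel.
#' @param bounds Admissible `(T_min, T_max)` in ms, `0 < T_min < T_max`.
#' @param init `"loglinear"` (default) or `"fixed"` (S0 = max signal,
#'   T = geometric mean of the bounds).
#' @param max_iter,tol Iteration cap and relative-step convergence
#'   tolerance.
#' @return A `relaxation_map` (see [loglinear_fit()]).
#' @export
fit_monoexponential <- function(series, mask = NULL, bounds = c(1, 200),
                                init = c("loglinear", "fixed"),
                                max_iter = 50L, tol = 1e-10) {
  stopifnot(inherits(series, "echo_series"))
  init <- match.arg(init)
  if (!(bounds[1] > 0 && bounds[1] < bounds[2])) {
    stopf("fit_monoexponential: bounds must satisfy 0 < T_min < T_max")
  }
  shp <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, shp)
  idx <- which(mask)
  if (!length(idx)) stopf("fit_monoexponential: empty mask")
  t <- series$echo_times_ms
  S <- matrix(series$data, ncol = length(t))[idx, , drop = FALSE]
  finite_ok <- rowSums(!is.finite(S)) == 0L

  out <- new_relaxation_map(shp, series$spacing_mm, series$modality, bounds)
  out$mask <- array(as.logical(mask), shp)
  if (!any(finite_ok)) return(out)

  Sf <- S[finite_ok, , drop = FALSE]
  V <- nrow(Sf)
  eps <- 1e-6 * max(abs(Sf), 1e-12)
  if (init == "loglinear") {
    Y <- log(pmax(Sf, eps))
    tc <- t - mean(t)
    slope <- as.vector(Y %*% tc) / sum(tc^2)
    Tv <- ifelse(slope < 0, -1 / slope, sqrt(bounds[1] * bounds[2]))
    s0 <- exp(rowMeans(Y) - slope * mean(t))
  } else {
    Tv <- rep(sqrt(bounds[1] * bounds[2]), V)
    s0 <- apply(Sf, 1L, max)
  }
  Tv <- pmin(pmax(Tv, bounds[1]), bounds[2])
  s0 <- pmax(s0, eps)

  cost_of <- function(s0v, Tvv, rows) {
    M <- s0v * exp(outer(-1 / Tvv, t))
    rowSums((Sf[rows, , drop = FALSE] - M)^2)
  }
  lambda <- rep(1e-3, V)
  cost <- cost_of(s0, Tv, seq_len(V))
  conv <- rep(FALSE, V)
  for (it in seq_len(max_iter)) {
    act <- which(!conv)
    if (!length(act)) break
    E <- exp(outer(-1 / Tv[act], t))          # n_act x E
    M <- s0[act] * E
    R <- Sf[act, , drop = FALSE] - M
    J2 <- M * outer(1 / Tv[act]^2, t)         # dM/dT
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * J2)
    a22 <- rowSums(J2 * J2)
    g1 <- rowSums(E * R)
    g2 <- rowSums(J2 * R)
    d11 <- a11 * (1 + lambda[act])
    d22 <- a22 * (1 + lambda[act])
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- NA
    ds0 <- (d22 * g1 - a12 * g2) / det
    dT <- (d11 * g2 - a12 * g1) / det
    bad_step <- !is.finite(ds0) | !is.finite(dT)
    ds0[bad_step] <- 0; dT[bad_step] <- 0
    s0_new <- pmax(s0[act] + ds0, 0)
    T_new <- pmin(pmax(Tv[act] + dT, bounds[1]), bounds[2])
    cost_new <- cost_of(s0_new, T_new, act)
    better <- is.finite(cost_new) & (cost_new <= cost[act])
    upd <- act[better]
    rel_step <- pmax(abs(ds0[better]) / pmax(abs(s0[act][better]), 1e-12),
                     abs(dT[better]) / pmax(abs(Tv[act][better]), 1e-12))
    s0[upd] <- s0_new[better]
    Tv[upd] <- T_new[better]
    cost[upd] <- cost_new[better]
    lambda[upd] <- pmax(lambda[upd] / 3, 1e-12)
    lambda[act[!better]] <- pmin(lambda[act[!better]] * 5, 1e12)
    conv[upd] <- rel_step < tol
    conv[act[!better]] <- conv[act[!better]] | lambda[act[!better]] >= 1e12
  }

  Mfin <- s0 * exp(outer(-1 / Tv, t))
  r2 <- signal_r_squared(Sf, Mfin)
  sub <- idx[finite_ok]
  out$time_ms[sub] <- Tv
  out$s0[sub] <- s0
  out$r_squared[sub] <- r2
  out$converged[sub] <- TRUE
  # non-finite voxels stay flagged (converged FALSE, NA values)
  out
}

#' Fit-quality mask
#'
#' Retains voxels that converged, meet the minimum signal-space R^2, and
#' whose relaxation time is strictly inside the fitting bounds.
#'
#' @param map A `relaxation_map`.
#' @param min_r_squared Minimum R^2 (default 0.8).
#' @param bounds Defaults to the map's own fitting bounds.
#' @return Logical 3D array.
#' @export
fit_quality_mask <- function(map, min_r_squared = 0.8, bounds = map$bounds) {
  stopifnot(inherits(map, "relaxation_map"))
  ok <- map$mask & map$converged &
    !is.na(map$r_squared) & map$r_squared >= min_r_squared &
    !is.na(map$time_ms) & map$time_ms > bounds[1] & map$time_ms < bounds[2]
  ok[is.na(ok)] <- FALSE
  array(ok, dim(map$mask))
}

#' Write a relaxation map as NIfTI volumes plus a JSON fit report
#'
#' Writes `<prefix>_time.nii`, `<prefix>_s0.nii`, `<prefix>_r2.nii`,
#' `<prefix>_mask.nii` and `<prefix>_report.json` (voxel counts and
#' convergence rate).
#'
#' @param map A `relaxation_map`.
#' @param path_prefix Output path prefix.
#' @return Character vector of paths written.
#' @export
write_relaxation_map <- function(map, path_prefix) {
  paths <- c(time = paste0(path_prefix, "_time.nii"),
             s0 = paste0(path_prefix, "_s0.nii"),
             r2 = paste0(path_prefix, "_r2.nii"),
             mask = paste0(path_prefix, "_mask.nii"),
             report = paste0(path_prefix, "_report.json"))
  z <- function(a) { a[is.na(a)] <- 0; a }
  write_nifti(z(map$time_ms), paths["time"], spacing_mm = map$spacing_mm)
  write_nifti(z(map$s0), paths["s0"], spacing_mm = map$spacing_mm)
  write_nifti(z(map$r_squared), paths["r2"], spacing_mm = map$spacing_mm)
  write_nifti(array(as.double(map$mask & map$converged), dim(map$mask)),
              paths["mask"], spacing_mm = map$spacing_mm, datatype = 2L)
  n_mask <- sum(map$mask)
  jsonlite::write_json(list(modality = map$modality,
                            n_voxels_masked = n_mask,
                            n_converged = sum(map$converged),
                            convergence_rate = if (n_mask) sum(map$converged) / n_mask else NA,
                            bounds_ms = map$bounds),
                       paths["report"], auto_unbox = TRUE, digits = NA)
  unname(paths)
}
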
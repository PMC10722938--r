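# Rigid echo alignment and subject-to-atlas resampling.
#
# The rigid stage (all echoes to the first spin-lock time / echo time) is
# implemented here with a mean-squared-error metric and a 2-level
# multi-resolution search; full deformable registration is a pluggable
# backend (phantom data are generated in atlas space, so the default
# atlas mode is an identity passthrough with a grid check).

#' Rigid transform (3 Euler angles + translation, about a center)
#'
#' Maps a world point p (mm) to `R (p - c) + c + t`, with `R` the ZYX
#' Euler rotation.
#'
#' @param rotation Angles (radians) about x, y, z.
#' @param translation mm per axis.
#' @param center Rotation center, mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  structure(list(rotation = rotation, translation = translation,
                 center = center, R = Rz %*% Ry %*% Rx),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  out <- rigid_transform(-tf$rotation[c(1, 2, 3)], c(0, 0, 0), tf$center)
  out$R <- t(tf$R)
  out$rotation <- -tf$rotation  # informational; R is authoritative
  out$translation <- as.vector(-t(tf$R) %*% tf$translation)
  out
}

# Apply transform to an n x 3 matrix of points (mm).
transform_points <- function(tf, pts) {
  ctr <- matrix(tf$center, nrow(pts), 3, byrow = TRUE)
  sweep((pts - ctr) %*% t(tf$R), 2, tf$center + tf$translation, "+")
}

# Vectorized trilinear sampling. `pts_vox` are 0-based continuous voxel
# coordinates (n x 3); values outside the grid return `default`.
trilinear_sample <- function(vol, pts_vox, default = 0) {
  d <- dim(vol)
  x <- pts_vox[, 1]; y <- pts_vox[, 2]; z <- pts_vox[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
    x0 <= d[1] - 2 + (fx == 0) & y0 <= d[2] - 2 + (fy == 0) &
    z0 <= d[3] - 2 + (fz == 0) &
    x >= 0 & y >= 0 & z >= 0 & x <= d[1] - 1 & y <= d[2] - 1 & z <= d[3] - 1
  out <- rep(default, nrow(pts_vox))
  if (!any(inside)) return(out)
  x0i <- pmin(pmax(x0[inside], 0), d[1] - 2); fxi <- x[inside] - x0i
  y0i <- pmin(pmax(y0[inside], 0), d[2] - 2); fyi <- y[inside] - y0i
  z0i <- pmin(pmax(z0[inside], 0), d[3] - 2); fzi <- z[inside] - z0i
  at <- function(ix, iy, iz) vol[cbind(ix + 1, iy + 1, iz + 1)]
  v000 <- at(x0i, y0i, z0i);     v100 <- at(x0i + 1, y0i, z0i)
  v010 <- at(x0i, y0i + 1, z0i); v110 <- at(x0i + 1, y0i + 1, z0i)
  v001 <- at(x0i, y0i, z0i + 1); v101 <- at(x0i + 1, y0i, z0i + 1)
  v011 <- at(x0i, y0i + 1, z0i + 1); v111 <- at(x0i + 1, y0i + 1, z0i + 1)
  out[inside] <-
    v000 * (1 - fxi) * (1 - fyi) * (1 - fzi) + v100 * fxi * (1 - fyi) * (1 - fzi) +
    v010 * (1 - fxi) * fyi * (1 - fzi) + v110 * fxi * fyi * (1 - fzi) +
    v001 * (1 - fxi) * (1 - fyi) * fzi + v101 * fxi * (1 - fyi) * fzi +
    v011 * (1 - fxi) * fyi * fzi + v111 * fxi * fyi * fzi
  out
}

# Nearest-neighbour sampling (labels / masks).
nearest_sample <- function(vol, pts_vox, default = 0) {
  d <- dim(vol)
  ix <- round(pts_vox[, 1]); iy <- round(pts_vox[, 2]); iz <- round(pts_vox[, 3])
  inside <- ix >= 0 & iy >= 0 & iz >= 0 & ix <= d[1] - 1 & iy <= d[2] - 1 & iz <= d[3] - 1
  out <- rep(default, nrow(pts_vox))
  out[inside] <- vol[cbind(ix[inside] + 1, iy[inside] + 1, iz[inside] + 1)]
  out
}

# World-coordinate grid of voxel centers (n x 3, mm), cached per call.
world_grid <- function(shp, spacing_mm) {
  idx <- arrayInd(seq_len(prod(shp)), shp) - 1L
  sweep(idx, 2, spacing_mm, "*")
}

#' Resample a volume through a point transform
#'
#' Inverse-mapping resampler: each output voxel at world position p takes
#' the input volume's (trilinearly interpolated) value at `transform(p)`.
#'
#' @param vol 3D array (the input/moving volume).
#' @param tf A `rigid_transform`, or a function mapping an n x 3 matrix of
#'   mm points to n x 3 sampled positions.
#' @param spacing_mm Voxel spacing shared by input and output grids.
#' @param out_shape Output grid shape (default: input shape).
#' @param interp `"linear"` or `"nearest"`.
#' @return Resampled 3D array.
#' @export
resample_volume <- function(vol, tf, spacing_mm, out_shape = dim(vol),
                            interp = c("linear", "nearest"), pts = NULL) {
  interp <- match.arg(interp)
  if (is.null(pts)) pts <- world_grid(out_shape, spacing_mm)
  mapped <- if (inherits(tf, "rigid_transform")) transform_points(tf, pts) else tf(pts)
  pv <- sweep(mapped, 2, spacing_mm, "/")
  vals <- if (interp == "linear") trilinear_sample(vol, pv) else nearest_sample(vol, pv)
  array(vals, out_shape)
}

# 2x downsampling by mean pooling (multi-resolution level); odd trailing
# planes are cropped. Volumes smaller than 4 voxels per axis pass through.
downsample2 <- function(vol) {
  d <- dim(vol)
  if (any(d < 4L)) return(vol)
  d2 <- d %/% 2L
  i1 <- seq(1L, 2L * d2[1], by = 2L)
  j1 <- seq(1L, 2L * d2[2], by = 2L)
  k1 <- seq(1L, 2L * d2[3], by = 2L)
  acc <- array(0, d2)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    acc <- acc + vol[i1 + di, j1 + dj, k1 + dk]
  }
  acc / 8
}

mse_metric <- function(a, b) mean((a - b)^2)

# Optimize a rigid transform aligning `moving` onto `fixed` (same grid) by
# minimizing MSE over (rotation, translation), 2-level pyramid.
register_rigid_pair <- function(fixed, moving, spacing_mm,
                                center = NULL, maxit = 400L) {
  center <- center %||% ((dim(fixed) - 1) * spacing_mm / 2)
  nf <- function(v) v / max(mean(abs(v)), 1e-12)
  fixed_n <- nf(fixed); moving_n <- nf(moving)
  pts_cache <- new.env(parent = emptyenv())
  grid_pts <- function(shp, sp) {
    key <- paste(c(shp, sp), collapse = "_")
    if (is.null(pts_cache[[key]])) pts_cache[[key]] <- world_grid(shp, sp)
    pts_cache[[key]]
  }
  objective <- function(par, fx, mv, sp) {
    tf <- rigid_transform(par[1:3], par[4:6], center)
    mse_metric(fx, resample_volume(mv, tf, sp, out_shape = dim(fx),
                                   pts = grid_pts(dim(fx), sp)))
  }
  par <- rep(0, 6)
  fx_c <- downsample2(fixed_n); mv_c <- downsample2(moving_n)
  sp_c <- spacing_mm * (dim(fixed_n)[1] / dim(fx_c)[1])
  # Coarse exhaustive translation search (one-voxel steps at the coarse
  # level) to escape plateaus of piecewise-constant images, then local
  # refinement at both levels.
  steps <- -4:4
  best <- c(0, 0, 0); best_val <- objective(par, fx_c, mv_c, sp_c)
  for (tx in steps) for (ty in steps) for (tz in steps) {
    v <- objective(c(0, 0, 0, tx * sp_c[1], ty * sp_c[2], tz * sp_c[3]),
                   fx_c, mv_c, sp_c)
    if (v < best_val) { best_val <- v; best <- c(tx * sp_c[1], ty * sp_c[2], tz * sp_c[3]) }
  }
  par[4:6] <- best
  lvls <- list(list(fx = fx_c, mv = mv_c, sp = sp_c),
               list(fx = fixed_n, mv = moving_n, sp = spacing_mm))
  for (lv in lvls) {
    opt <- stats::optim(par, objective, fx = lv$fx, mv = lv$mv, sp = lv$sp,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = c(rep(0.05, 3), rep(1, 3))))
    par <- opt$par
  }
  if (!is.finite(opt$value)) stopf("register_rigid_pair: optimization diverged")
  list(transform = rigid_transform(par[1:3], par[4:6], center), mse = opt$value)
}

#' Rigidly align all echoes to the first echo
#'
#' Echo 0 defines the reference frame; each later echo is registered to it
#' by rigid MSE optimization (on mean-normalized intensities, since echoes
#' differ by a global decay factor) and resampled into its frame.
#'
#' @param series An [echo_series()] (>= 2 echoes).
#' @param maxit Optimizer iteration cap per level.
#' @return List: `series` (aligned copy) and `transforms` (per-echo
#'   `rigid_transform`; identity for echo 1).
#' @export
register_echoes_rigid <- function(series, maxit = 400L) {
  ne <- length(series$echo_times_ms)
  if (ne < 2L) stopf("register_echoes_rigid: need >= 2 echoes, got %d", ne)
  fixed <- series$data[, , , 1]
  out <- series$data
  tfs <- vector("list", ne)
  tfs[[1]] <- rigid_transform()
  for (e in 2:ne) {
    res <- tryCatch(
      register_rigid_pair(fixed, series$data[, , , e], series$spacing_mm,
                          maxit = maxit),
      error = function(err) stopf("register_echoes_rigid: echo %d failed: %s",
                                  e, conditionMessage(err)))
    tfs[[e]] <- res$transform
    out[, , , e] <- resample_volume(series$data[, , , e], res$transform,
                                    series$spacing_mm)
  }
  aligned <- series
  aligned$data <- out
  list(series = aligned, transforms = tfs)
}

# Closed-form affine initializer: match intensity-weighted centroids and
# per-axis variances of the two images (diagonal A, no rotation).
affine_moments_init <- function(fixed, moving, spacing_mm, center) {
  wstat <- function(v) {
    pts <- world_grid(dim(v), spacing_mm)
    w <- pmax(as.vector(v), 0)
    s <- sum(w)
    if (s <= 0) return(list(c = center, v = rep(1, 3)))
    w <- w / s
    c_ <- colSums(pts * w)
    list(c = c_, v = pmax(colSums(sweep(pts, 2, c_)^2 * w), 1e-12))
  }
  mf <- wstat(fixed); mm <- wstat(moving)
  A <- diag(sqrt(mm$v / mf$v))
  b <- as.vector(A %*% (center - mf$c)) + mm$c - center
  c(as.vector(A - diag(3)), b)
}

# 12-parameter affine: x -> A x + b (mm coordinates about a center).
affine_transform_fun <- function(par, center) {
  A <- diag(3) + matrix(par[1:9], 3, 3)
  b <- par[10:12]
  function(pts) {
    ctr <- matrix(center, nrow(pts), 3, byrow = TRUE)
    sweep((pts - ctr) %*% t(A), 2, center + b, "+")
  }
}

#' Resample a subject map onto the atlas grid
#'
#' `identity` mode (the synthetic default) requires matching grids and
#' passes values through untouched. `affine` mode optimizes a
#' 12-parameter transform on MSE (2-level pyramid) and resamples
#' (linear for values, nearest for the mask). `plugin` mode delegates to
#' a caller-supplied function implementing the exchange contract
#' documented in the README.
#'
#' @param subject_map A `relaxation_map` (or a bare 3D array in affine /
#'   plugin modes).
#' @param atlas_reference 3D array defining the atlas grid (and the fixed
#'   image for affine optimization).
#' @param spacing_mm Atlas voxel spacing.
#' @param mode `"identity"`, `"affine"` or `"plugin"`.
#' @param plugin Function `(subject_map, atlas_reference, spacing_mm) ->
#'   list(map =, deformation_mm =)` used when `mode = "plugin"`.
#' @param maxit Optimizer cap for affine mode.
#' @return List: `map` (resampled `relaxation_map` or array) and
#'   `deformation_mm` (voxel-wise displacement, array of dim c(shape, 3);
#'   all zero in identity mode).
#' @export
register_to_atlas <- function(subject_map, atlas_reference, spacing_mm,
                              mode = c("identity", "affine", "plugin"),
                              plugin = NULL, maxit = 500L) {
  mode <- match.arg(mode)
  shp_ref <- dim(atlas_reference)
  map_is_obj <- inherits(subject_map, "relaxation_map")
  shp_sub <- if (map_is_obj) dim(subject_map$time_ms) else dim(subject_map)

  if (mode == "identity") {
    if (!identical(as.integer(shp_sub), as.integer(shp_ref))) {
      stopf("register_to_atlas: identity mode requires matching grids (%s vs %s)",
            paste(shp_sub, collapse = "x"), paste(shp_ref, collapse = "x"))
    }
    defo <- array(0, c(shp_ref, 3))
    return(list(map = subject_map, deformation_mm = defo))
  }

  if (mode == "plugin") {
    if (!is.function(plugin)) stopf("register_to_atlas: plugin mode requires a plugin function")
    res <- tryCatch(plugin(subject_map, atlas_reference, spacing_mm),
                    error = function(e) stopf("register_to_atlas: plugin failed: %s",
                                              conditionMessage(e)))
    return(res)
  }

  # affine mode
  moving <- if (map_is_obj) {
    v <- subject_map$time_ms; v[is.na(v)] <- 0; v
  } else subject_map
  center <- (shp_ref - 1) * spacing_mm / 2
  pts_cache <- new.env(parent = emptyenv())
  grid_pts <- function(shp, sp) {
    key <- paste(c(shp, sp), collapse = "_")
    if (is.null(pts_cache[[key]])) pts_cache[[key]] <- world_grid(shp, sp)
    pts_cache[[key]]
  }
  objective <- function(par, fx, mv, sp) {
    f <- affine_transform_fun(par, center)
    mse_metric(fx, resample_volume(mv, f, sp, out_shape = dim(fx),
                                   pts = grid_pts(dim(fx), sp)))
  }
  nf <- function(v) v / max(mean(abs(v)), 1e-12)
  # Axis-aligned moments initialization (intensity centroid + per-axis
  # variance matching) followed by Nelder-Mead refinement, coarse level
  # first. The init assumes no gross rotation between subject and atlas
  # (the pluggable deformable backend owns harder geometry); it avoids
  # the reflection ambiguity a full eigen-decomposition init would have
  # on near-symmetric images.
  par <- affine_moments_init(atlas_reference, moving, spacing_mm, center)
  lvls <- list(list(fx = downsample2(nf(atlas_reference)), mv = downsample2(nf(moving)),
                    sp = spacing_mm * 2),
               list(fx = nf(atlas_reference), mv = nf(moving), sp = spacing_mm))
  scales <- c(rep(0.02, 9), rep(0.5, 3))
  for (lv in lvls) {
    opt <- stats::optim(par, objective, fx = lv$fx, mv = lv$mv, sp = lv$sp,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12,
                                       parscale = scales))
    par <- opt$par
  }
  f <- affine_transform_fun(par, center)
  pts <- world_grid(shp_ref, spacing_mm)
  defo <- array(f(pts) - pts, c(shp_ref, 3))

  if (map_is_obj) {
    out <- subject_map
    rs <- function(a, interp) {
      a0 <- a; a0[is.na(a0)] <- 0
      resample_volume(a0, f, spacing_mm, out_shape = shp_ref, interp = interp)
    }
    out$time_ms <- rs(subject_map$time_ms, "linear")
    out$s0 <- rs(subject_map$s0, "linear")
    out$r_squared <- rs(subject_map$r_squared, "linear")
    out$mask <- array(rs(array(as.double(subject_map$mask), shp_sub), "nearest") > 0.5, shp_ref)
    out$converged <- array(rs(array(as.double(subject_map$converged), shp_sub), "nearest") > 0.5, shp_ref)
    list(map = out, deformation_mm = defo, parameters = par)
  } else {
    list(map = resample_volume(moving, f, spacing_mm, out_shape = shp_ref),
         deformation_mm = defo, parameters = par)
  }
}

#' Serialize / restore transforms as JSON
#'
#' @param tf A `rigid_transform` or affine parameter vector.
#' @param path Output path.
#' @return `path` (write) or the restored transform (read).
#' @export
write_transform_json <- function(tf, path) {
  if (inherits(tf, "rigid_transform")) {
    jsonlite::write_json(list(type = "rigid", rotation = tf$rotation,
                              translation = tf$translation, center = tf$center),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(type = "affine", parameters = as.vector(tf)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (j$type == "rigid") {
    rigid_transform(j$rotation, j$translation, j$center)
  } else {
    j$parameters
  }
}
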
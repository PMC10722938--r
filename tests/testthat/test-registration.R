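# Rigid echo alignment and atlas-space resampling.

test_that("rigid transform composed with its inverse is identity", {
  tf <- rigid_transform(rotation = c(0.1, -0.05, 0.2), translation = c(2, -1, 0.5),
                        center = c(8, 8, 8))
  inv <- invert_rigid(tf)
  pts <- withr::with_seed(1, matrix(runif(300, 0, 16), ncol = 3))
  back <- kneevbr:::transform_points(inv, kneevbr:::transform_points(tf, pts))
  expect_lt(mean(sqrt(rowSums((back - pts)^2))), 1e-6)
})

test_that("already-aligned echoes register to near-identity transforms", {
  atlas <- tiny_atlas(16L)
  tr <- generate_truth(atlas, seed = 1)
  es <- simulate_echo_series(tr, "T1rho", noise_sd = 0,
                             echo_times_ms = c(0, 10, 40))
  reg <- register_echoes_rigid(es)
  for (tf in reg$transforms) {
    expect_lt(max(abs(tf$translation)), 0.05)
  }
})

test_that("a known 2-voxel shift is recovered within a quarter voxel", {
  atlas <- tiny_atlas(24L)
  tr <- generate_truth(atlas, seed = 2)
  vol <- tr$t1rho_ms
  dat <- array(0, c(dim(vol), 3))
  dat[, , , 1] <- vol
  shifted <- array(0, dim(vol))
  shifted[, 3:dim(vol)[2], ] <- vol[, 1:(dim(vol)[2] - 2), ]
  dat[, , , 2] <- shifted * exp(-10 / 40)
  dat[, , , 3] <- vol * exp(-40 / 40)
  es <- echo_series(dat, c(0, 10, 40), spacing_mm = c(1, 1, 1))
  reg <- register_echoes_rigid(es)
  expect_lt(abs(reg$transforms[[2]]$translation[2] - 2), 0.25)
  expect_lt(max(abs(reg$transforms[[2]]$translation[c(1, 3)])), 0.25)
  # inverse-consistency: the aligned echo matches the reference echo
  msk <- atlas$labels > 0
  aligned <- reg$series$data[, , , 2] / exp(-10 / 40)
  rng <- diff(range(vol[msk]))
  inner <- msk & aligned > 0
  expect_lt(mean(abs(aligned[inner] - vol[inner])) / rng, 0.02)
})

test_that("single-echo input violates the registration precondition", {
  fake <- structure(list(data = array(1, c(4, 4, 4, 1)), echo_times_ms = 0,
                         spacing_mm = c(1, 1, 1)), class = "echo_series")
  expect_error(register_echoes_rigid(fake), ">= 2 echoes")
})

test_that("identity atlas mode is a bit-exact passthrough and checks grids", {
  atlas <- tiny_atlas(16L)
  tr <- generate_truth(atlas, seed = 3)
  es <- simulate_echo_series(tr, "T1rho", seed = 4)
  map <- fit_monoexponential(es, mask = array(atlas$labels > 0, dim(atlas$labels)))
  out <- register_to_atlas(map, array(0, dim(atlas$labels)), atlas$spacing_mm,
                           mode = "identity")
  expect_identical(out$map$time_ms, map$time_ms)
  expect_identical(out$map$mask, map$mask)
  expect_true(all(out$deformation_mm == 0))
  expect_error(register_to_atlas(map, array(0, c(8, 8, 8)), c(1, 1, 1),
                                 mode = "identity"), "matching grids")
})

test_that("a known affine (scale 1.05, shift 1.5 mm) is recovered", {
  atlas <- generate_atlas(phantom_spec())
  tr <- generate_truth(atlas, seed = 5)
  vol <- tr$t1rho_ms
  ctr <- (dim(vol) - 1) / 2
  par_true <- c(c(0.05, 0, 0, 0, 0.05, 0, 0, 0, 0.05), c(1.5, 1.5, 1.5))
  f_true <- kneevbr:::affine_transform_fun(par_true, ctr)
  warped <- resample_volume(vol, f_true, c(1, 1, 1))
  reg <- register_to_atlas(warped, vol, c(1, 1, 1), mode = "affine")
  f_rec <- kneevbr:::affine_transform_fun(reg$parameters, ctr)
  msk <- atlas$labels > 0
  pts <- kneevbr:::world_grid(dim(vol), c(1, 1, 1))[as.vector(msk), ]
  err <- sqrt(rowSums((f_true(f_rec(pts)) - pts)^2))
  expect_lt(mean(err), 0.5)
})

test_that("compartment masks survive warping as 6 nonempty labels", {
  atlas <- generate_atlas(phantom_spec())
  ctr <- (dim(atlas$labels) - 1) / 2
  f <- kneevbr:::affine_transform_fun(c(rep(0.02, 1), rep(0, 8), 0.8, -0.5, 0.3), ctr)
  warped <- resample_volume(array(as.double(atlas$labels), dim(atlas$labels)),
                            f, c(1, 1, 1), interp = "nearest")
  expect_identical(sort(unique(as.vector(warped[warped > 0]))), as.double(1:6))
})

test_that("plugin mode delegates and surfaces failures", {
  atlas <- tiny_atlas(16L)
  ref <- array(0, dim(atlas$labels))
  ok_plugin <- function(map, ref, sp) list(map = map, deformation_mm = array(0, c(dim(ref), 3)))
  out <- register_to_atlas(ref, ref, c(1, 1, 1), mode = "plugin", plugin = ok_plugin)
  expect_identical(out$map, ref)
  bad_plugin <- function(map, ref, sp) stop("backend exploded")
  expect_error(register_to_atlas(ref, ref, c(1, 1, 1), mode = "plugin",
                                 plugin = bad_plugin), "plugin failed.*backend exploded")
})

test_that("transform JSON round-trips", {
  tf <- rigid_transform(c(0.02, 0, -0.01), c(1, 2, 3), c(8, 8, 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tf, path)
  tf2 <- read_transform_json(path)
  expect_equal(tf2$R, tf$R, tolerance = 1e-12)
  expect_equal(tf2$translation, tf$translation)
})
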
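# Voxel-wise SPM statistics: stacking, group differences, partial
# correlations, clustering, compartment summaries.

test_that("cohort stacking applies the coverage rule", {
  rec <- basic_records(10)
  vals <- matrix(40, 10, 5)
  st <- values_stack(vals, rec)
  expect_equal(sum(st$common_mask), 5)

  # one subject missing one voxel: dropped at fraction 1, kept at 0.5
  grid <- c(5L, 1L, 1L)
  maps <- lapply(1:10, function(i) {
    m <- kneevbr:::new_relaxation_map(grid, c(1, 1, 1), "T1rho", c(1, 200))
    m$time_ms <- array(40, grid)
    msk <- array(TRUE, grid)
    if (i == 1) msk[3, 1, 1] <- FALSE
    m$mask <- msk; m$converged <- msk
    m
  })
  st1 <- build_cohort_stack(maps, rec, min_coverage_fraction = 1,
                            covariates = character(0))
  expect_equal(sum(st1$common_mask), 4)
  st2 <- build_cohort_stack(maps, rec, min_coverage_fraction = 0.5,
                            covariates = character(0))
  expect_equal(sum(st2$common_mask), 5)
})

test_that("stacking rejects mismatched grids and tiny cohorts", {
  rec <- basic_records(10)
  maps <- lapply(1:10, function(i) {
    m <- kneevbr:::new_relaxation_map(c(4L, 1L, 1L), c(1, 1, 1), "T1rho", c(1, 200))
    m$time_ms <- array(40, c(4, 1, 1)); m$mask <- array(TRUE, c(4, 1, 1))
    m$converged <- m$mask
    m
  })
  maps2 <- maps
  maps2[[3]]$time_ms <- array(40, c(5, 1, 1))
  expect_error(build_cohort_stack(maps2, rec, covariates = character(0)),
               "different grids")
  expect_error(values_stack(matrix(40, 3, 4), basic_records(3)), "unidentifiable")
})

test_that("identical groups with zero noise give null effect and degenerate p", {
  rec <- basic_records(12)
  vals <- matrix(rep(c(40, 42, 44, 40), each = 12), 12, 4)
  st <- values_stack(vals, rec)
  spm <- voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                    covariates = character(0))
  expect_true(all(abs(spm$effect) < 1e-10))
  expect_true(all(spm$p == 1))
  expect_true(all(spm$degenerate))
})

test_that("adjusted effect recovers the -10% convention (with-group higher)", {
  n <- 400
  rec <- basic_records(n)
  grp <- rec$grade_patellar_tendinosis
  withr::with_seed(6, {
    vals <- matrix(40 + 4 * grp, n, 6) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  })
  st <- values_stack(vals, rec)
  spm <- voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                    covariates = character(0))
  expect_equal(mean(spm$effect), -10, tolerance = 0.05)
  expect_true(all(spm$p < 1e-10))
})

test_that("a duplicated group column triggers a rank-deficiency error", {
  rec <- basic_records(20)
  rec$dup <- as.numeric(rec$grade_patellar_tendinosis)
  st <- values_stack(matrix(rnorm(20 * 3, 40), 20, 3), rec)
  expect_error(voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                          covariates = "dup"),
               "rank deficient.*dup")
})

test_that("single-level covariates are dropped with a message", {
  rec <- basic_records(30)
  rec$site <- "siteA"
  st <- values_stack(matrix(rnorm(30 * 3, 40), 30, 3), rec)
  expect_message(
    spm <- voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                      covariates = c("age", "site")),
    "single level")
  expect_length(spm$p, 3)
})

test_that("partial correlation reduces to plain Pearson with no covariates", {
  n <- 30
  rec <- basic_records(n)
  withr::with_seed(8, {
    vals <- matrix(rnorm(n * 10, 40, 3), n, 10)
    outc <- rnorm(n)
  })
  st <- values_stack(vals, rec)
  spm <- voxelwise_partial_correlation(st, outc, covariates = character(0))
  plain <- apply(vals, 2, function(v) cor(v, outc))
  expect_lt(max(abs(spm$effect - plain)), 1e-12)
  plain_p <- apply(vals, 2, function(v) cor.test(v, outc)$p.value)
  expect_lt(max(abs(spm$p - plain_p)), 1e-12)
})

test_that("self-correlation yields r = 1", {
  n <- 20
  rec <- basic_records(n)
  withr::with_seed(9, vals <- matrix(rnorm(n * 4, 40, 3), n, 4))
  st <- values_stack(vals, rec)
  spm <- voxelwise_partial_correlation(st, vals[, 2], covariates = character(0))
  expect_equal(spm$effect[2], 1, tolerance = 1e-12)
})

test_that("partial r matches the brute-force double-residualization oracle", {
  # oracle: residualize both variables via lm() and correlate residuals
  withr::with_seed(10, {
    for (rep_i in 1:10) {
      n <- 8
      rec <- basic_records(n, seed = rep_i)
      vals <- matrix(rnorm(n * 6, 40, 3), n, 6)
      outc <- rnorm(n)
      st <- values_stack(vals, rec)
      spm <- voxelwise_partial_correlation(st, outc, covariates = "age")
      oracle <- apply(vals, 2, function(v) {
        cor(resid(lm(v ~ rec$age)), resid(lm(outc ~ rec$age)))
      })
      expect_lt(max(abs(spm$effect - oracle)), 1e-10)
    }
  })
})

test_that("degrees-of-freedom preconditions are enforced", {
  rec <- basic_records(4)
  st <- values_stack(matrix(rnorm(4 * 3, 40), 4, 3), rec)
  expect_error(voxelwise_partial_correlation(st, rnorm(4),
                                             covariates = c("age", "bmi")),
               "n - k - 2")
  expect_error(voxelwise_partial_correlation(st, rep(1, 4), covariates = character(0)),
               "zero variance")
})

test_that("thresholding and clustering follow the construction", {
  rec <- basic_records(10)
  grid <- c(8L, 8L, 1L)
  V <- prod(grid)
  vals <- matrix(40, 10, V)
  st <- values_stack(vals, rec, grid = grid)
  spm <- kneevbr:::new_spm_result(st, rep(0, V), rep(1, V), "difference", character(0))
  out <- threshold_and_cluster(spm)
  expect_equal(sum(out$sig_mask), 0)
  expect_equal(nrow(out$clusters), 0)

  # two disjoint 3-voxel blobs at p = 0.01
  p <- rep(1, V)
  blob1 <- c(1, 2, 3)                     # linear idx: column 1 rows 1:3
  blob2 <- c(41, 42, 43)                  # column 6 rows 1:3
  p[c(blob1, blob2)] <- 0.01
  spm2 <- kneevbr:::new_spm_result(st, rep(0, V), p, "difference", character(0))
  out2 <- threshold_and_cluster(spm2)
  expect_equal(nrow(out2$clusters), 2)
  expect_equal(out2$clusters$size, c(3, 3))
  expect_equal(out2$clusters$mean_p, c(0.01, 0.01))
  # min_cluster_voxels removes small components from the mask
  out2b <- threshold_and_cluster(spm2, min_cluster_voxels = 4)
  expect_equal(sum(out2b$sig_mask), 0)
})

test_that("diagonal voxels merge at 26- but not 6-connectivity", {
  rec <- basic_records(10)
  grid <- c(4L, 4L, 4L)
  V <- prod(grid)
  st <- values_stack(matrix(40, 10, V), rec, grid = grid)
  p <- rep(1, V)
  i1 <- 1L                                         # (1,1,1)
  i2 <- 1L + 1L + 4L + 16L                         # (2,2,2): diagonal neighbor
  p[c(i1, i2)] <- 0.01
  spm <- kneevbr:::new_spm_result(st, rep(0, V), p, "difference", character(0))
  expect_equal(nrow(threshold_and_cluster(spm, connectivity = 26)$clusters), 1)
  expect_equal(nrow(threshold_and_cluster(spm, connectivity = 6)$clusters), 2)
})

test_that("compartment summaries match a brute-force voxel loop", {
  atlas <- tiny_atlas(16L)
  rec <- basic_records(10)
  vox <- which(atlas$labels > 0)
  V <- length(vox)
  vals <- matrix(40, 10, V)
  maps <- lapply(1:10, function(i) {
    m <- kneevbr:::new_relaxation_map(dim(atlas$labels), c(1, 1, 1), "T1rho", c(1, 200))
    vol <- array(NA_real_, dim(atlas$labels)); vol[vox] <- 40
    m$time_ms <- vol
    msk <- array(FALSE, dim(atlas$labels)); msk[vox] <- TRUE
    m$mask <- msk; m$converged <- msk
    m
  })
  st <- build_cohort_stack(maps, rec, covariates = character(0))
  withr::with_seed(11, {
    eff <- rnorm(V, 0, 5)
    p <- runif(V)
  })
  spm <- kneevbr:::new_spm_result(st, eff, p, "difference", character(0))
  spm <- threshold_and_cluster(spm)
  summ <- summarize_by_compartment(spm, atlas)
  # loop oracle
  eff_vol <- array(NA_real_, dim(atlas$labels)); eff_vol[st$voxel_index] <- eff
  p_vol <- array(NA_real_, dim(atlas$labels)); p_vol[st$voxel_index] <- p
  for (i in seq_len(nrow(summ))) {
    lab <- kneevbr:::COMPARTMENT_LABELS[[summ$compartment[i]]]
    cvox <- which(atlas$labels == lab)
    sig <- cvox[!is.na(p_vol[cvox]) & p_vol[cvox] <= 0.05]
    expect_equal(summ$psv_pct[i], 100 * length(sig) / length(cvox), tolerance = 1e-12)
    if (length(sig)) {
      expect_equal(summ$apd_pct[i], mean(eff_vol[sig]), tolerance = 1e-12)
      expect_equal(summ$avg_p[i], mean(p_vol[sig]), tolerance = 1e-12)
    } else {
      expect_true(is.na(summ$apd_pct[i]))
    }
  }
})

test_that("PSV ratio and constant APD behave as defined", {
  atlas <- tiny_atlas(16L)   # each compartment has 392 voxels
  rec <- basic_records(10)
  vox <- which(atlas$labels > 0)
  maps <- lapply(1:10, function(i) {
    m <- kneevbr:::new_relaxation_map(dim(atlas$labels), c(1, 1, 1), "T1rho", c(1, 200))
    vol <- array(NA_real_, dim(atlas$labels)); vol[vox] <- 40
    m$time_ms <- vol
    msk <- array(FALSE, dim(atlas$labels)); msk[vox] <- TRUE
    m$mask <- msk; m$converged <- msk
    m
  })
  st <- build_cohort_stack(maps, rec, covariates = character(0))
  V <- length(st$voxel_index)
  p <- rep(1, V); eff <- rep(0, V)
  mt_lin <- which(atlas$labels == 4L)
  sel <- match(mt_lin[seq_len(39L)], st$voxel_index)  # within rounding of 10%
  p[sel] <- 0.01; eff[sel] <- -12
  spm <- threshold_and_cluster(
    kneevbr:::new_spm_result(st, eff, p, "difference", character(0)))
  summ <- summarize_by_compartment(spm, atlas)
  mt <- summ[summ$compartment == "MT", ]
  expect_equal(mt$psv_pct, 100 * 39 / 392)
  expect_equal(mt$apd_pct, -12)
})

test_that("neglog p display transform matches closed forms", {
  rec <- basic_records(10)
  st <- values_stack(matrix(40, 10, 3), rec)
  spm <- kneevbr:::new_spm_result(st, rep(0, 3), c(1, 0.05, 0.01), "difference",
                                  character(0))
  nl <- neglog_p_map(spm)
  expect_equal(nl[1, 1, 1], 0)
  expect_equal(nl[2, 1, 1], 13.0103, tolerance = 1e-4)
  expect_equal(nl[3, 1, 1], 20)
  expect_true(all(is.na(nl[!spm$common_mask])) || sum(!spm$common_mask) == 0)
})

test_that("site confounding inflates PSV unless adjusted", {
  n <- 80
  withr::with_seed(12, {
    site <- sample(c("A", "B"), n, TRUE)
    grade <- ifelse(site == "B", rbinom(n, 1, 0.8), rbinom(n, 1, 0.2))
    rec <- data.frame(subject_id = sprintf("s%03d", 1:n),
                      age = rnorm(n, 19, 1), sex = sample(c("M", "F"), n, TRUE),
                      bmi = rnorm(n, 24, 2), site = site,
                      grade_patellar_tendinosis = grade,
                      stringsAsFactors = FALSE)
    V <- 300
    vals <- matrix(40 + 3 * (site == "B"), n, V) + matrix(rnorm(n * V), n, V)
  })
  st <- values_stack(vals, rec)
  psv_unadj <- mean(voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                               covariates = character(0))$p <= 0.05)
  psv_adj <- mean(voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                             covariates = "site")$p <= 0.05)
  expect_gt(psv_unadj, 0.3)
  expect_lt(psv_adj, 0.15)
})

test_that("partial r recovers the sign of an outcome slope", {
  n <- 60
  withr::with_seed(13, {
    rec <- basic_records(n)
    V <- 50
    vals <- matrix(rnorm(n * V, 40, 2), n, V)
    outc <- 80 - 2 * rowMeans(vals[, 1:3]) + rnorm(n, 0, 1)
  })
  st <- values_stack(vals, rec)
  spm <- voxelwise_partial_correlation(st, outc, covariates = c("age", "bmi"))
  expect_true(all(spm$effect[1:3] < 0))
  expect_true(all(spm$p[1:3] <= 0.05))
})

test_that("permutation p agrees with parametric p on Gaussian data", {
  n <- 40
  withr::with_seed(14, {
    rec <- basic_records(n)
    vals <- matrix(rnorm(n * 200, 40, 2), n, 200)
  })
  st <- values_stack(vals, rec)
  par_p <- voxelwise_group_difference(st, "grade_patellar_tendinosis",
                                      covariates = c("age"))$p
  perm_p <- voxelwise_group_permutation(st, "grade_patellar_tendinosis",
                                        covariates = c("age"),
                                        n_perm = 499, seed = 15)$p
  expect_gt(mean(abs(par_p - perm_p) <= 0.05), 0.95)
})

test_that("contrast battery handles empty lists and unknown fields", {
  rec <- basic_records(10)
  st <- values_stack(matrix(rnorm(10 * 4, 40), 10, 4), rec)
  atlas <- tiny_atlas(16L)
  bat <- run_contrast_battery(list(T1rho = st), list(), atlas)
  expect_equal(nrow(bat$table), 0)
  expect_named(bat$table, c("modality", "contrast", "kind", "compartment",
                            "psv_pct", "effect", "avg_p", "n_sig_voxels"))
  expect_error(
    run_contrast_battery(list(T1rho = st),
                         list(list(kind = "difference", variable = "grade_unknown")),
                         atlas),
    "unknown field")
})
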
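acq60 <- acquisition_spec(n_volumes = 60)

test_that("inactive-unit filter drops exactly the all-zero rows", {
  m <- matrix(rnorm(5 * 40), 5, 40)
  m[3, ] <- 0
  f <- feature_series(m, paste0("l", 1:5))
  out <- drop_inactive_units(f)
  expect_equal(nrow(out$values), 4)
  expect_equal(out$unit_layer, paste0("l", c(1, 2, 4, 5)))
  expect_equal(attr(out, "n_dropped"), 1)

  # all rows somewhere nonzero: unchanged
  f2 <- feature_series(matrix(rnorm(12), 3, 4), rep("a", 3))
  expect_equal(drop_inactive_units(f2)$values, f2$values)

  # random sparse matrix: survivor count equals brute-force count
  withr::with_seed(5, {
    sp <- matrix(rbinom(300, 1, 0.1) * rnorm(300), 30, 10)
  })
  fs <- feature_series(sp, rep("a", 30))
  expect_equal(nrow(drop_inactive_units(fs)$values),
               sum(apply(sp, 1, function(r) any(r != 0))))

  # union over sessions: unit active in any session survives in all
  s1 <- feature_series(rbind(c(0, 0, 0), c(1, 0, 0)), c("a", "a"))
  s2 <- feature_series(rbind(c(0, 1, 0), c(0, 0, 0)), c("a", "a"))
  out2 <- drop_inactive_units(list(s1, s2))
  expect_equal(nrow(out2[[1]]$values), 2)

  f0 <- feature_series(matrix(0, 2, 5), c("a", "a"))
  expect_error(drop_inactive_units(f0), "inactive")
})

test_that("dual z-scoring matches the closed form and is idempotent", {
  # row (1,2,3) z-scored over time with sample sd gives (-1, 0, 1)
  m <- rbind(c(1, 2, 3), c(5, 1, 9))
  z <- voxelenc:::zscore_rows(m)
  expect_equal(z[1, ], c(-1, 0, 1))

  withr::with_seed(3, r <- matrix(rnorm(300 * 600), 300, 600))
  zd <- zscore_dual(r)
  # the trailing feature pass standardizes every time point exactly ...
  expect_equal(colMeans(zd), rep(0, 600), tolerance = 1e-8)
  expect_equal(apply(zd, 2, sd), rep(1, 600), tolerance = 1e-8)
  # ... and perturbs the temporal standardization only mildly, so one more
  # temporal pass is close to a no-op (exact idempotence is impossible: the
  # two passes do not commute)
  expect_lt(max(abs(voxelenc:::zscore_rows(zd) - zd)), 0.05)
  expect_gt(min(diag(cor(t(voxelenc:::zscore_rows(zd)), t(zd)))), 0.999)

  expect_error(zscore_dual(rbind(rep(2, 5), rnorm(5))), "constant")
  # single-unit input skips the (undefined) feature pass
  one <- matrix(c(1, 2, 3), 1)
  expect_equal(zscore_dual(one), matrix(c(-1, 0, 1), 1))
})

test_that("hemodynamic kernel peaks at 5 s and convolution is linear", {
  k <- hrf_kernel(hrf_spec(), rate_hz = 45)
  t_axis <- seq(0, 32, by = 1 / 45)
  expect_equal(t_axis[which.max(k)], 5, tolerance = 1 / 45)
  expect_error(hrf_spec(peak_delay = -1), "positive")

  # impulse convolution returns the kernel itself
  x <- matrix(0, 1, 200); x[1, 1] <- 1
  got <- voxelenc:::convolve_rows(x, k)
  expect_equal(got[1, ], k[1:200], tolerance = 1e-10)

  # linearity
  withr::with_seed(8, { a <- rnorm(100); b <- rnorm(100) })
  ca <- voxelenc:::convolve_rows(rbind(a), k)
  cb <- voxelenc:::convolve_rows(rbind(b), k)
  cab <- voxelenc:::convolve_rows(rbind(2 * a - 3 * b), k)
  expect_lt(max(abs(cab - (2 * ca - 3 * cb))), 1e-10)
})

test_that("TR resampling is exact on affine signals and counts volumes by floor", {
  # 7-minute session at TR 0.987 s: floor(420 / 0.987) = 425 volumes
  expect_identical(n_volumes_for(18900, 45, 0.987), 425L)

  cst <- matrix(3, 1, 500)
  out <- resample_to_tr(cst, acquisition_spec(n_volumes = 10))
  expect_equal(out, matrix(3, 1, 10))

  # linear ramp r(t) = t resampled at k * TR is exactly k * TR
  tt <- 1000
  ramp <- matrix((0:(tt - 1)) / 45, 1)
  acq <- acquisition_spec(n_volumes = 20)
  got <- resample_to_tr(ramp, acq)
  expect_equal(got[1, ], (0:19) * 0.987, tolerance = 1e-12)

  expect_error(resample_to_tr(matrix(1, 1, 10), acquisition_spec(n_volumes = 50)),
               "beyond")
})

test_that("DCT high-pass removes slow components and keeps fast ones", {
  nvol <- 300
  acq <- acquisition_spec(n_volumes = nvol)
  tt <- (0:(nvol - 1)) * acq$tr_seconds

  expect_equal(highpass_dct(matrix(5, 1, nvol), acq), matrix(0, 1, nvol),
               tolerance = 1e-10)
  # a 256-s cosine on the DCT grid (component k = 3 of a 384-volume run at
  # TR 1 s has period 2*384/3 = 256 s) is removed exactly
  acq1 <- acquisition_spec(tr_seconds = 1, n_volumes = 384)
  comp256 <- matrix(cos(pi * 3 * (2 * (1:384) - 1) / (2 * 384)), 1)
  expect_lt(max(abs(highpass_dct(comp256, acq1))), 1e-6)
  # an off-grid slow cosine is still strongly attenuated
  slow <- matrix(cos(2 * pi * tt / 256 + 0.7), 1)
  expect_lt(var(drop(highpass_dct(slow, acq))) / var(drop(slow)), 0.05)
  fast <- matrix(cos(2 * pi * tt / 20), 1)
  expect_gt(cor(drop(highpass_dct(fast, acq)), drop(fast)), 0.999)

  # output orthogonal to the whole basis
  withr::with_seed(2, x <- matrix(rnorm(3 * nvol), 3))
  hp <- highpass_dct(x, acq)
  basis <- dct_basis(nvol, acq$tr_seconds, acq$highpass_cutoff_seconds)
  expect_lt(max(abs(hp %*% basis)), 1e-8)
  expect_error(dct_basis(100, 1, 1.5), "2 \\* TR")
})

test_that("assembled designs are standardized and reproducible stage by stage", {
  co <- small_designs()
  d <- co$designs$all[[1]]
  expect_equal(rowMeans(d$values), rep(0, nrow(d$values)), tolerance = 1e-8)
  expect_equal(apply(d$values, 1, sd), rep(1, nrow(d$values)), tolerance = 1e-8)

  # stage-order audit: recompose from the individual stage operations
  feats <- co$features
  fl <- drop_inactive_units(feats, also_constant = TRUE)
  kern <- hrf_kernel(co$hrf, 45)
  manual <- voxelenc:::zscore_rows(
    highpass_dct(
      resample_to_tr(
        voxelenc:::convolve_rows(zscore_dual(fl[[1]]$values), kern),
        co$acq, 45),
      co$acq))
  expect_equal(manual, d$values, tolerance = 1e-10, ignore_attr = TRUE)

  # layer selection restricts the labels
  d1 <- co$designs$conv1[[1]]
  expect_true(all(d1$predictor_layer == "conv1"))
  expect_setequal(unique(d$predictor_layer),
                  c("conv1", "conv2", "conv3", "lstm", "layer4"))
  expect_error(assemble_design(feats, character(0)), "empty")
  expect_error(assemble_design(feats, "conv9"), "unknown")
})

test_that("motion residualization is an exact orthogonal projection", {
  nvol <- 120
  acq <- acquisition_spec(n_volumes = nvol)
  motion <- simulate_motion(nvol, seed = 4)
  # a voxel equal to one motion regressor is annihilated
  v <- matrix(motion[3, ], 1)
  expect_lt(max(abs(motion_residualize(v, motion, acq))), 1e-8)

  withr::with_seed(6, vox <- matrix(rnorm(4 * nvol), 4))
  res <- motion_residualize(vox, motion, acq)
  regs <- cbind(dct_basis(nvol, acq$tr_seconds, 128), t(motion))
  expect_lt(max(abs(res %*% regs)), 1e-6)
  expect_true(all(apply(res, 1, var) <= apply(vox, 1, var)))

  # a voxel already orthogonal to all regressors is unchanged
  q <- qr.Q(qr(regs))
  vperp <- vox - (vox %*% q) %*% t(q)
  expect_equal(motion_residualize(vperp, motion, acq), vperp, tolerance = 1e-8)

  expect_error(motion_residualize(vox, rbind(motion, motion[1, ]), acq), "rank")
})

test_that("pixel control design exposes screen pixels as predictors", {
  tt <- 70 * 45 / 45 # frames for ~63 volumes at 45 Hz handled below
  nf <- 2800
  frames <- array(0, c(84, 84, nf))
  withr::with_seed(11, blink <- rbinom(nf, 1, 0.5) * 255)
  frames[40, 40, ] <- blink
  seq1 <- frame_sequence(frames)
  acq <- acquisition_spec(n_volumes = 60)
  d <- pixel_control_design(seq1, acq, block_factor = 1)
  expect_equal(nrow(d$values), 1) # single blinking pixel survives
  expect_true(all(d$predictor_layer == "pixel"))

  expect_error(pixel_control_design(frame_sequence(array(7, c(84, 84, nf))), acq),
               "inactive")

  withr::with_seed(12, rnd <- array(runif(84 * 84 * nf, 0, 255), c(84, 84, nf)))
  d4 <- pixel_control_design(frame_sequence(rnd), acq, block_factor = 4)
  expect_equal(nrow(d4$values), 21 * 21)
})

test_that("motor control design builds one indicator per pressed button", {
  nf <- 2800
  acq <- acquisition_spec(n_volumes = 60)
  withr::with_seed(3, acts <- sample(c(0L, 2L), nf, replace = TRUE))
  d <- motor_control_design(acts, acq)
  expect_equal(nrow(d$values), 1)
  expect_error(motor_control_design(rep(0L, nf), acq), "press")
  expect_error(motor_control_design(c(acts[-1], 9L), acq), "unknown")

  # indicator predictor equals the composed stage pipeline on the raw train
  withr::with_seed(4, acts2 <- sample(0:3, nf, replace = TRUE, prob = c(.7, .1, .1, .1)))
  d2 <- motor_control_design(acts2, acq)
  kern <- hrf_kernel(hrf_spec(), 45)
  ind <- t(vapply(1:3, function(cd) as.numeric(acts2 == cd), numeric(nf)))
  manual <- voxelenc:::zscore_rows(
    highpass_dct(resample_to_tr(voxelenc:::convolve_rows(zscore_dual(ind), kern),
                                acq, 45), acq))
  expect_equal(d2$values, manual, tolerance = 1e-10, ignore_attr = TRUE)
})
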
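# Phantom and cohort generators: reproducibility, calibration, recovery.

test_that("zero design fraction leaves only Gaussian-tail leakage above -700 HU", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(40, 56, 56), seed = 61,
                                      design_fibrotic_fraction = 0))
  # closed form: upper tail of N(-850, 40) beyond -700
  leak <- pnorm((-700 - (-850)) / 40, lower.tail = FALSE)
  expect_lt(abs(ph$truth$realized_fibrotic_fraction - leak), 0.001)
})

test_that("generation is bit-identical under the same seed", {
  s <- phantom_spec(seed = 62, design_fibrotic_fraction = 0.3)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth, b$truth)
  co1 <- generate_cohort(cohort_spec(n = 50, seed = 63))
  co2 <- generate_cohort(cohort_spec(n = 50, seed = 63))
  expect_identical(co1, co2)
})

test_that("the realized fraction tracks the design fraction", {
  # ~1e5 lung voxels; binomial + tail-exchange error well under 0.02
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 96, 96), seed = 64,
                                      design_fibrotic_fraction = 0.41))
  expect_gt(ph$truth$lung_voxel_count, 5e4)
  expect_lt(abs(ph$truth$realized_fibrotic_fraction - 0.41), 0.02)
})

test_that("spatial patterns shift density where they claim to", {
  base <- phantom_spec(grid_shape = c(32, 48, 48), seed = 65,
                       design_fibrotic_fraction = 0.3, pattern = "basal")
  ph <- generate_phantom(base)
  prof <- slice_profile(ph$volume, ph$truth$lung_mask)
  ok <- !is.na(prof$fibrosis_pct)
  lower <- prof$fibrosis_pct[ok][seq_len(sum(ok) %/% 3)]          # lung base
  upper <- rev(prof$fibrosis_pct[ok])[seq_len(sum(ok) %/% 3)]     # lung apex
  expect_gt(mean(lower), mean(upper))
})

test_that("invalid phantom geometry is refused", {
  expect_error(phantom_spec(grid_shape = c(20, 20, 20),
                            lung_geometry = list(
                              list(centre = c(10, 10, 10), radii = c(30, 5, 5)),
                              list(centre = c(10, 10, 15), radii = c(5, 5, 4)))),
               "outside the grid")
  expect_error(phantom_spec(design_fibrotic_fraction = 1.2), "\\[0, 1\\]")
})

test_that("ground-truth scoring and the pipeline agree on phantoms", {
  for (seed in c(71, 72)) {
    ph <- small_phantom(seed = seed, fraction = 0.08 * (seed - 70))
    # with the generator's own mask the score equals the realized fraction
    res_truth <- cam_score(ph$volume, ph$truth$lung_mask)
    expect_equal(res_truth$fibrosis_pct,
                 100 * ph$truth$realized_fibrotic_fraction)
    # with the pipeline's segmentation it differs only by edge voxels
    res_seg <- cam_score(ph$volume, segment_lungs(ph$volume))
    expect_lt(abs(res_seg$fibrosis_pct - res_truth$fibrosis_pct), 0.5)
  }
})

test_that("a 126-patient cohort satisfies every field invariant", {
  co <- generate_cohort(cohort_spec(n = 126, seed = 73))
  expect_equal(nrow(co), 126)
  expect_true(validate_cohort(co))
  expect_setequal(levels(co$sex), c("F", "M"))
  expect_setequal(levels(co$subtype), c("dcSSc", "lcSSc"))
  expect_type(co$anti_topo_I, "logical")
  expect_true(all(co$mrss == round(co$mrss)))
})

test_that("uncorrelated targets generate near-zero sample correlations", {
  marg <- default_marginals()
  spec <- cohort_spec(n = 5000, marginals = marg,
                      correlation_targets = diag(length(marg)) |>
                        (\(R) {dimnames(R) <- list(names(marg), names(marg)); R})(),
                      seed = 74)
  co <- generate_cohort(spec)
  num <- co[vapply(co, is.numeric, logical(1))]
  C <- cor(as.matrix(num))
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("pairwise correlation targets are recovered at n = 5000", {
  for (rho in c(0.3, 0.7)) {
    marg <- default_marginals()
    R <- diag(length(marg))
    dimnames(R) <- list(names(marg), names(marg))
    R["cam_fibrosis_pct", "covr_total"] <- rho
    R["covr_total", "cam_fibrosis_pct"] <- rho
    co <- generate_cohort(cohort_spec(n = 5000, marginals = marg,
                                      correlation_targets = R, seed = 75))
    r_hat <- cor(co$cam_fibrosis_pct, co$covr_total)
    expect_lt(abs(r_hat - rho), 0.03)
  }
})

test_that("clamping biases each marginal mean by at most 5% of its SD", {
  co <- generate_cohort(cohort_spec(n = 1e5, seed = 76))
  marg <- default_marginals()
  for (v in names(marg)) {
    m <- marg[[v]]
    if (!is.null(m$p)) next
    expect_lt(abs(mean(co[[v]]) - m$mean), 0.05 * m$sd + 3 * m$sd / sqrt(1e5))
  }
})

test_that("binary prevalences match their specification", {
  co <- generate_cohort(cohort_spec(n = 2e4, seed = 77))
  expect_lt(abs(mean(co$sex == "F") - 0.837), 0.01)
  expect_lt(abs(mean(co$anti_topo_I) - 0.325), 0.01)
  expect_lt(abs(mean(co$subtype == "dcSSc") - 55 / 126), 0.01)
})

test_that("regression on a wide-bound cohort recovers the implied coefficients", {
  # wide bounds disable clamping, so the latent covariance fixes the truth
  marg <- default_marginals()
  for (v in names(marg)) {
    if (is.null(marg[[v]]$p)) {
      marg[[v]]$min <- -1e6; marg[[v]]$max <- 1e6
    }
  }
  marg$mrss$integer <- FALSE
  spec <- cohort_spec(n = 5000, marginals = marg, seed = 78)
  co <- generate_cohort(spec)
  R <- attr(co, "effective_correlation")
  covs <- c("covr_total", "fvc_pct", "dlco_pct", "haq_di", "borg")
  beta_z <- solve(R[covs, covs], R[covs, "cam_fibrosis_pct"])
  sds <- vapply(covs, function(v) marg[[v]]$sd, numeric(1))
  beta_true <- beta_z * marg$cam_fibrosis_pct$sd / sds
  fit <- fit_multivariate(co, "cam_fibrosis_pct", covs)
  expect_true(all(abs(fit$coefficients$coefficient - beta_true) <
                    3 * fit$coefficients$std_error))
})

test_that("an unrepairable correlation specification is refused", {
  marg <- default_marginals()
  R <- default_correlation_targets(names(marg))
  R[1, 2] <- 0.5   # asymmetric
  expect_error(cohort_spec(marginals = marg, correlation_targets = R),
               "symmetric")
})
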
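# Photon transport engine: sampling primitives, ballistic limits, energy
# bookkeeping, determinism, spatial averaging, batch standard errors.

test_that("free path sampling has the exponential mean in micrometers", {
  set.seed(1)
  s <- sample_free_path(1e6, 1500)
  expect_equal(mean(s), 1 / (1500 * 1e-4), tolerance = 0.005)
  expect_error(sample_free_path(10, 0), "ballistic")
})

test_that("scatterer selection follows the competing-interaction rule", {
  set.seed(2)
  expect_true(all(sample_scatterer_type(100, 1500, 0) == "sphere"))
  frac <- mean(sample_scatterer_type(1e5, 1500, 500) == "sphere")
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  frac <- mean(sample_scatterer_type(1e5, 1000, 1000) == "sphere")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(sample_scatterer_type(10, 0, 0), "positive")
})

test_that("birefringence acts as the closed-form segment retarder", {
  cfg <- model_config(thickness_um = 10, delta_n = 0.009)
  # propagation along the optic axis: no retardance
  b <- birefringence_retarder(c(1, 0, 0), 25, cfg)
  expect_equal(b$delta, 0)
  expect_mueller_equal(b$mueller, diag(4))
  # normal incidence through d = 10 um: delta = 2 pi dn d / lambda
  b <- birefringence_retarder(c(0, 0, 1), 10, cfg)
  expect_equal(b$delta, 2 * pi * 0.009 * 10 / 0.533, tolerance = 1e-12)
  expect_equal(b$axis_angle, 0)
  # delta_n = 0: identity for any direction
  cfg0 <- model_config(thickness_um = 10, delta_n = 0)
  b <- birefringence_retarder(c(0.6, 0, 0.8), 10, cfg0)
  expect_mueller_equal(b$mueller, diag(4))
  # oblique propagation uses the angle-dependent extraordinary index
  v <- c(sqrt(0.5), 0, sqrt(0.5))
  b <- birefringence_retarder(v, 10, cfg)
  nmo <- 1.33
  nme <- 1.33 + 0.009
  ne <- 1 / sqrt(0.5 / nmo^2 + 0.5 / nme^2)
  expect_equal(b$delta, 2 * pi / 0.533 * (ne - nmo) * 10, tolerance = 1e-12)
})

test_that("empty and ballistic slabs reproduce closed forms exactly", {
  cfg <- model_config(thickness_um = 0.01, n_photons = 10, n_batches = 10)
  res <- run_simulation(cfg)
  expect_mueller_equal(res$mueller, diag(4), 1e-6)
  delta <- 2 * pi * 0.009 * 10 / 0.533
  cfg <- model_config(thickness_um = 10, delta_n = 0.009, n_photons = 10, n_batches = 10)
  res <- run_simulation(cfg)
  expect_mueller_equal(res$mueller, make_retarder(delta, 0), 1e-12)
  expect_equal(res$invariants$RT, delta, tolerance = 1e-9)
})

test_that("every launched photon is classified exactly once", {
  cfg <- model_config(
    thickness_um = 20, mu_s_cm = 1500, mu_c_cm = 500,
    delta_n = 0.009, n_photons = 2e3, n_batches = 10, seed = 5
  )
  res <- run_simulation(cfg)
  expect_equal(sum(res$counts$n), 4 * cfg$n_photons)
  expect_true(all(res$counts$n >= 0))
})

test_that("identical configuration and seed give bit-identical results", {
  cfg <- model_config(
    thickness_um = 15, mu_s_cm = 1500, delta_n = 0.009,
    n_photons = 2e3, n_batches = 10, seed = 9
  )
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$mueller, r2$mueller)
  expect_identical(r1$image$sums, r2$image$sums)
  expect_identical(r1$counts, r2$counts)
  # a different seed gives a different (but valid) estimate
  cfg$seed <- 10L
  r3 <- run_simulation(cfg)
  expect_false(identical(r1$mueller, r3$mueller))
})

test_that("thin-slab limit stays near the identity", {
  cfg <- model_config(
    thickness_um = 1, mu_s_cm = 100, n_photons = 4e3,
    n_batches = 10, seed = 2
  )
  res <- run_simulation(cfg)
  expect_lt(max(abs(res$mueller - diag(4))), 0.03)
})

test_that("spatial averaging is consistent, linear and guarded", {
  cfg <- model_config(
    thickness_um = 10, mu_s_cm = 1500, delta_n = 0.009,
    n_photons = 4e3, n_batches = 10, seed = 3
  )
  res <- run_simulation(cfg)
  # the result's matrix is the 600-um average of its own image
  expect_mueller_equal(spatial_average(res$image, 600), res$mueller, 1e-12)
  # averaging commutes with global scaling of the accumulators
  img2 <- res$image
  img2$sums <- img2$sums * 3.7
  expect_mueller_equal(spatial_average(img2, 600), res$mueller, 1e-12)
  # diameter 0 degenerates to the central pixel (ballistic photons land there)
  cfg0 <- model_config(thickness_um = 10, delta_n = 0.009, n_photons = 10, n_batches = 10)
  res0 <- run_simulation(cfg0)
  expect_mueller_equal(
    spatial_average(res0$image, 0),
    make_retarder(2 * pi * 0.009 * 10 / 0.533, 0), 1e-12
  )
  expect_error(spatial_average(res$image, 1e6), "exceeds")
})

test_that("batch standard errors behave like Monte Carlo standard errors", {
  # identical batches: zero SE (depolarizer equal in the retarder plane so
  # the two elements commute and RT stays exactly 0.5)
  M <- make_retarder(0.5, 0.1) %*%
    rotate_mueller(diag(c(1, exp(-0.2), exp(-0.4), exp(-0.4))), 0.1)
  se <- mc_standard_error(rep(list(M), 10))
  expect_true(all(se$se < 1e-12))
  expect_equal(se$estimate[se$invariant == "RT"], 0.5, tolerance = 1e-9)
  # SE scales as 1 / sqrt(n_batches) on synthetic jitter
  set.seed(4)
  jitter_batches <- function(nb, eps) {
    lapply(seq_len(nb), function(i) {
      make_retarder(0.5 + rnorm(1, sd = eps), 0.1)
    })
  }
  se10 <- mc_standard_error(jitter_batches(10, 0.01))
  se40 <- mc_standard_error(jitter_batches(40, 0.01))
  r <- se40$se[se40$invariant == "RT"] / se10$se[se10$invariant == "RT"]
  expect_lt(abs(r - 0.5), 0.35)
  expect_error(mc_standard_error(rep(list(M), 5)), "at least 10")
  # seeded MC run reproduces its SEs exactly
  cfg <- model_config(
    thickness_um = 10, mu_s_cm = 1500, n_photons = 2e3,
    n_batches = 10, seed = 6
  )
  expect_identical(run_simulation(cfg)$se, run_simulation(cfg)$se)
})

test_that("zero detection raises an explicit under-sampling error", {
  # photons are lost laterally long before crossing a very thick slab
  cfg <- model_config(
    thickness_um = 5000, mu_s_cm = 5000, n_photons = 40,
    n_batches = 10, seed = 1, lateral_halfwidth_um = 100
  )
  expect_error(run_simulation(cfg), "no photons")
})

test_that("model configuration validates physical constraints", {
  expect_error(model_config(thickness_um = -1), "thickness_um")
  expect_error(model_config(10, optic_axis = c(0, 0, 1)), "slab plane")
  expect_error(
    model_config(10, detector_diameter_um = 5000, image_pixels = 11, image_pitch_um = 10),
    "exceeds"
  )
  cfg <- model_config(10, optic_axis = c(2, 0, 0))
  expect_equal(cfg$optic_axis, c(1, 0, 0))
})

test_that("configurations serialize through JSON and YAML", {
  cfg <- make_preset("SCB", thickness_um = 12)
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_model_config(cfg, f)
    back <- read_model_config(f)
    expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
    unlink(f)
  }
})

test_that("mueller image export writes one row per pixel", {
  cfg <- model_config(
    thickness_um = 10, delta_n = 0.009, n_photons = 10,
    n_batches = 10, image_pixels = 5, image_pitch_um = 150
  )
  res <- run_simulation(cfg)
  f <- tempfile(fileext = ".tsv")
  write_mueller_image(res$image, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 25)
  expect_true(all(c("x_um", "y_um", "m11", "m44") %in% names(tab)))
  unlink(f)
})
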
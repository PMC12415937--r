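test_that("the tabular generator is deterministic and leaves the caller's RNG alone", {
  cfg <- study_config(mice_per_group = 2, images_per_mouse = 2,
                      arterioles_per_image = 3, capillaries_per_image = 3,
                      intramural_per_image = 3, extramural_per_image = 3)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- simulate_tabular_study(cfg, seed = 7)
  after <- runif(1)
  expect_equal(before, after)  # generator did not consume the global stream
  b <- simulate_tabular_study(cfg, seed = 7)
  expect_identical(a$study$vessels, b$study$vessels)
  expect_identical(a$study$aggregates, b$study$aggregates)
  c2 <- simulate_tabular_study(cfg, seed = 8)
  expect_false(identical(a$study$vessels$coverage_pct,
                         c2$study$vessels$coverage_pct))
})

test_that("the zero fraction matches the logistic zero-inflation intercept", {
  pars <- list(beta0 = qlogis(0.2), beta1 = 0, phi = 3, gamma0 = qlogis(0.35),
               sigma_mouse = 0, sigma_image = 0)
  d <- simulate_glmm_data(pars, "zibeta", 2, 5, 1000, seed = 3)
  p0 <- mean(d$value == 0)
  n <- nrow(d)
  tol <- 4 * sqrt(0.35 * 0.65 / n)  # binomial Monte-Carlo error
  expect_equal(p0, plogis(pars$gamma0), tolerance = tol / plogis(pars$gamma0))
})

test_that("under the null the two groups are exchangeable", {
  pars <- list(beta0 = qlogis(0.2), beta1 = 0, phi = 3, gamma0 = qlogis(0.3),
               sigma_mouse = 0, sigma_image = 0)
  ps <- vapply(1:5, function(s) {
    d <- simulate_glmm_data(pars, "zibeta", 3, 4, 25, seed = 100 + s)
    suppressWarnings(stats::ks.test(d$value[d$group == "control"],
                                    d$value[d$group == "clu"])$p.value)
  }, numeric(1))
  expect_gt(max(ps), 0.1)     # not systematically different
  expect_gt(min(ps), 0.001)
})

test_that("rendered scenes are recovered exactly by the segmentation rules", {
  sc <- synthetic_scene(shape = c(256, 256), n_arterioles = 3,
                        n_capillaries = 10, n_intramural = 0,
                        n_extramural = 0, arteriole_outer_um = c(14, 30),
                        seed = 71)
  ren <- render_synthetic_image(sc, n_z = 2,
                                noise = list(gaussian_sd = 0, poisson_scale = 0))
  proj <- max_project(ren$stack)
  m <- measure_image(proj, image_id = "s71")
  truth <- ren$truth$vessels
  expect_equal(sum(m$vessels$kind == "arteriole"),
               sum(truth$kind == "arteriole"))
  expect_equal(sum(m$vessels$kind == "capillary"),
               sum(truth$kind == "capillary"))
  # matched wall areas
  expect_setequal(m$arterioles$records$area_px,
                  truth$area_px[truth$kind == "arteriole"])

  # a scene whose only ring-like object is a gap-ring yields no arterioles
  sc2 <- synthetic_scene(shape = c(128, 128), n_arterioles = 0,
                         n_capillaries = 0, n_intramural = 0,
                         n_extramural = 0, n_gap_rings = 1, seed = 72)
  ren2 <- render_synthetic_image(sc2, n_z = 1,
                                 noise = list(gaussian_sd = 0, poisson_scale = 0))
  m2 <- detect_arterioles(ren2$truth$collagen4, ren2$truth$sma)
  expect_equal(nrow(m2$records), 0)

  # empty scene
  sc3 <- synthetic_scene(shape = c(64, 64), n_arterioles = 0,
                         n_capillaries = 0, n_intramural = 0,
                         n_extramural = 0, seed = 73)
  ren3 <- render_synthetic_image(sc3, n_z = 1,
                                 noise = list(gaussian_sd = 0, poisson_scale = 0))
  expect_equal(sum(ren3$truth$collagen4), 0)
  m3 <- measure_image(max_project(ren3$stack),
                      segmentation_params(threshold_method = "fixed",
                                          threshold_value = 0.5),
                      detection_params(threshold_method = "fixed",
                                       threshold_value = 0.5),
                      image_id = "empty")
  expect_equal(nrow(m3$vessels), 0)
  expect_equal(nrow(m3$aggregates), 0)
})

test_that("rendering is deterministic, including the noise draw", {
  sc <- synthetic_scene(shape = c(96, 96), n_arterioles = 1, n_capillaries = 2,
                        n_intramural = 1, n_extramural = 2, seed = 74)
  r1 <- render_synthetic_image(sc, n_z = 3,
                               noise = list(gaussian_sd = 0.02, poisson_scale = 0),
                               seed = 75)
  r2 <- render_synthetic_image(sc, n_z = 3,
                               noise = list(gaussian_sd = 0.02, poisson_scale = 0),
                               seed = 75)
  expect_identical(r1$stack$channels, r2$stack$channels)
  expect_identical(r1$truth$vessels, r2$truth$vessels)
})

test_that("ground truth is pixel-consistent with the noise-free scene", {
  sc <- synthetic_scene(shape = c(160, 160), n_arterioles = 2,
                        n_capillaries = 3, n_intramural = 2, n_extramural = 3,
                        seed = 76)
  ren <- render_synthetic_image(sc, n_z = 1,
                                noise = list(gaussian_sd = 0, poisson_scale = 0))
  proj <- max_project(ren$stack)
  expect_identical(proj$channels$collagen4 > 0, ren$truth$collagen4)
  expect_identical(proj$channels$sma > 0, ren$truth$sma)
  # blob footprints are exactly the half-maximum region
  expect_identical(proj$channels$abeta >= 0.5 - 1e-9, ren$truth$abeta)
  # recorded wall areas match the mask
  for (k in seq_len(nrow(ren$truth$vessels))) {
    v <- ren$truth$vessels[k, ]
    lab <- if (v$kind == "arteriole") ren$truth$arteriole_labels else
      ren$truth$capillary_labels
    expect_equal(v$area_px, sum(lab == as.integer(sub(".*_", "", v$vessel_id))))
  }
})
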
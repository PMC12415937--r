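test_that("white top-hat agrees with a brute-force min/max window oracle", {
  expect_equal(white_top_hat(matrix(3.7, 12, 12), 2), matrix(0, 12, 12))

  one <- matrix(0, 15, 15); one[8, 8] <- 100
  th <- white_top_hat(one, 3)
  expect_equal(th[8, 8], 100)
  expect_equal(sum(th) - th[8, 8], 0)

  set.seed(9)
  img <- matrix(runif(256), 16, 16)
  for (r in c(1, 2)) {
    expect_equal(white_top_hat(img, r), bf_white_top_hat(img, r),
                 tolerance = 1e-12)
  }
  expect_error(white_top_hat(img, 0), "at least 1")
})

test_that("Mexican-hat response vanishes on constants and ramps, peaks at blob scale", {
  expect_equal(max(abs(mexican_hat_filter(matrix(5, 32, 32), 2))), 0,
               tolerance = 1e-10)
  ramp <- outer(1:32, 1:32, function(i, j) 0.3 * i + 0.1 * j)
  resp <- mexican_hat_filter(ramp, 2)
  expect_lt(max(abs(resp[10:22, 10:22])), 1e-8)  # interior only

  # isotropic Gaussian blob of scale s: response at centre maximised near
  # sigma = s over a dense sigma grid
  s <- 3
  blob <- outer(1:49, 1:49, function(i, j)
    exp(-((i - 25)^2 + (j - 25)^2) / (2 * s^2)))
  sigmas <- seq(1, 6, by = 0.25)
  centre <- vapply(sigmas, function(sg)
    mexican_hat_filter(blob, sg)[25, 25], numeric(1))
  expect_equal(sigmas[which.max(centre)], s, tolerance = 0.26)
  expect_error(mexican_hat_filter(blob, 0), "positive")
})

test_that("aggregate labelling respects connectivity and minimum size", {
  resp <- matrix(0, 20, 20)
  resp[4:6, 4:6] <- 1
  resp[14:16, 12:15] <- 1
  det <- detect_aggregates(resp, detection_params(threshold_method = "fixed",
                                                  threshold_value = 0.5))
  expect_equal(nrow(det$records), 2)
  expect_setequal(det$records$size_px, c(9L, 12L))

  diagpx <- matrix(0, 8, 8)
  diagpx[3, 3] <- 1; diagpx[4, 4] <- 1
  p8 <- detection_params(threshold_method = "fixed", threshold_value = 0.5,
                         connectivity = 8)
  p4 <- detection_params(threshold_method = "fixed", threshold_value = 0.5,
                         connectivity = 4)
  expect_equal(nrow(detect_aggregates(diagpx, p8)$records), 1)
  expect_equal(nrow(detect_aggregates(diagpx, p4)$records), 2)

  expect_equal(nrow(detect_aggregates(matrix(0.1, 6, 6),
                                      detection_params(threshold_method = "fixed",
                                                       threshold_value = 5))$records),
               0)
})

test_that("labelling agrees with EBImage at its 4-connectivity convention", {
  set.seed(21)
  mask <- matrix(runif(900) < 0.35, 30, 30)
  ours <- detect_aggregates(ifelse(mask, 1, 0),
                            detection_params(threshold_method = "fixed",
                                             threshold_value = 0.5,
                                             connectivity = 4))
  ref <- EBImage::bwlabel(mask)
  expect_equal(max(ours$labels), max(ref))
  # identical partition: every reference component maps to one of ours
  for (k in seq_len(max(ref)))
    expect_equal(length(unique(ours$labels[ref == k])), 1)
})

test_that("detection is invariant to constant offsets and conserves pixel sums", {
  set.seed(33)
  sc <- synthetic_scene(shape = c(128, 128), n_arterioles = 0,
                        n_capillaries = 0, n_intramural = 0,
                        n_extramural = 6, seed = 17)
  ren <- render_synthetic_image(sc, n_z = 1,
                                noise = list(gaussian_sd = 0, poisson_scale = 0))
  ab <- max_project(ren$stack)$channels$abeta
  p <- detection_params(top_hat_radius_px = 8, mexican_hat_sigma_px = 1.6,
                        threshold_method = "fixed", threshold_value = 0.1)
  d0 <- detect_amyloid(ab, p)
  d1 <- detect_amyloid(ab + 0.37, p)  # top-hat removes the offset
  expect_identical(d0$labels, d1$labels)
  expect_equal(d0$records$size_px, d1$records$size_px)
  # sum conservation: sizes add up to the suprathreshold pixel count
  expect_equal(sum(d0$records$size_px), sum(d0$labels > 0))
})

test_that("zero-noise blob scenes are recovered with correct counts and sizes", {
  sc <- synthetic_scene(shape = c(160, 160), n_arterioles = 0,
                        n_capillaries = 0, n_intramural = 0,
                        n_extramural = 8, seed = 23)
  ren <- render_synthetic_image(sc, n_z = 2,
                                noise = list(gaussian_sd = 0, poisson_scale = 0))
  ab <- max_project(ren$stack)$channels$abeta
  det <- detect_amyloid(ab, detection_params(top_hat_radius_px = 8,
                                             mexican_hat_sigma_px = 1.6,
                                             threshold_method = "fixed",
                                             threshold_value = 0.1))
  truth <- ren$truth$aggregates
  expect_equal(nrow(det$records), nrow(truth))
  # per-blob size within a boundary-pixel band of the rendered footprint
  got <- sort(det$records$size_px)
  want <- sort(truth$size_px)
  radius <- sqrt(want / pi)
  expect_true(all(abs(got - want) <= 2 * (2 * pi * radius + 4)))
})
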
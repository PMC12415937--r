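test_that("thresholding matches a per-pixel comparison oracle", {
  expect_false(any(threshold_channel(matrix(0, 8, 8), "fixed", value = 10)))
  two <- matrix(0, 10, 10); two[3:5, 3:5] <- 100
  m <- threshold_channel(two, "otsu")
  expect_identical(unclass(m)[, ], two == 100)
  set.seed(5)
  r <- matrix(runif(400, 0, 10), 20, 20)
  thr <- 4.2
  got <- threshold_channel(r, "fixed", value = thr)
  ref <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20) ref[i, j] <- r[i, j] > thr
  expect_identical(unclass(got)[, ], ref)
  expect_error(threshold_channel(r, "fixed"), "requires")
})

test_that("complete-ring test distinguishes rings, gap-rings and disks", {
  ann <- make_annulus(40, 40, 20, 20, 10, 5)
  rings <- find_complete_rings(ann)
  expect_equal(nrow(rings), 1)
  expect_true(rings$is_ring[1])
  # the enclosed hole is the interior disk
  expect_equal(rings$lumen_px[1], sum(make_disk(40, 40, 20, 20, 5)))

  gap <- make_annulus(40, 40, 20, 20, 10, 5, gap_deg = 25)  # > 2 px cut
  rg <- find_complete_rings(gap)
  expect_equal(nrow(rg), 1)
  expect_false(rg$is_ring[1])
  expect_equal(rg$lumen_px[1], 0)

  disk <- make_disk(40, 40, 20, 20, 8)
  rd <- find_complete_rings(disk)
  expect_false(rd$is_ring[1])

  expect_equal(nrow(find_complete_rings(matrix(FALSE, 10, 10))), 0)
})

test_that("ring flag is invariant to translation and 90-degree rotation", {
  base <- make_annulus(60, 60, 20, 25, 9, 5)
  shifted <- make_annulus(60, 60, 35, 30, 9, 5)
  for (m in list(base, shifted, t(base), base[60:1, ], base[, 60:1])) {
    r <- find_complete_rings(m)
    expect_true(all(r$is_ring))
    expect_equal(r$lumen_px, find_complete_rings(base)$lumen_px)
  }
  gap <- make_annulus(60, 60, 30, 30, 9, 5, gap_deg = 30)
  for (m in list(gap, t(gap), gap[60:1, ], gap[, 60:1]))
    expect_false(any(find_complete_rings(m)$is_ring))
})

test_that("arteriole detection applies ring, co-positivity and area rules", {
  # qualifying annulus: area >= 150 px, fully co-positive
  big <- annulus_with_area(150, 260, wall = 3.5)
  det <- detect_arterioles(big$mask, big$mask)
  expect_equal(nrow(det$records), 1)
  expect_equal(det$records$area_px, big$area)
  expect_equal(det$records$kind, "arteriole")
  expect_equal(sum(det$labels > 0), big$area)

  # identical shape but wall area below 150 px: excluded
  small <- annulus_with_area(120, 149, wall = 2.2)
  expect_lt(small$area, 150)
  det2 <- detect_arterioles(small$mask, small$mask)
  expect_equal(nrow(det2$records), 0)

  # complete ring with no Collagen IV overlap: excluded
  det3 <- detect_arterioles(matrix(FALSE, 64, 64), big$mask)
  expect_equal(nrow(det3$records), 0)

  expect_error(detect_arterioles(matrix(FALSE, 5, 5), matrix(FALSE, 6, 5)),
               "shapes differ")
})

test_that("capillaries are carved from the dilated-arteriole complement", {
  ny <- nx <- 96
  art <- annulus_with_area(150, 260, wall = 3.5, ny = ny, nx = nx)
  colIV <- art$mask
  colIV[10:14, 20:29] <- TRUE  # separate 5 x 10 = 50 px tube
  arts <- detect_arterioles(colIV, art$mask)
  caps <- derive_capillaries(colIV, arts)
  expect_equal(nrow(caps$records), 1)
  expect_equal(caps$records$area_px, 50L)
  expect_equal(caps$records$kind, "capillary")

  # a 28-px fragment (4 x 7) is below the 29-px rule
  colIV2 <- art$mask
  colIV2[10:13, 20:26] <- TRUE
  caps2 <- derive_capillaries(colIV2, arts)
  expect_equal(nrow(caps2$records), 0)

  # empty Collagen IV mask: no capillaries
  caps3 <- derive_capillaries(matrix(FALSE, ny, nx), arts)
  expect_equal(nrow(caps3$records), 0)

  # disjointness: no pixel is both arteriole wall and capillary
  expect_equal(sum(arts$labels > 0 & caps$labels > 0), 0)
})

test_that("raising area thresholds never increases vessel counts", {
  sc <- synthetic_scene(shape = c(192, 192), n_arterioles = 3,
                        n_capillaries = 6, n_intramural = 0,
                        n_extramural = 0, seed = 31)
  ren <- render_synthetic_image(sc, n_z = 1,
                                noise = list(gaussian_sd = 0, poisson_scale = 0))
  colm <- ren$truth$collagen4
  smam <- ren$truth$sma
  # arteriole threshold raised alone
  prev_a <- Inf
  for (thr in c(50, 150, 400, 1200)) {
    arts <- detect_arterioles(colm, smam,
                              segmentation_params(min_arteriole_area_px = thr))
    expect_lte(nrow(arts$records), prev_a)
    prev_a <- nrow(arts$records)
  }
  # capillary threshold raised alone, arteriole set held fixed
  arts <- detect_arterioles(colm, smam)
  prev_c <- Inf
  for (thr in c(10, 29, 80, 240)) {
    caps <- derive_capillaries(colm, arts,
                               segmentation_params(min_capillary_area_px = thr))
    expect_lte(nrow(caps$records), prev_c)
    prev_c <- nrow(caps$records)
  }
})
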
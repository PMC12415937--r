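test_that("wall coverage is the overlap percentage", {
  wall <- matrix(FALSE, 20, 20); wall[5:14, 5:14] <- TRUE   # 100 px
  expect_equal(vessel_coverage(wall, wall), 100)
  expect_equal(vessel_coverage(wall, matrix(FALSE, 20, 20)), 0)

  wall2 <- matrix(FALSE, 20, 40); wall2[1:10, 1:20] <- TRUE  # 200 px
  ab <- matrix(FALSE, 20, 40); ab[1:5, 1:10] <- TRUE         # 50 px overlap
  expect_equal(sum(wall2), 200); expect_equal(sum(wall2 & ab), 50)
  expect_equal(vessel_coverage(wall2, ab), 25)

  expect_error(vessel_coverage(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)),
               "empty wall")
  expect_error(vessel_coverage(wall, matrix(FALSE, 5, 5)), "shapes differ")
})

test_that("compartment assignment uses a strict pixel majority", {
  wall <- matrix(FALSE, 10, 10); wall[1:10, 1:5] <- TRUE
  inside <- matrix(FALSE, 10, 10); inside[2:4, 2:4] <- TRUE
  outside <- matrix(FALSE, 10, 10); outside[2:4, 7:9] <- TRUE
  expect_equal(assign_compartment(inside, wall), "intramural")
  expect_equal(assign_compartment(outside, wall), "extramural")

  # straddling: 6 of 10 px on the wall -> intramural; 5 of 10 -> extramural
  agg6 <- matrix(FALSE, 10, 10); agg6[1, 1:10] <- TRUE
  wall6 <- matrix(FALSE, 10, 10); wall6[1, 1:6] <- TRUE
  expect_equal(assign_compartment(agg6, wall6), "intramural")
  wall5 <- matrix(FALSE, 10, 10); wall5[1, 1:5] <- TRUE
  expect_equal(assign_compartment(agg6, wall5), "extramural")
  # any-overlap variant
  expect_equal(assign_compartment(agg6, wall5, rule = "any"), "intramural")
  expect_error(assign_compartment(matrix(FALSE, 10, 10), wall), "empty")
})

test_that("extreme-outlier rule removes only >20x jumps and is idempotent", {
  r1 <- remove_extreme_outliers(c(1, 2, 3, 100))
  expect_equal(r1$removed, 100)
  expect_equal(sort(r1$kept), c(1, 2, 3))

  r2 <- remove_extreme_outliers(c(1, 2, 3, 50))
  expect_equal(length(r2$removed), 0)
  expect_equal(r2$kept, c(1, 2, 3, 50))

  expect_equal(remove_extreme_outliers(numeric(0))$kept, numeric(0))
  expect_equal(remove_extreme_outliers(7)$kept, 7)

  # iterative: both extremes fall, then the rule stops (30 <= 20 * 2)
  r3 <- remove_extreme_outliers(c(2, 30, 1000, 50000))
  expect_equal(sort(r3$removed), c(1000, 50000))
  expect_equal(sort(r3$kept), c(2, 30))

  # idempotence
  again <- remove_extreme_outliers(r1$kept)
  expect_equal(again$kept, r1$kept)
  expect_equal(length(again$removed), 0)
  expect_error(remove_extreme_outliers(1:3, factor = 1), "exceed 1")
})

test_that("images without arterioles are excluded from vessel-level analyses", {
  vessels <- tibble::tibble(
    group = c("control", "control", "clu"),
    mouse_id = c("m1", "m1", "m6"),
    image_id = c("i1", "i2", "i3"),
    vessel_id = c("art_1", "cap_1", "art_1"),
    kind = c("arteriole", "capillary", "arteriole"),
    wall_area_px = c(200L, 60L, 300L), abeta_px = c(10L, 0L, 30L),
    coverage_pct = c(5, 0, 10))
  aggregates <- tibble::tibble(
    group = c("control", "control", "clu"),
    mouse_id = c("m1", "m1", "m6"),
    image_id = c("i1", "i2", "i3"),
    agg_id = 1:3, size_px = c(5, 8, 12),
    compartment = c("intramural", "extramural", "intramural"))
  st <- build_study_table(vessels, aggregates)

  out <- exclude_images_without_arterioles(st)
  # image i2 has no arteriole: its aggregates go, its capillary row stays
  expect_equal(out$exclusions$image_id, "i2")
  expect_false("i2" %in% out$aggregates$image_id)
  expect_true("i2" %in% out$vessels$image_id[out$vessels$kind == "capillary"])
  # images with arterioles retained untouched
  expect_true(all(c("i1", "i3") %in% out$vessels$image_id))

  # all images have arterioles: identity
  st2 <- build_study_table(vessels[c(1, 3), ], aggregates[c(1, 3), ])
  out2 <- exclude_images_without_arterioles(st2)
  expect_equal(out2$vessels, st2$vessels)
  expect_equal(out2$aggregates, st2$aggregates)
  expect_equal(nrow(out2$exclusions), 0)
})

test_that("study tables enforce the nesting invariants", {
  v <- tibble::tibble(group = c("control", "clu"), mouse_id = c("m1", "m2"),
                      image_id = c("i1", "i1"), vessel_id = c("a", "b"),
                      kind = "arteriole", wall_area_px = c(200L, 200L),
                      abeta_px = c(1L, 1L), coverage_pct = c(0.5, 0.5))
  a <- v[0, ]
  expect_error(build_study_table(v, tibble::tibble(
    group = character(), mouse_id = character(), image_id = character(),
    agg_id = integer(), size_px = integer(), compartment = character())),
    "more than one mouse")
  v2 <- v; v2$image_id <- c("i1", "i2"); v2$mouse_id <- c("m1", "m1")
  expect_error(build_study_table(v2, a[0, ]), "more than one group")
  v3 <- v; v3$image_id <- c("i1", "i2"); v3$abeta_px <- c(300L, 1L)
  expect_error(build_study_table(v3, a[0, ]), "cannot exceed")
})

test_that("coverage lies in [0, 100] with exact zeros on rendered scenes", {
  sc <- synthetic_scene(shape = c(192, 192), n_arterioles = 2,
                        n_capillaries = 4, n_intramural = 2, n_extramural = 4,
                        seed = 41)
  ren <- render_synthetic_image(sc, n_z = 1,
                                noise = list(gaussian_sd = 0, poisson_scale = 0))
  m <- measure_image(max_project(ren$stack), image_id = "x")
  expect_true(all(m$vessels$coverage_pct >= 0 & m$vessels$coverage_pct <= 100))
  expect_true(any(m$vessels$coverage_pct == 0))  # feeds the zero-inflation part
  # compartment partition: every aggregate in exactly one compartment
  expect_equal(sum(m$aggregates$compartment == "intramural") +
                 sum(m$aggregates$compartment == "extramural"),
               nrow(m$aggregates))
})
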
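## Synthetic study generator: (a) tabular data drawn exactly from the two
## GLMM families for inference testing, and (b) rendered multi-channel
## image scenes with pixel-level ground truth for the image pipeline.

#' Study configuration for the synthetic generator
#'
#' Defaults emulate the study design: 2 groups x 5 mice x 10 images per
#' mouse, 1024 x 1024 px at 0.5676 um/pixel, arterioles of 10-40 um outer
#' diameter with 2-5 um walls, 3.5-um capillaries, and generative
#' parameters in the vicinity of the fitted real-data effects (coverage
#' group effect about -0.24 on the logit scale, intramural size effect
#' about -0.56 on the log scale) -- illustrative of the study's magnitude,
#' not a reproduction of it.
#'
#' @param mice_per_group mice per group (default 5).
#' @param images_per_mouse images per mouse (default 10).
#' @param image_shape image size in pixels, `c(ny, nx)`.
#' @param pixel_size_um lateral calibration (um/pixel).
#' @param n_z number of z planes rendered per stack.
#' @param arterioles_per_image,capillaries_per_image vessel counts drawn
#'   per image.
#' @param intramural_per_image,extramural_per_image aggregate counts per
#'   image (placement rates per compartment).
#' @param arteriole_outer_um range of arteriole outer diameters (um).
#' @param wall_um range of arteriole wall thicknesses (um).
#' @param capillary_width_um capillary tube width (um).
#' @param zib_arteriole,zib_capillary zero-inflated Beta generative
#'   parameters for vessel coverage (lists with `beta0`, `beta1`, `phi`,
#'   `gamma0`, `sigma_mouse`, `sigma_image`).
#' @param tweedie_intramural,tweedie_extramural Tweedie generative
#'   parameters for aggregate size (lists with `beta0`, `beta1`, `phi`,
#'   `p`, `sigma_mouse`, `sigma_image`).
#' @param noise list with `gaussian_sd` (additive background noise SD) and
#'   `poisson_scale` (photon-like scaling; 0 disables).
#' @param seed default seed used when none is passed to the generator.
#' @return A list of class `study_config`.
#' @export
study_config <- function(mice_per_group = 5L,
                         images_per_mouse = 10L,
                         image_shape = c(1024L, 1024L),
                         pixel_size_um = 0.5676,
                         n_z = 3L,
                         arterioles_per_image = 3L,
                         capillaries_per_image = 8L,
                         intramural_per_image = 6L,
                         extramural_per_image = 12L,
                         arteriole_outer_um = c(10, 40),
                         wall_um = c(2, 5),
                         capillary_width_um = 3.5,
                         zib_arteriole = list(beta0 = qlogis(0.10), beta1 = -0.24,
                                              phi = 3, gamma0 = qlogis(0.35),
                                              sigma_mouse = 0.4, sigma_image = 0.3),
                         zib_capillary = list(beta0 = qlogis(0.05), beta1 = 0.17,
                                              phi = 3, gamma0 = qlogis(0.7),
                                              sigma_mouse = 0.4, sigma_image = 0.3),
                         tweedie_intramural = list(beta0 = log(12), beta1 = -0.56,
                                                   phi = 2, p = 1.6,
                                                   sigma_mouse = 0.3,
                                                   sigma_image = 0.2),
                         tweedie_extramural = list(beta0 = log(4), beta1 = -0.48,
                                                   phi = 1.5, p = 1.5,
                                                   sigma_mouse = 0.3,
                                                   sigma_image = 0.2),
                         noise = list(gaussian_sd = 0.02, poisson_scale = 0),
                         seed = 1L) {
  stopifnot(mice_per_group >= 1, images_per_mouse >= 1,
            all(image_shape >= 32), pixel_size_um > 0,
            arteriole_outer_um[1] >= 10, all(wall_um > 0),
            capillary_width_um > 0)
  structure(as.list(environment()), class = "study_config")
}

#' Simulate hierarchical data from one GLMM family
#'
#' Draws mouse and image random intercepts from their Gaussians, then
#' responses from the requested family at the group-specific linear
#' predictor. This is the generative counterpart of [fit_zib_glmm()] /
#' [fit_tweedie_glmm()] and is what the parameter-recovery checks consume.
#'
#' @param params generative parameters (see [study_config()]); `gamma1`
#'   may be supplied for a group effect in the zero part.
#' @param family `"zibeta"` or `"tweedie"`.
#' @param mice_per_group,images_per_mouse,units_per_image design sizes.
#' @param seed RNG seed (local; the caller's RNG stream is untouched).
#' @return A tibble with columns `value`, `group`, `mouse_id`, `image_id`,
#'   plus attributes `params` and `ranef` (the drawn intercepts).
#' @export
simulate_glmm_data <- function(params, family = c("zibeta", "tweedie"),
                               mice_per_group = 5L, images_per_mouse = 5L,
                               units_per_image = 10L, seed = 1L) {
  family <- match.arg(family)
  local_seed(seed, {
    groups <- rep(c("control", "clu"), each = mice_per_group)
    n_mouse <- length(groups)
    u <- rnorm(n_mouse, 0, params$sigma_mouse)
    rows <- vector("list", n_mouse * images_per_mouse)
    k <- 0L
    for (m in seq_len(n_mouse)) {
      x <- as.numeric(groups[m] != "control")
      for (j in seq_len(images_per_mouse)) {
        v <- rnorm(1, 0, params$sigma_image)
        eta <- params$beta0 + params$beta1 * x + u[m] + v
        y <- if (family == "zibeta") {
          g1 <- if (is.null(params$gamma1)) 0 else params$gamma1
          rzibeta(units_per_image, plogis(eta), params$phi,
                  plogis(params$gamma0 + g1 * x))
        } else {
          rtweedie_cpg(units_per_image, exp(eta), params$phi, params$p)
        }
        k <- k + 1L
        rows[[k]] <- tibble(
          value = y, group = groups[m],
          mouse_id = sprintf("m%02d", m),
          image_id = sprintf("m%02d_i%02d", m, j))
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "params") <- params
    attr(out, "ranef") <- u
    out
  })
}

#' Simulate a full tabular study
#'
#' Generates the four study outcomes -- arteriole coverage, capillary
#' coverage, intramural aggregate size, extramural aggregate size -- each
#' drawn exactly from its generative GLMM (independent random-effect
#' draws per outcome), assembled into a `study_table`.
#'
#' @param config a [study_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with `study` (a `study_table`), and `truth` (the
#'   generative parameter lists).
#' @export
simulate_tabular_study <- function(config = study_config(), seed = config$seed) {
  sims <- list(
    arteriole = simulate_glmm_data(config$zib_arteriole, "zibeta",
                                   config$mice_per_group, config$images_per_mouse,
                                   config$arterioles_per_image, seed = seed),
    capillary = simulate_glmm_data(config$zib_capillary, "zibeta",
                                   config$mice_per_group, config$images_per_mouse,
                                   config$capillaries_per_image, seed = seed + 1L),
    intramural = simulate_glmm_data(config$tweedie_intramural, "tweedie",
                                    config$mice_per_group, config$images_per_mouse,
                                    config$intramural_per_image, seed = seed + 2L),
    extramural = simulate_glmm_data(config$tweedie_extramural, "tweedie",
                                    config$mice_per_group, config$images_per_mouse,
                                    config$extramural_per_image, seed = seed + 3L))

  mk_vessels <- function(d, kind) tibble(
    group = d$group, mouse_id = d$mouse_id, image_id = d$image_id,
    vessel_id = paste0(substr(kind, 1, 3), "_", stats::ave(
      seq_len(nrow(d)), d$image_id, FUN = seq_along)),
    kind = kind, wall_area_px = NA_integer_, abeta_px = NA_integer_,
    coverage_pct = 100 * d$value)
  mk_aggs <- function(d, comp) tibble(
    group = d$group, mouse_id = d$mouse_id, image_id = d$image_id,
    agg_id = stats::ave(seq_len(nrow(d)), d$image_id, FUN = seq_along),
    size_px = d$value, compartment = comp)

  vessels <- rbind(mk_vessels(sims$arteriole, "arteriole"),
                   mk_vessels(sims$capillary, "capillary"))
  aggregates <- rbind(mk_aggs(sims$intramural, "intramural"),
                      mk_aggs(sims$extramural, "extramural"))
  study <- build_study_table(vessels, aggregates)
  list(study = study,
       truth = list(zib_arteriole = config$zib_arteriole,
                    zib_capillary = config$zib_capillary,
                    tweedie_intramural = config$tweedie_intramural,
                    tweedie_extramural = config$tweedie_extramural,
                    ranef = lapply(sims, attr, "ranef")))
}

## ---------------------------------------------------------------------------
## Image-scene rendering

stamp_disk <- function(mask, cy, cx, r) {
  ny <- nrow(mask); nx <- ncol(mask)
  y0 <- max(1L, floor(cy - r)); y1 <- min(ny, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(nx, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(mask)
  yy <- y0:y1; xx <- x0:x1
  d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
  mask[yy, xx] <- mask[yy, xx] | (d2 <= r^2)
  mask
}

# annulus with optional angular gap (radians); returns a logical mask patch
annulus_mask <- function(shape, cy, cx, r_out, r_in, gap_at = NULL,
                         gap_width = 0) {
  ny <- shape[1]; nx <- shape[2]
  m <- matrix(FALSE, ny, nx)
  y0 <- max(1L, floor(cy - r_out)); y1 <- min(ny, ceiling(cy + r_out))
  x0 <- max(1L, floor(cx - r_out)); x1 <- min(nx, ceiling(cx + r_out))
  yy <- y0:y1; xx <- x0:x1
  dy <- yy - cy
  dx <- xx - cx
  d2 <- outer(dy^2, dx^2, "+")
  ring <- d2 <= r_out^2 & d2 > r_in^2
  if (!is.null(gap_at)) {
    ang <- outer(dy, dx, function(a, b) atan2(a, b))
    dd <- abs(((ang - gap_at + pi) %% (2 * pi)) - pi)
    ring <- ring & !(dd <= gap_width / 2)
  }
  m[yy, xx] <- ring
  m
}

#' Sample a synthetic scene specification
#'
#' Draws the geometry of one image: non-overlapping arterioles (annuli
#' co-positive for Collagen IV and smooth-muscle actin, unstained lumen),
#' Collagen-IV-only capillary tubes, amyloid aggregates placed on arteriole
#' walls (intramural) or in the parenchyma (extramural), and optional
#' distractors: gap-rings (incomplete smooth-muscle rings), solid disks
#' (no lumen), small complete rings below the arteriole area threshold,
#' and sub-threshold Collagen specks.
#'
#' @param shape image shape `c(ny, nx)` in pixels.
#' @param pixel_size_um calibration (um/pixel).
#' @param n_arterioles,n_capillaries,n_intramural,n_extramural structure
#'   counts.
#' @param n_gap_rings,n_solid_disks,n_small_rings,n_specks distractor
#'   counts.
#' @param arteriole_outer_um,wall_um geometry ranges (um).
#' @param capillary_width_um capillary tube width (um).
#' @param aggregate_sigma_px range of Gaussian blob scales (px).
#' @param seed RNG seed (local).
#' @return A list of class `synthetic_scene` describing every structure.
#' @export
synthetic_scene <- function(shape = c(256L, 256L), pixel_size_um = 0.5676,
                            n_arterioles = 3L, n_capillaries = 8L,
                            n_intramural = 5L, n_extramural = 10L,
                            n_gap_rings = 0L, n_solid_disks = 0L,
                            n_small_rings = 0L, n_specks = 0L,
                            arteriole_outer_um = c(10, 40),
                            wall_um = c(2, 5),
                            capillary_width_um = 3.5,
                            aggregate_sigma_px = c(1.2, 2.2),
                            seed = 1L) {
  local_seed(seed, {
    ny <- shape[1]; nx <- shape[2]
    px <- pixel_size_um
    centres <- matrix(numeric(0), 0, 3)  # cy, cx, radius of exclusion
    place <- function(r_excl, margin, tries = 200L) {
      for (t in seq_len(tries)) {
        cy <- runif(1, margin, ny - margin)
        cx <- runif(1, margin, nx - margin)
        if (nrow(centres) == 0 ||
            all(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2) >
                centres[, 3] + r_excl)) {
          centres <<- rbind(centres, c(cy, cx, r_excl))
          return(c(cy, cx))
        }
      }
      NULL
    }
    arterioles <- list()
    for (k in seq_len(n_arterioles)) {
      r_out <- runif(1, arteriole_outer_um[1] / 2, arteriole_outer_um[2] / 2) / px
      wall <- runif(1, wall_um[1], wall_um[2]) / px
      pos <- place(r_out + 8, r_out + 10)
      if (is.null(pos)) next
      arterioles[[length(arterioles) + 1L]] <-
        list(cy = pos[1], cx = pos[2], r_out = r_out,
             r_in = max(r_out - wall, 1.5))
    }
    mk_ring_distractor <- function(type) {
      r_out <- switch(type,
        gap_ring = runif(1, 8, 16), solid_disk = runif(1, 6, 12),
        small_ring = runif(1, 5.5, 6.5))
      wall <- switch(type, gap_ring = runif(1, 3.5, 6),
                     solid_disk = r_out, small_ring = 2)
      pos <- place(r_out + 8, r_out + 10)
      if (is.null(pos)) return(NULL)
      r_in <- if (type == "solid_disk") 0 else max(r_out - wall, 1.5)
      list(cy = pos[1], cx = pos[2], r_out = r_out, r_in = r_in,
           gap_at = if (type == "gap_ring") runif(1, -pi, pi) else NULL,
           # the gap must truly sever the ring: >= ~3.5 px of arc at the
           # inner wall radius, where the arc is shortest
           gap_width = if (type == "gap_ring")
             max(0.4, 3.5 / max(r_in, 1)) else 0,
           type = type)
    }
    distractors <- list()
    for (type in c("gap_ring", "solid_disk", "small_ring")) {
      n <- switch(type, gap_ring = n_gap_rings, solid_disk = n_solid_disks,
                  small_ring = n_small_rings)
      for (k in seq_len(n)) {
        d <- mk_ring_distractor(type)
        if (!is.null(d)) distractors[[length(distractors) + 1L]] <- d
      }
    }
    capillaries <- list()
    w_cap <- capillary_width_um / px / 2
    for (k in seq_len(n_capillaries)) {
      L <- round(runif(1, 40, 80))
      for (t in 1:100) {
        sy <- runif(1, 10, ny - 10); sx <- runif(1, 10, nx - 10)
        ang <- runif(1, -pi, pi)
        path <- matrix(0, L, 2)
        y <- sy; x <- sx
        ok <- TRUE
        dang <- rnorm(L, 0, 0.12)
        for (i in seq_len(L)) {
          ang <- ang + dang[i]
          y <- y + sin(ang); x <- x + cos(ang)
          if (y < 6 || y > ny - 5 || x < 6 || x > nx - 5) { ok <- FALSE; break }
          path[i, ] <- c(y, x)
        }
        if (!ok) next
        # reject paths near arterioles/distractors (keeps components disjoint)
        if (nrow(centres) > 0) {
          mind <- min(vapply(seq_len(nrow(centres)), function(ci)
            min(sqrt((path[, 1] - centres[ci, 1])^2 +
                     (path[, 2] - centres[ci, 2])^2)) - centres[ci, 3],
            numeric(1)))
          if (mind < w_cap + 7) next
        }
        if (length(capillaries) > 0) {
          prev <- do.call(rbind, lapply(capillaries, `[[`, "path"))
          dmin <- min(sqrt(outer(path[, 1], prev[, 1], "-")^2 +
                           outer(path[, 2], prev[, 2], "-")^2))
          if (dmin < 2 * w_cap + 3) next
        }
        capillaries[[length(capillaries) + 1L]] <- list(path = path, w = w_cap)
        break
      }
    }
    specks <- list()
    for (k in seq_len(n_specks)) {
      pos <- place(4, 8)
      if (!is.null(pos)) specks[[length(specks) + 1L]] <-
        list(cy = pos[1], cx = pos[2], r = runif(1, 1.0, 2.4))  # area < 29 px
    }
    aggregates <- list()
    if (n_intramural > 0 && length(arterioles) > 0) {
      for (k in seq_len(n_intramural)) {
        a <- arterioles[[sample.int(length(arterioles), 1)]]
        ang <- runif(1, -pi, pi)
        r <- (a$r_in + a$r_out) / 2
        aggregates[[length(aggregates) + 1L]] <-
          list(cy = a$cy + r * sin(ang), cx = a$cx + r * cos(ang),
               sigma = runif(1, aggregate_sigma_px[1], aggregate_sigma_px[2]),
               compartment = "intramural")
      }
    }
    for (k in seq_len(n_extramural)) {
      pos <- place(6, 10)
      if (!is.null(pos)) aggregates[[length(aggregates) + 1L]] <-
        list(cy = pos[1], cx = pos[2],
             sigma = runif(1, aggregate_sigma_px[1], aggregate_sigma_px[2]),
             compartment = "extramural")
    }
    structure(list(shape = as.integer(shape), pixel_size_um = px,
                   arterioles = arterioles, capillaries = capillaries,
                   distractors = distractors, specks = specks,
                   aggregates = aggregates),
              class = "synthetic_scene")
  })
}

#' Render a synthetic scene to a calibrated z-stack with ground truth
#'
#' Arterioles appear as annuli positive in both the smooth-muscle and
#' Collagen IV channels with an unstained lumen; capillaries as
#' Collagen-IV-only tubes; amyloid aggregates as Gaussian blobs whose
#' ground-truth extent is their half-maximum footprint. Structures are
#' spread across `n_z` planes with per-plane weights whose maximum is 1,
#' so the maximum projection of a noise-free stack equals the 2D scene.
#' Noise (added last) does not alter the recorded ground truth.
#'
#' @param scene a [synthetic_scene()].
#' @param n_z number of z planes.
#' @param noise list with `gaussian_sd` and `poisson_scale`.
#' @param seed RNG seed for the noise draw (local).
#' @return A list with `stack` (a [zstack_image]), `truth` (masks
#'   `collagen4`, `sma`, `abeta`, arteriole label matrix, and tibbles
#'   `vessels` / `aggregates` with true areas, coverage and compartments)
#'   and `scene`.
#' @export
render_synthetic_image <- function(scene, n_z = 3L,
                                   noise = list(gaussian_sd = 0,
                                                poisson_scale = 0),
                                   seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ny <- scene$shape[1]; nx <- scene$shape[2]
  sma <- matrix(FALSE, ny, nx)
  col <- matrix(FALSE, ny, nx)
  art_labels <- matrix(0L, ny, nx)
  vrows <- list()

  for (k in seq_along(scene$arterioles)) {
    a <- scene$arterioles[[k]]
    ring <- annulus_mask(scene$shape, a$cy, a$cx, a$r_out, a$r_in)
    sma <- sma | ring
    col <- col | ring
    art_labels[ring] <- k
    lumen <- annulus_mask(scene$shape, a$cy, a$cx, a$r_in, 0)
    vrows[[length(vrows) + 1L]] <- tibble(
      vessel_id = paste0("art_", k), kind = "arteriole",
      area_px = as.integer(sum(ring)), lumen_area_px = as.integer(sum(lumen)))
  }
  for (d in scene$distractors) {
    ring <- annulus_mask(scene$shape, d$cy, d$cx, d$r_out, d$r_in,
                         gap_at = d$gap_at, gap_width = d$gap_width)
    sma <- sma | ring
    col <- col | ring
  }
  cap_labels <- matrix(0L, ny, nx)
  for (k in seq_along(scene$capillaries)) {
    cp <- scene$capillaries[[k]]
    m <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(cp$path)))
      m <- stamp_disk(m, cp$path[i, 1], cp$path[i, 2], cp$w)
    col <- col | m
    cap_labels[m] <- k
    vrows[[length(vrows) + 1L]] <- tibble(
      vessel_id = paste0("cap_", k), kind = "capillary",
      area_px = as.integer(sum(m)), lumen_area_px = NA_integer_)
  }
  for (s in scene$specks) col <- stamp_disk(col, s$cy, s$cx, s$r)

  ab <- matrix(0, ny, nx)
  ab_mask <- matrix(FALSE, ny, nx)
  arows <- list()
  half_max_r <- function(sig) sig * sqrt(2 * log(2))
  for (k in seq_along(scene$aggregates)) {
    g <- scene$aggregates[[k]]
    r4 <- ceiling(4 * g$sigma)
    y0 <- max(1L, floor(g$cy - r4)); y1 <- min(ny, ceiling(g$cy + r4))
    x0 <- max(1L, floor(g$cx - r4)); x1 <- min(nx, ceiling(g$cx + r4))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    d2 <- outer((yy - g$cy)^2, (xx - g$cx)^2, "+")
    blob <- exp(-d2 / (2 * g$sigma^2))
    ab[yy, xx] <- pmax(ab[yy, xx], blob)
    foot <- matrix(FALSE, ny, nx)
    foot[yy, xx] <- d2 <= half_max_r(g$sigma)^2
    ab_mask <- ab_mask | foot
    arows[[length(arows) + 1L]] <- tibble(
      agg_id = k, size_px = as.integer(sum(foot)),
      compartment = g$compartment, centroid_y = g$cy - 1, centroid_x = g$cx - 1)
  }

  vessels <- if (length(vrows)) dplyr::bind_rows(vrows) else
    tibble(vessel_id = character(), kind = character(), area_px = integer(),
           lumen_area_px = integer())
  if (nrow(vessels) > 0) {
    cov <- numeric(nrow(vessels))
    for (i in seq_len(nrow(vessels))) {
      wall <- if (vessels$kind[i] == "arteriole")
        art_labels == as.integer(sub("art_", "", vessels$vessel_id[i]))
      else cap_labels == as.integer(sub("cap_", "", vessels$vessel_id[i]))
      cov[i] <- if (any(wall)) 100 * sum(wall & ab_mask) / sum(wall) else 0
    }
    vessels$coverage_pct <- cov
  } else vessels$coverage_pct <- numeric(0)
  aggregates <- if (length(arows)) dplyr::bind_rows(arows) else
    tibble(agg_id = integer(), size_px = integer(), compartment = character(),
           centroid_y = numeric(), centroid_x = numeric())

  # channel intensities (float): stained structures at 0.8, blobs up to 1
  col_im <- ifelse(col, 0.8, 0)
  sma_im <- ifelse(sma, 0.8, 0)
  wz <- if (n_z == 1L) 1 else exp(-((seq_len(n_z) - (n_z + 1) / 2)^2) /
                                  (2 * (n_z / 3)^2))
  wz <- wz / max(wz)
  mk_stack <- function(im2d) {
    arr <- array(0, dim = c(n_z, ny, nx))
    for (z in seq_len(n_z)) arr[z, , ] <- im2d * wz[z]
    arr
  }
  channels <- list(collagen4 = mk_stack(col_im), sma = mk_stack(sma_im),
                   abeta = mk_stack(ab))
  if (noise$gaussian_sd > 0 || noise$poisson_scale > 0) {
    channels <- local_seed(seed, lapply(channels, function(arr) {
      if (noise$poisson_scale > 0)
        arr[] <- rpois(length(arr), arr * noise$poisson_scale) /
          noise$poisson_scale
      if (noise$gaussian_sd > 0)
        arr[] <- arr + rnorm(length(arr), 0, noise$gaussian_sd)
      pmax(arr, 0)
    }))
  }
  stack <- zstack_image(channels, scene$pixel_size_um)
  list(stack = stack,
       truth = list(collagen4 = col, sma = sma, abeta = ab_mask,
                    arteriole_labels = art_labels,
                    capillary_labels = cap_labels,
                    vessels = vessels, aggregates = aggregates),
       scene = scene)
}

#' Simulate a rendered image study
#'
#' Renders one scene per image for every mouse, runs the measurement
#' pipeline on the maximum projections, and assembles the hierarchical
#' study table. Ground-truth structure counts are drawn from the
#' configuration; the per-image seed is derived deterministically from
#' `seed`.
#'
#' @param config a [study_config()].
#' @param seed RNG seed.
#' @param seg_params,det_params pipeline parameters.
#' @return A list with `study` (a `study_table`), `truth` (per-image
#'   ground-truth lists), and `n_images`.
#' @export
simulate_image_study <- function(config = study_config(), seed = config$seed,
                                 seg_params = segmentation_params(),
                                 det_params = detection_params()) {
  groups <- rep(c("control", "clu"), each = config$mice_per_group)
  vrows <- list(); arows <- list(); truth <- list()
  img_n <- 0L
  for (m in seq_along(groups)) {
    for (j in seq_len(config$images_per_mouse)) {
      img_n <- img_n + 1L
      sc_seed <- (seed * 10007L + img_n * 101L) %% .Machine$integer.max
      scene <- synthetic_scene(
        shape = config$image_shape, pixel_size_um = config$pixel_size_um,
        n_arterioles = config$arterioles_per_image,
        n_capillaries = config$capillaries_per_image,
        n_intramural = config$intramural_per_image,
        n_extramural = config$extramural_per_image,
        arteriole_outer_um = config$arteriole_outer_um,
        wall_um = config$wall_um,
        capillary_width_um = config$capillary_width_um,
        seed = sc_seed)
      ren <- render_synthetic_image(scene, n_z = config$n_z,
                                    noise = config$noise, seed = sc_seed + 1L)
      proj <- max_project(ren$stack)
      image_id <- sprintf("m%02d_i%02d", m, j)
      meas <- measure_image(proj, seg_params, det_params, image_id = image_id)
      if (nrow(meas$vessels) > 0)
        vrows[[length(vrows) + 1L]] <- tibble(
          group = groups[m], mouse_id = sprintf("m%02d", m), meas$vessels)
      if (nrow(meas$aggregates) > 0)
        arows[[length(arows) + 1L]] <- tibble(
          group = groups[m], mouse_id = sprintf("m%02d", m), meas$aggregates)
      truth[[image_id]] <- ren$truth
    }
  }
  empty_v <- tibble(group = character(), mouse_id = character(),
                    image_id = character(), vessel_id = character(),
                    kind = character(), wall_area_px = integer(),
                    abeta_px = integer(), coverage_pct = numeric())
  empty_a <- tibble(group = character(), mouse_id = character(),
                    image_id = character(), agg_id = integer(),
                    size_px = integer(), compartment = character())
  vessels <- if (length(vrows)) dplyr::bind_rows(vrows) else empty_v
  aggregates <- if (length(arows)) dplyr::bind_rows(arows) else empty_a
  list(study = build_study_table(vessels, aggregates), truth = truth,
       n_images = img_n)
}
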
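# Independent oracles and fixture builders shared across the test files.
# Everything here deliberately avoids the package's own computational paths
# (brute-force loops, quadrature, plain simulation), so agreement between
# the two routes is informative.

# --- geometry fixtures ------------------------------------------------------

# annulus mask on an ny x nx grid; gap_deg > 0 cuts an angular gap
make_annulus <- function(ny, nx, cy, cx, r_out, r_in, gap_deg = 0) {
  yy <- matrix(seq_len(ny), ny, nx) - cy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  d2 <- yy^2 + xx^2
  m <- d2 <= r_out^2 & d2 > r_in^2
  if (gap_deg > 0) {
    ang <- atan2(yy, xx)
    m <- m & !(abs(ang) <= gap_deg * pi / 360)
  }
  m
}

make_disk <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny), ny, nx) - cy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  yy^2 + xx^2 <= r^2
}

# search an outer radius whose rendered annulus wall area falls in a window
annulus_with_area <- function(target_lo, target_hi, wall = 3, ny = 64, nx = 64) {
  for (r_out in seq(4, 25, by = 0.1)) {
    m <- make_annulus(ny, nx, ny / 2, nx / 2, r_out, r_out - wall)
    a <- sum(m)
    if (a >= target_lo && a <= target_hi) return(list(mask = m, area = a))
  }
  stop("no radius found for the requested area window")
}

# --- grayscale morphology oracle -------------------------------------------

# brute-force erosion/dilation with the same disc brush EBImage uses
brush_offsets <- function(radius) {
  b <- EBImage::makeBrush(2L * radius + 1L, "disc")
  w <- which(b > 0, arr.ind = TRUE)
  cbind(w[, 1] - (radius + 1L), w[, 2] - (radius + 1L))
}

bf_erode <- function(img, off) {
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    yy <- i + off[, 1]; xx <- j + off[, 2]
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    out[i, j] <- min(img[cbind(yy[ok], xx[ok])])
  }
  out
}

bf_dilate <- function(img, off) {
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    yy <- i + off[, 1]; xx <- j + off[, 2]
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    out[i, j] <- max(img[cbind(yy[ok], xx[ok])])
  }
  out
}

bf_white_top_hat <- function(img, radius) {
  off <- brush_offsets(radius)
  img - bf_dilate(bf_erode(img, off), off)
}

# --- compound Poisson-gamma simulation oracle -------------------------------

# written from the definition, independent of rtweedie_cpg
oracle_cpg_draws <- function(n, mu, phi, p) {
  lambda <- mu^(2 - p) / (phi * (2 - p))
  alpha <- (2 - p) / (p - 1)
  theta <- phi * (p - 1) * mu^(p - 1)
  N <- stats::rpois(n, lambda)
  out <- numeric(n)
  pos <- which(N > 0)
  out[pos] <- stats::rgamma(length(pos), shape = N[pos] * alpha, scale = theta)
  out
}

# --- quadrature of the zero-inflated Beta continuous part -------------------

# integral of dzibeta over (0, 1), with the power substitutions z = y^a
# (near 0) and z = (1 - y)^b (near 1) that make the integrand finite at
# singular endpoints (Beta shapes below 1). Where the back-transformed y
# would round to exactly 0 or 1 in double precision (y within eps of the
# endpoint, a z-interval on which the transformed integrand is constant to
# relative ~eps), the sliver is completed analytically; everywhere else
# the integrand is the package's own density.
zib_continuous_mass <- function(mu, phi, pi0, rel.tol = 1e-10) {
  a <- mu * phi; b <- (1 - mu) * phi
  f <- function(y) dzibeta(y, mu, phi, pi0)
  logC <- lgamma(a + b) - lgamma(a) - lgamma(b)
  eps <- 1e-14
  g_lo <- function(z) f(pmax(z^(1 / a), eps)) * z^(1 / a - 1) / a
  g_hi <- function(z) f(pmin(1 - z^(1 / b), 1 - eps)) * z^(1 / b - 1) / b
  z0_lo <- eps^a
  z0_hi <- eps^b
  tail_lo <- (1 - pi0) * exp(logC) * z0_lo / a   # y in (0, eps)
  tail_hi <- (1 - pi0) * exp(logC) * z0_hi / b   # y in (1 - eps, 1)
  tail_lo +
    stats::integrate(g_lo, z0_lo, mu^a, rel.tol = rel.tol,
                     subdivisions = 500L)$value +
    tail_hi +
    stats::integrate(g_hi, z0_hi, (1 - mu)^b, rel.tol = rel.tol,
                     subdivisions = 500L)$value
}

# --- nested Gauss-Hermite quadrature oracle ---------------------------------

# marginal log-likelihood by nested adaptive Gauss-Hermite quadrature
# (nodes centred on the standard-normal scale; 50 nodes are ample for the
# tiny fixtures this is used on)
gh_marginal_loglik <- function(data, params, family, nodes = 50) {
  gh <- pracma::gaussHermite(nodes)
  zk <- sqrt(2) * gh$x
  dens1 <- function(y, eta) {
    if (family == "zibeta")
      dzibeta(y, stats::plogis(eta), params$phi, stats::plogis(params$gamma0))
    else
      dtweedie_cpg(y, exp(eta), params$phi, params$p)
  }
  grp <- as.character(data$group)
  ref <- if ("control" %in% grp) "control" else sort(unique(grp))[1]
  x <- as.numeric(grp != ref)
  ll <- 0
  for (m in unique(data$mouse_id)) {
    sel <- data$mouse_id == m
    outer_vals <- vapply(zk, function(s) {
      val <- 1
      for (img in unique(data$image_id[sel])) {
        seli <- which(sel & data$image_id == img)
        inner <- vapply(zk, function(tt) {
          eta <- params$beta0 + params$beta1 * x[seli] +
            params$sigma_mouse * s + params$sigma_image * tt
          prod(mapply(dens1, data$value[seli], eta))
        }, numeric(1))
        val <- val * sum(gh$w * inner) / sqrt(pi)
      }
      val
    }, numeric(1))
    ll <- ll + log(sum(gh$w * outer_vals) / sqrt(pi))
  }
  ll
}

# fast controls used throughout the fit tests
fast_control <- function(seed = 1L, ...) {
  glmm_control(n_restarts = 1L, seed = seed, p_grid = c(1.4, 1.6, 1.8), ...)
}
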
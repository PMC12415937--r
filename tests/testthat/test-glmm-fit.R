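# generative parameter sets at the study's design scale
gen_zib <- list(beta0 = qlogis(0.10), beta1 = -0.24, phi = 3,
                gamma0 = qlogis(0.35), sigma_mouse = 0.4, sigma_image = 0.3)
gen_tw <- list(beta0 = log(12), beta1 = -0.56, phi = 2, p = 1.6,
               sigma_mouse = 0.3, sigma_image = 0.2)

test_that("Wald statistics reproduce the worked examples and definitions", {
  w1 <- wald_test(-0.242, 0.234)
  expect_equal(w1$z, -1.033, tolerance = 0.01)
  w2 <- wald_test(-0.557, 0.243)
  expect_equal(w2$z, -2.295, tolerance = 0.01)
  w0 <- wald_test(0, 1.7)
  expect_equal(w0$z, 0)
  expect_equal(w0$p, 1)
  expect_error(wald_test(1, 0), "positive")
  expect_error(wald_test(1, -2), "positive")
})

test_that("a single study-scale fit recovers the generating parameters", {
  d <- simulate_glmm_data(gen_zib, "zibeta", 8, 6, 12, seed = 61)
  f <- fit_zib_glmm(d, fast_control())
  expect_true(f$converged)
  expect_equal(f$coefficients$estimate[1], gen_zib$beta0, tolerance = 0.35)
  expect_equal(f$coefficients$estimate[2], gen_zib$beta1, tolerance = 0.45)
  expect_equal(f$coefficients$estimate[3], gen_zib$gamma0, tolerance = 0.3)
  expect_equal(unname(f$varcomp["phi"]), gen_zib$phi, tolerance = 0.8)
  # z is estimate/SE to machine precision
  expect_equal(f$coefficients$z,
               f$coefficients$estimate / f$coefficients$se)

  dt <- simulate_glmm_data(gen_tw, "tweedie", 8, 6, 12, seed = 62)
  ft <- fit_tweedie_glmm(dt, fast_control())
  expect_true(ft$converged)
  expect_equal(ft$coefficients$estimate[1], gen_tw$beta0, tolerance = 0.3)
  expect_equal(ft$coefficients$estimate[2], gen_tw$beta1, tolerance = 0.45)
  expect_equal(unname(ft$varcomp["p"]), gen_tw$p, tolerance = 0.15)
  expect_equal(ft$coefficients$z,
               ft$coefficients$estimate / ft$coefficients$se)
})

test_that("degenerate inputs are rejected", {
  d <- simulate_glmm_data(gen_zib, "zibeta", 2, 2, 4, seed = 63)
  d$value <- 0
  expect_error(fit_zib_glmm(d, fast_control()), "unidentified")
  d$value <- 1.2
  expect_error(fit_zib_glmm(d, fast_control()), "\\[0, 1\\]")
  dt <- simulate_glmm_data(gen_tw, "tweedie", 2, 2, 4, seed = 64)
  dt$value[3] <- -5
  expect_error(fit_tweedie_glmm(dt, fast_control()), "nonnegative")
})

test_that("full coverage is squeezed before the Beta component sees it", {
  d <- simulate_glmm_data(gen_zib, "zibeta", 3, 3, 8, seed = 65)
  d$value[which.max(d$value)] <- 1
  f <- suppressWarnings(fit_zib_glmm(d, fast_control()))
  expect_s3_class(f, "caaq_glmm")
  expect_true(is.finite(f$loglik))
})

test_that("sigma = 0 data reduce to a fixed-effects-only Tweedie fit", {
  p0 <- modifyList(gen_tw, list(sigma_mouse = 0, sigma_image = 0))
  d <- simulate_glmm_data(p0, "tweedie", 4, 3, 15, seed = 66)
  f <- suppressWarnings(fit_tweedie_glmm(d, fast_control()))
  # independent fixed-effects-only fit: direct optimisation of the summed
  # density (no hierarchy involved)
  x <- as.numeric(d$group != "control")
  nll_fe <- function(th) {
    p <- 1 + min(max(plogis(th[4]), 1e-6), 1 - 1e-6)
    -sum(dtweedie_cpg(d$value, exp(th[1] + th[2] * x), exp(th[3]), p,
                      log = TRUE))
  }
  fe <- optim(c(log(mean(d$value)), 0, 0, 0), nll_fe, method = "BFGS")
  expect_equal(f$coefficients$estimate[1], fe$par[1], tolerance = 0.02)
  expect_equal(f$coefficients$estimate[2], fe$par[2], tolerance = 0.02)
  # the collapsed variance components sit at (numerically) zero
  expect_lt(unname(f$varcomp["sigma_mouse"]), 0.05)
})

test_that("estimated marginal means invert the link at the group predictors", {
  mk_fit <- function(family, par, zi_group = FALSE) {
    k <- length(par)
    structure(list(family = family, par = par,
                   vcov = diag(1e-4, k), converged = TRUE, note = NULL,
                   control = glmm_control(zi_group = zi_group),
                   groups = c("control", "clu")),
              class = "caaq_glmm")
  }
  # logit link, beta0 = beta1 = 0 -> conditional means 0.5 for both groups
  fz <- mk_fit("zibeta", c(0, 0, qlogis(0.3), log(2), -10, -10))
  em <- estimated_marginal_means(fz, type = "conditional")
  expect_equal(em$mean, c(0.5, 0.5))
  # overall mean multiplies in the zero part: (1 - 0.3) * 0.5
  emo <- estimated_marginal_means(fz, type = "overall")
  expect_equal(emo$mean, c(0.35, 0.35), tolerance = 1e-6)

  # log link with beta0 = 0, beta1 = log 2 -> means 1 and 2
  ft <- mk_fit("tweedie", c(0, log(2), log(1), 0, -10, -10))
  emt <- estimated_marginal_means(ft)
  expect_equal(emt$mean, c(1, 2), tolerance = 1e-8)
  expect_true(all(emt$ci_low <= emt$mean & emt$mean <= emt$ci_high))
})

test_that("delta-method intervals track a parametric bootstrap at sigma = 0", {
  p0 <- modifyList(gen_tw, list(sigma_mouse = 0, sigma_image = 0))
  d <- simulate_glmm_data(p0, "tweedie", 2, 1, 60, seed = 67)
  f <- suppressWarnings(fit_tweedie_glmm(d, fast_control()))
  em <- f$emmeans
  # bootstrap: resimulate at the fitted parameters, refit, collect emmeans
  nb <- 150
  boot <- local({
    set.seed(99)
    hat <- list(beta0 = f$coefficients$estimate[1],
                beta1 = f$coefficients$estimate[2],
                phi = unname(f$varcomp["phi"]), p = unname(f$varcomp["p"]),
                sigma_mouse = 0, sigma_image = 0)
    t(vapply(seq_len(nb), function(b) {
      db <- simulate_glmm_data(hat, "tweedie", 2, 1, 60, seed = 7000 + b)
      fb <- suppressWarnings(fit_tweedie_glmm(db, fast_control()))
      # response-scale group means straight from the log-link coefficients
      exp(c(fb$coefficients$estimate[1],
            sum(fb$coefficients$estimate[1:2])))
    }, numeric(2)))
  })
  for (g in 1:2) {
    bs_ci <- quantile(boot[, g], c(0.025, 0.975), names = FALSE)
    expect_equal(em$ci_low[g], bs_ci[1], tolerance = 0.1 * em$mean[g])
    expect_equal(em$ci_high[g], bs_ci[2], tolerance = 0.1 * em$mean[g])
  }
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  d <- simulate_glmm_data(gen_tw, "tweedie", 5, 5, 10, seed = 68)
  f <- fit_tweedie_glmm(d, fast_control())
  g <- suppressWarnings(glmmTMB::glmmTMB(
    value ~ group + (1 | mouse_id / image_id),
    family = glmmTMB::tweedie(),
    data = transform(d, group = factor(group, levels = c("control", "clu")))))
  sg <- summary(g)$coefficients$cond
  expect_equal(f$coefficients$estimate[2], sg[2, 1], tolerance = 0.02)
  expect_equal(f$coefficients$se[2], sg[2, 2], tolerance = 0.05 * abs(sg[2, 2]) + 0.01)

  dz <- simulate_glmm_data(gen_zib, "zibeta", 5, 5, 10, seed = 69)
  fz <- fit_zib_glmm(dz, fast_control())
  gz <- suppressWarnings(glmmTMB::glmmTMB(
    value ~ group + (1 | mouse_id / image_id), ziformula = ~1,
    family = glmmTMB::beta_family(),
    data = transform(dz, group = factor(group, levels = c("control", "clu")))))
  sgz <- summary(gz)$coefficients$cond
  expect_equal(fz$coefficients$estimate[2], sgz[2, 1], tolerance = 0.03)
  expect_equal(fz$coefficients$se[2], sgz[2, 2],
               tolerance = 0.05 * abs(sgz[2, 2]) + 0.01)
})
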
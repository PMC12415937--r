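## Hierarchical models: zero-inflated Beta GLMM (vessel coverage) and
## Tweedie GLMM (aggregate size), nested mouse/image random intercepts
## integrated out by Laplace approximation (see src/glmm.cpp).

# run expr with a local, seeded RNG stream, restoring the caller's state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Validate and encode the hierarchical layout. `data` needs columns
# value, group, mouse_id, image_id; group is encoded 0 = reference
# ("control" when present, else first sorted level), 1 = treatment.
encode_model_data <- function(data) {
  need <- c("value", "group", "mouse_id", "image_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop("no observations")
  grp <- as.character(data$group)
  levels <- unique(grp)
  ref <- if ("control" %in% levels) "control" else sort(levels)[1]
  if (length(levels) > 2) stop("only two groups are supported")
  x <- as.numeric(grp != ref)
  mouse <- match(data$mouse_id, unique(data$mouse_id)) - 1L
  # image ids are interpreted nested within mouse (same label under two
  # mice means two distinct images)
  image_key <- paste(data$mouse_id, data$image_id, sep = "\r")
  image <- match(image_key, unique(image_key)) - 1L
  gm <- split(x, mouse)
  if (any(vapply(gm, function(v) length(unique(v)), integer(1)) > 1))
    stop("a mouse_id maps to more than one group")
  list(y = as.numeric(data$value), x = x, mouse = mouse, image = image,
       n_mouse = max(mouse) + 1L, n_image = max(image) + 1L,
       ref = ref, trt = setdiff(levels, ref))
}

glmm_nll_eval <- function(enc, beta0, beta1, phi, sig_m, sig_i, family,
                          p = 1.5, gamma0 = 0, gamma1 = 0, cache = NULL) {
  offset <- beta0 + beta1 * enc$x
  zi_lp <- gamma0 + gamma1 * enc$x
  fam <- if (family == "zibeta") 1L else 2L
  cpp_glmm_nll(enc$y, offset, zi_lp, enc$mouse, enc$image,
               enc$n_mouse, enc$n_image, phi, p, sig_m, sig_i, fam,
               if (is.null(cache)) NULL else cache)
}

#' Laplace-approximated marginal log-likelihood
#'
#' Marginal log-likelihood of a two-group GLMM with nested Gaussian random
#' intercepts (mouse, and image within mouse), the random effects
#' integrated out by a Laplace approximation around the per-mouse joint
#' mode (inner Newton iterations, tolerance 1e-8). With both random-effect
#' SDs equal to zero the result is exact: the sum of per-observation log
#' densities.
#'
#' @param data data frame with columns `value`, `group`, `mouse_id`,
#'   `image_id`. For `family = "zibeta"` the values must lie in `[0, 1)`
#'   (squeeze full coverage first); for `"tweedie"` they must be
#'   nonnegative.
#' @param params named list of parameters. For `"zibeta"`: `beta0`,
#'   `beta1` (logit-scale fixed effects of the conditional Beta mean),
#'   `phi` (precision), `gamma0` and optional `gamma1` (logit-scale
#'   zero-inflation coefficients), `sigma_mouse`, `sigma_image`. For
#'   `"tweedie"`: `beta0`, `beta1` (log scale), `phi` (dispersion), `p`
#'   (power in (1, 2)), `sigma_mouse`, `sigma_image`.
#' @param family `"zibeta"` or `"tweedie"`.
#' @return The marginal log-likelihood (scalar).
#' @export
laplace_marginal_loglik <- function(data, params, family = c("zibeta", "tweedie")) {
  family <- match.arg(family)
  enc <- encode_model_data(data)
  stopifnot(params$phi > 0, params$sigma_mouse >= 0, params$sigma_image >= 0)
  if (family == "tweedie" && !(params$p > 1 && params$p < 2))
    stop("`p` must lie in (1, 2)")
  g1 <- if (!is.null(params$gamma1)) params$gamma1 else 0
  nll <- glmm_nll_eval(enc, params$beta0, params$beta1, params$phi,
                       params$sigma_mouse, params$sigma_image, family,
                       p = if (is.null(params$p)) 1.5 else params$p,
                       gamma0 = if (is.null(params$gamma0)) 0 else params$gamma0,
                       gamma1 = g1)
  if (!is.finite(nll))
    stop("non-finite inner objective; check parameter values and responses")
  -nll
}

#' Optimiser settings for the GLMM fits
#'
#' @param n_restarts number of random restarts of the outer quasi-Newton
#'   optimisation (>= 1; the first start is deterministic, the rest are
#'   jittered).
#' @param seed seed for the restart jitter (does not touch the caller's
#'   RNG stream).
#' @param zi_group should the experimental group enter the zero-inflation
#'   linear predictor? Default `FALSE` (intercept-only zero part).
#' @param squeeze `"auto"` (squeeze nonzero proportions only when a value
#'   of exactly 1 is present), `"always"`, or `"never"`.
#' @param p_grid Tweedie power values profiled before the joint
#'   refinement.
#' @param maxit outer iteration cap per start.
#' @param restart_sd SD of the restart jitter.
#' @return A list of class `glmm_control`.
#' @export
glmm_control <- function(n_restarts = 3L, seed = 1L, zi_group = FALSE,
                         squeeze = c("auto", "always", "never"),
                         p_grid = c(1.2, 1.35, 1.5, 1.65, 1.8),
                         maxit = 500L, restart_sd = 0.3) {
  squeeze <- match.arg(squeeze)
  stopifnot(n_restarts >= 1, all(p_grid > 1 & p_grid < 2))
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 zi_group = isTRUE(zi_group), squeeze = squeeze,
                 p_grid = p_grid, maxit = as.integer(maxit),
                 restart_sd = restart_sd),
            class = "glmm_control")
}

# outer optimisation with restarts; obj maps the full parameter vector to
# the penalised nll. Returns the best nlminb result.
optimise_restarts <- function(obj, start, lower, upper, control) {
  starts <- list(start)
  if (control$n_restarts > 1) {
    jit <- local_seed(control$seed, {
      lapply(seq_len(control$n_restarts - 1L), function(i)
        start + rnorm(length(start), sd = control$restart_sd))
    })
    starts <- c(starts, lapply(jit, function(s) pmin(pmax(s, lower), upper)))
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      nlminb(s, obj, lower = lower, upper = upper,
             control = list(iter.max = control$maxit, eval.max = 4L * control$maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimiser starts failed")
  best
}

numeric_grad <- function(fn, par, eps = 1e-5) {
  vapply(seq_along(par), function(k) {
    h <- eps * max(1, abs(par[k]))
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    (fn(pp) - fn(pm)) / (2 * h)
  }, numeric(1))
}

# SEs from the observed-information inverse. Parameters that ended on a
# box bound (typically a random-effect log-SD collapsing to zero) carry no
# usable curvature; they are held fixed and the information is computed
# over the free parameters only (their vcov rows/columns are NA).
# Returns list(vcov, ok, free, grad_ok).
information_vcov <- function(obj, par, lower, upper, eps = 1e-6) {
  free <- which(par > lower + eps & par < upper - eps)
  g <- numeric_grad(obj, par)
  at_lo <- par <= lower + eps
  at_hi <- par >= upper - eps
  grad_ok <- all(abs(g[free]) < 0.05) &&
    all(g[at_lo] > -0.05) && all(g[at_hi] < 0.05)
  k <- length(par)
  V <- matrix(NA_real_, k, k)
  if (length(free) == 0) return(list(vcov = V, ok = FALSE, free = free,
                                     grad_ok = grad_ok))
  objf <- function(pf) { pp <- par; pp[free] <- pf; obj(pp) }
  H <- tryCatch(optimHess(par[free], objf), error = function(e) NULL)
  if (is.null(H)) return(list(vcov = V, ok = FALSE, free = free,
                              grad_ok = grad_ok))
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || any(ev <= 0)) {
    sv <- svd(H)   # pseudo-inverse fallback; flagged as non-converged
    d <- ifelse(sv$d > max(sv$d) * 1e-10, 1 / sv$d, 0)
    V[free, free] <- sv$v %*% diag(d, length(d)) %*% t(sv$u)
    return(list(vcov = V, ok = FALSE, free = free, grad_ok = grad_ok))
  }
  V[free, free] <- solve(H)
  list(vcov = V, ok = TRUE, free = free, grad_ok = grad_ok)
}

new_glmm_fit <- function(family, coefs, varcomp, loglik, converged, vcov,
                         par, par_names, enc, control, note = NULL) {
  fit <- structure(list(family = family, coefficients = coefs,
                        varcomp = varcomp, loglik = loglik,
                        converged = converged, vcov = vcov, par = par,
                        par_names = par_names,
                        groups = c(enc$ref, enc$trt), control = control,
                        n_obs = length(enc$y), n_mouse = enc$n_mouse,
                        n_image = enc$n_image, note = note),
                   class = "caaq_glmm")
  fit$emmeans <- tryCatch(estimated_marginal_means(fit),
                          error = function(e) NULL)
  fit
}

#' Fit the zero-inflated Beta GLMM for vessel coverage
#'
#' Maximises the Laplace-approximated marginal likelihood of the
#' zero-inflated Beta model: a logistic component for the probability of
#' exactly zero coverage (fixed effects only, intercept-only by default)
#' and a Beta regression component (logit link, precision `phi`) for the
#' nonzero proportions, with nested mouse/image random intercepts on the
#' Beta mean. Standard errors come from the observed-information inverse;
#' Wald z and two-sided p are reported per fixed effect.
#'
#' @param data data frame with columns `value` (coverage as a proportion
#'   in `[0, 1]`), `group`, `mouse_id`, `image_id`.
#' @param control a [glmm_control()] list.
#' @return An object of class `caaq_glmm`.
#' @export
fit_zib_glmm <- function(data, control = glmm_control()) {
  enc <- encode_model_data(data)
  y <- enc$y
  if (any(y < 0 | y > 1)) stop("coverage responses must lie in [0, 1]")
  if (all(y == 0))
    stop("all responses are zero: the Beta component is unidentified")
  if (control$squeeze == "always" || (control$squeeze == "auto" && any(y == 1)))
    y <- squeeze_proportions(y)
  if (any(y == 1))
    stop("responses equal to 1 present; use squeeze = \"auto\" or \"always\"")
  enc$y <- y

  zi_group <- control$zi_group
  pn <- c("beta0", "beta1", if (zi_group) c("gamma0", "gamma1") else "gamma0",
          "log_phi", "log_sigma_mouse", "log_sigma_image")
  unpack <- function(par) {
    i <- if (zi_group) 1L else 0L
    list(beta0 = par[1], beta1 = par[2], gamma0 = par[3],
         gamma1 = if (zi_group) par[4] else 0,
         phi = exp(par[4 + i]), sig_m = exp(par[5 + i]),
         sig_i = exp(par[6 + i]))
  }
  cache <- cpp_glmm_cache()
  obj <- function(par) {
    q <- unpack(par)
    v <- glmm_nll_eval(enc, q$beta0, q$beta1, q$phi, q$sig_m, q$sig_i,
                       "zibeta", gamma0 = q$gamma0, gamma1 = q$gamma1,
                       cache = cache)
    if (!is.finite(v)) 1e10 else v
  }

  ypos <- y[y > 0]
  mu0 <- min(max(mean(ypos), 1e-3), 1 - 1e-3)
  v0 <- max(var(ypos), 1e-6)
  phi0 <- max(mu0 * (1 - mu0) / v0 - 1, 0.5)
  start <- c(qlogis(mu0), 0, qlogis(min(max(mean(y == 0), 0.02), 0.98)),
             if (zi_group) 0, log(phi0), log(0.3), log(0.3))
  lower <- c(-30, -30, -30, if (zi_group) -30, -10, -10, -10)
  upper <- c(30, 30, 30, if (zi_group) 30, 10, 3, 3)

  best <- optimise_restarts(obj, start, lower, upper, control)
  par <- best$par
  iv <- information_vcov(obj, par, lower, upper)
  converged <- best$convergence == 0 && iv$ok && iv$grad_ok
  if (!converged)
    warning("zero-inflated Beta GLMM: convergence is questionable; ",
            "inspect the fit (flag is FALSE)")

  q <- unpack(par)
  se <- sqrt(pmax(diag(iv$vcov), 0))
  kfix <- seq_len(if (zi_group) 4L else 3L)
  est <- par[kfix]
  coefs <- tibble(term = c("mu_(Intercept)", "mu_group",
                           if (zi_group) c("zi_(Intercept)", "zi_group") else "zi_(Intercept)"),
                  estimate = est, se = se[kfix],
                  z = est / se[kfix], p = 2 * pnorm(-abs(est / se[kfix])))
  varcomp <- c(sigma_mouse = q$sig_m, sigma_image = q$sig_i, phi = q$phi)
  new_glmm_fit("zibeta", coefs, varcomp, -best$objective, converged,
               iv$vcov, par, pn, enc, control)
}

#' Fit the Tweedie GLMM for aggregate size
#'
#' Maximises the Laplace-approximated marginal likelihood of a Tweedie
#' (compound Poisson-gamma, 1 < p < 2) model with log link and nested
#' mouse/image random intercepts. The power `p` is first profiled over a
#' coarse grid, then refined jointly with the other parameters from the
#' best grid point.
#'
#' @param data data frame with columns `value` (nonnegative sizes),
#'   `group`, `mouse_id`, `image_id`.
#' @param control a [glmm_control()] list.
#' @return An object of class `caaq_glmm`.
#' @export
fit_tweedie_glmm <- function(data, control = glmm_control()) {
  enc <- encode_model_data(data)
  y <- enc$y
  if (any(y < 0)) stop("size responses must be nonnegative")
  if (all(y == 0)) stop("all responses are zero: the mean model is unidentified")

  # parameters: beta0, beta1, log_phi, psi (p = 1 + plogis(psi)), log sds
  pn <- c("beta0", "beta1", "log_phi", "psi_p", "log_sigma_mouse",
          "log_sigma_image")
  unpack <- function(par) list(beta0 = par[1], beta1 = par[2],
                               phi = exp(par[3]), p = 1 + plogis(par[4]),
                               sig_m = exp(par[5]), sig_i = exp(par[6]))
  cache <- cpp_glmm_cache()
  obj <- function(par) {
    q <- unpack(par)
    v <- glmm_nll_eval(enc, q$beta0, q$beta1, q$phi, q$sig_m, q$sig_i,
                       "tweedie", p = q$p, cache = cache)
    if (!is.finite(v)) 1e10 else v
  }
  mu0 <- mean(y[y >= 0])
  lower <- c(-30, -30, -10, qlogis(0.05), -10, -10)
  upper <- c(30, 30, 10, qlogis(0.95), 3, 3)

  # profile p over the grid with a reduced optimisation, then refine jointly
  prof_best <- NULL
  for (pg in control$p_grid) {
    psi <- qlogis(pg - 1)
    phi_g <- max(var(y) / mu0^pg, 1e-3)
    s <- c(log(mu0), 0, log(phi_g), psi, log(0.3), log(0.3))
    robj <- function(par5) obj(c(par5[1:3], psi, par5[4:5]))
    res <- tryCatch(
      nlminb(s[-4], robj, lower = lower[-4], upper = upper[-4],
             control = list(iter.max = control$maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(prof_best) || res$objective < prof_best$objective)
      prof_best <- list(objective = res$objective,
                        par = c(res$par[1:3], psi, res$par[4:5]))
  }
  start <- if (!is.null(prof_best)) prof_best$par else
    c(log(mu0), 0, log(max(var(y) / mu0^1.5, 1e-3)), 0, log(0.3), log(0.3))

  best <- optimise_restarts(obj, start, lower, upper, control)
  par <- best$par
  iv <- information_vcov(obj, par, lower, upper)
  converged <- best$convergence == 0 && iv$ok && iv$grad_ok
  if (!converged)
    warning("Tweedie GLMM: convergence is questionable; inspect the fit ",
            "(flag is FALSE)")

  q <- unpack(par)
  se <- sqrt(pmax(diag(iv$vcov), 0))
  est <- par[1:2]
  coefs <- tibble(term = c("mu_(Intercept)", "mu_group"),
                  estimate = est, se = se[1:2],
                  z = est / se[1:2], p = 2 * pnorm(-abs(est / se[1:2])))
  varcomp <- c(sigma_mouse = q$sig_m, sigma_image = q$sig_i, phi = q$phi,
               p = q$p)
  new_glmm_fit("tweedie", coefs, varcomp, -best$objective, converged,
               iv$vcov, par, pn, enc, control)
}

#' Wald z statistic and two-sided p value
#'
#' @param estimate fixed-effect estimate.
#' @param se its standard error (> 0).
#' @return A list with `z = estimate / se` and `p = 2 * pnorm(-|z|)`.
#' @export
wald_test <- function(estimate, se) {
  if (!is.numeric(se) || any(se <= 0)) stop("`se` must be positive")
  z <- estimate / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Estimated marginal means with 95% confidence intervals
#'
#' Group means predicted by the model at random effects zero. Confidence
#' intervals are delta-method intervals computed on the link scale (log of
#' the mean for the Tweedie and the overall zero-inflated mean; logit for
#' the conditional Beta mean), then transformed back, so they respect the
#' response range. For the zero-inflated Beta model the default reports
#' the overall mean `(1 - pi) * mu`; `type = "conditional"` reports the
#' Beta mean `mu` among nonzero vessels.
#'
#' @param fit a `caaq_glmm` object.
#' @param level confidence level (default 0.95).
#' @param type `"overall"` or `"conditional"` (zero-inflated Beta only).
#' @return A tibble with columns `group`, `mean`, `ci_low`, `ci_high`.
#' @export
estimated_marginal_means <- function(fit, level = 0.95,
                                     type = c("overall", "conditional")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "caaq_glmm"))
  if (!fit$converged && is.null(fit$note))
    stop("fit did not converge; refusing to report marginal means")
  if (is.null(fit$vcov)) stop("no covariance matrix available")
  zq <- qnorm(1 - (1 - level) / 2)
  zi_group <- fit$family == "zibeta" && fit$control$zi_group
  kfix <- if (fit$family == "zibeta") (if (zi_group) 1:4 else 1:3) else 1:2
  V <- fit$vcov[kfix, kfix, drop = FALSE]
  theta <- fit$par[kfix]

  rows <- lapply(c(0, 1), function(x) {
    if (fit$family == "tweedie") {
      h <- function(th) th[1] + th[2] * x          # log mean
      inv <- exp
    } else if (type == "conditional") {
      h <- function(th) th[1] + th[2] * x          # logit conditional mean
      inv <- plogis
    } else {
      h <- function(th) {                          # log overall mean
        zi <- th[3] + (if (zi_group) th[4] else 0) * x
        log1p(-plogis(zi)) + log(plogis(th[1] + th[2] * x))
      }
      inv <- exp
    }
    est <- h(theta)
    gr <- numeric_grad(h, theta)
    se <- sqrt(max(drop(t(gr) %*% V %*% gr), 0))
    tibble(group = fit$groups[x + 1],
           mean = inv(est), ci_low = inv(est - zq * se),
           ci_high = inv(est + zq * se))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.caaq_glmm <- function(x, ...) {
  cat(sprintf("%s GLMM (Laplace), %d obs, %d mice, %d images; logLik %.3f%s\n",
              if (x$family == "zibeta") "Zero-inflated Beta" else "Tweedie",
              x$n_obs, x$n_mouse, x$n_image, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cf <- as.data.frame(x$coefficients)
  cf[, -1] <- lapply(cf[, -1], function(v) signif(v, 4))
  print(cf, row.names = FALSE)
  cat("variance components:",
      paste(names(x$varcomp), signif(x$varcomp, 4), sep = " = ",
            collapse = ", "), "\n")
  if (!is.null(x$emmeans)) {
    cat("estimated marginal means:\n")
    print(as.data.frame(x$emmeans), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.caaq_glmm <- function(object, ...) {
  print(object)
  invisible(object)
}
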
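#' Bar chart of estimated marginal means with 95% CIs
#'
#' Mirrors the study's presentation: one bar per group at the
#' model-estimated marginal mean, error bars at the 95% confidence
#' interval.
#'
#' @param fit a `caaq_glmm` with computed `emmeans`.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_emmeans <- function(fit, title = NULL) {
  em <- fit$emmeans
  if (is.null(em)) stop("fit has no estimated marginal means")
  ylab <- if (fit$family == "zibeta") "estimated mean coverage (proportion)"
          else "estimated mean size (px)"
  ggplot2::ggplot(em, ggplot2::aes(x = .data$group, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = NULL, y = ylab, title = title) +
    ggplot2::theme_minimal()
}

#' Faceted per-mouse boxplots of the raw data
#'
#' One panel per mouse with a boxplot of all units from that animal and
#' the individual data points overlaid (jittered).
#'
#' @param study a `study_table`.
#' @param what `"vessel"` (coverage) or `"aggregate"` (size).
#' @return A ggplot object.
#' @export
plot_mouse_distributions <- function(study, what = c("vessel", "aggregate")) {
  what <- match.arg(what)
  d <- if (what == "vessel") {
    tibble(group = study$vessels$group, mouse_id = study$vessels$mouse_id,
           value = study$vessels$coverage_pct)
  } else {
    tibble(group = study$aggregates$group,
           mouse_id = study$aggregates$mouse_id,
           value = as.numeric(study$aggregates$size_px))
  }
  ylab <- if (what == "vessel") "coverage (%)" else "aggregate size (px)"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.6,
                         show.legend = FALSE) +
    ggplot2::facet_wrap(~mouse_id, nrow = 2) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
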
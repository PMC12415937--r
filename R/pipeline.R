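## Configuration-driven orchestration: simulate -> segment/detect/quantify
## -> fit -> report, with per-stage outputs so downstream stages can be
## rerun on cached upstream files.

#' Validate a pipeline configuration
#'
#' A configuration (R list or YAML file) must contain exactly one of
#' `inputs` (a list of TIFF paths with mouse/group assignments) or
#' `simulation` (arguments for [study_config()]), plus optional
#' `segmentation`, `detection`, `statistics` parameter blocks, `outdir`
#' and `seed`.
#'
#' @param config list or path to a YAML file.
#' @return The validated configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulation)
  if (has_inputs == has_sim)
    stop("config must contain exactly one of `inputs` or `simulation`")
  if (has_inputs) {
    paths <- vapply(config$inputs, function(x) x$path, character(1))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    need <- vapply(config$inputs, function(x)
      all(c("path", "group", "mouse_id", "image_id") %in% names(x)), logical(1))
    if (!all(need))
      stop("each input needs path, group, mouse_id, image_id")
  }
  known_seg <- names(formals(segmentation_params))
  bad <- setdiff(names(config$segmentation), known_seg)
  if (length(bad)) stop("unknown segmentation option(s): ", paste(bad, collapse = ", "))
  known_det <- names(formals(detection_params))
  bad <- setdiff(names(config$detection), known_det)
  if (length(bad)) stop("unknown detection option(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) config$outdir <- "caaquant_out"
  structure(config, class = c("pipeline_config", "list"))
}

write_study_csv <- function(study, outdir) {
  write.csv(study$vessels, file.path(outdir, "vessels.csv"), row.names = FALSE)
  write.csv(study$aggregates, file.path(outdir, "aggregates.csv"),
            row.names = FALSE)
  write.csv(study$exclusions, file.path(outdir, "exclusions.csv"),
            row.names = FALSE)
  write.csv(study_table_tidy(study), file.path(outdir, "study_table.csv"),
            row.names = FALSE)
}

read_study_csv <- function(outdir) {
  study <- build_study_table(
    read.csv(file.path(outdir, "vessels.csv")),
    read.csv(file.path(outdir, "aggregates.csv")))
  ex <- file.path(outdir, "exclusions.csv")
  if (file.exists(ex)) {
    excl <- read.csv(ex)
    if (nrow(excl)) study$exclusions <- as_tibble(excl)
  }
  study
}

fit_summary_list <- function(fit) {
  list(family = fit$family, converged = fit$converged, loglik = fit$loglik,
       coefficients = as.data.frame(fit$coefficients),
       varcomp = as.list(fit$varcomp),
       emmeans = if (!is.null(fit$emmeans)) as.data.frame(fit$emmeans))
}

#' Fit the four study models to a study table
#'
#' Arteriole and capillary coverage (zero-inflated Beta GLMM) and
#' intramural and extramural aggregate size (Tweedie GLMM), after the
#' preprocessing rules: images without detected arterioles are excluded
#' and extreme size outliers (more than 20 times the next-largest value)
#' are removed per compartment.
#'
#' @param study a `study_table`.
#' @param control a [glmm_control()] list.
#' @param outlier_factor multiplier for [remove_extreme_outliers()].
#' @return Named list of `caaq_glmm` fits (`arteriole_coverage`,
#'   `capillary_coverage`, `intramural_size`, `extramural_size`; entries
#'   are `NULL` with a message when a dataset is empty), with an
#'   `outliers` attribute recording removed sizes.
#' @export
fit_study_models <- function(study, control = glmm_control(),
                             outlier_factor = 20) {
  study <- exclude_images_without_arterioles(study)
  v <- study$vessels
  a <- study$aggregates
  removed <- list()
  fits <- list()
  for (kind in c("arteriole", "capillary")) {
    d <- v[v$kind == kind, , drop = FALSE]
    nm <- paste0(kind, "_coverage")
    fits[[nm]] <- if (nrow(d) == 0) NULL else
      fit_zib_glmm(data.frame(value = d$coverage_pct / 100, group = d$group,
                              mouse_id = d$mouse_id, image_id = d$image_id),
                   control)
  }
  for (comp in c("intramural", "extramural")) {
    d <- a[a$compartment == comp, , drop = FALSE]
    nm <- paste0(comp, "_size")
    if (nrow(d) == 0) { fits[[nm]] <- NULL; next }
    ro <- remove_extreme_outliers(d$size_px, outlier_factor)
    removed[[comp]] <- ro$removed
    d <- d[ro$kept_idx, , drop = FALSE]
    fits[[nm]] <- fit_tweedie_glmm(
      data.frame(value = d$size_px, group = d$group,
                 mouse_id = d$mouse_id, image_id = d$image_id), control)
  }
  attr(fits, "outliers") <- removed
  attr(fits, "exclusions") <- study$exclusions
  fits
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (tabular draw from
#' the generative models, or rendered image scenes measured by the image
#' pipeline), `fit` (the four GLMMs with preprocessing), and `report`
#' (estimated-marginal-mean bar charts, per-mouse boxplots, CSV/JSON
#' summaries). Each stage reads and writes only files under `outdir`, so
#' a downstream stage can be rerun against cached upstream output.
#'
#' @param config a [pipeline_config()] (list or YAML path).
#' @param seed overrides `config$seed`.
#' @param outdir overrides `config$outdir`.
#' @param stages subset of `c("simulate", "fit", "report")`.
#' @return Invisibly, a list with the study table, fits and output paths.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL,
                         stages = c("simulate", "fit", "report")) {
  config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(outdir)) config$outdir <- outdir
  stages <- match.arg(stages, c("simulate", "fit", "report"),
                      several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "run_log.txt")
  logmsg <- function(...) cat(sprintf("[%s] %s\n",
                                      format(Sys.time(), "%H:%M:%S"),
                                      sprintf(...)),
                              file = logfile, append = TRUE)
  logmsg("pipeline start; seed = %d; stages: %s", config$seed,
         paste(stages, collapse = ", "))
  seg <- do.call(segmentation_params, as.list(config$segmentation))
  det <- do.call(detection_params, as.list(config$detection))

  study <- NULL
  if ("simulate" %in% stages) {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      tabular <- isTRUE(sim_args$tabular)
      sim_args$tabular <- NULL
      if (!is.null(sim_args$image_shape))
        sim_args$image_shape <- as.integer(unlist(sim_args$image_shape))
      cfg <- do.call(study_config, sim_args)
      if (tabular) {
        logmsg("simulate: tabular study (%d mice/group, %d images/mouse)",
               cfg$mice_per_group, cfg$images_per_mouse)
        study <- simulate_tabular_study(cfg, seed = config$seed)$study
      } else {
        logmsg("simulate: rendered image study (%d x %d px)",
               cfg$image_shape[1], cfg$image_shape[2])
        study <- simulate_image_study(cfg, seed = config$seed,
                                      seg_params = seg, det_params = det)$study
      }
    } else {
      logmsg("measure: %d input image(s)", length(config$inputs))
      vrows <- list(); arows <- list()
      for (inp in config$inputs) {
        stk <- read_zstack(inp$path,
                           pixel_size_um = config$pixel_size_um)
        meas <- measure_image(max_project(stk), seg, det,
                              image_id = inp$image_id)
        if (nrow(meas$vessels))
          vrows[[length(vrows) + 1L]] <- tibble(group = inp$group,
                                                mouse_id = inp$mouse_id,
                                                meas$vessels)
        if (nrow(meas$aggregates))
          arows[[length(arows) + 1L]] <- tibble(group = inp$group,
                                                mouse_id = inp$mouse_id,
                                                meas$aggregates)
      }
      study <- build_study_table(dplyr::bind_rows(vrows),
                                 dplyr::bind_rows(arows))
    }
    write_study_csv(study, config$outdir)
    logmsg("simulate: wrote study tables (%d vessels, %d aggregates)",
           nrow(study$vessels), nrow(study$aggregates))
    # downstream stages always consume the written tables, so a staged
    # rerun on cached output is bit-identical to a full run
    study <- NULL
  }

  fits <- NULL
  if ("fit" %in% stages) {
    if (is.null(study)) study <- read_study_csv(config$outdir)
    stat_args <- config$statistics
    control <- do.call(glmm_control,
                       c(stat_args[setdiff(names(stat_args), "outlier_factor")],
                         list(seed = config$seed)))
    of <- if (!is.null(stat_args$outlier_factor)) stat_args$outlier_factor else 20
    fits <- fit_study_models(study, control, outlier_factor = of)
    summaries <- lapply(Filter(Negate(is.null), fits), fit_summary_list)
    jsonlite::write_json(summaries, file.path(config$outdir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    coefs <- dplyr::bind_rows(lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (is.null(f)) return(NULL)
      tibble(model = nm, f$coefficients)
    }))
    write.csv(coefs, file.path(config$outdir, "fit_coefficients.csv"),
              row.names = FALSE)
    logmsg("fit: %d model(s) fitted", length(Filter(Negate(is.null), fits)))
  }

  if ("report" %in% stages) {
    if (is.null(study)) study <- read_study_csv(config$outdir)
    if (is.null(fits)) stop("report stage needs the fit stage in the same run")
    figdir <- file.path(config$outdir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    for (nm in names(fits)) {
      f <- fits[[nm]]
      if (is.null(f) || is.null(f$emmeans)) next
      ggplot2::ggsave(file.path(figdir, paste0(nm, "_emmeans.png")),
                      plot_emmeans(f, title = nm), width = 4, height = 4,
                      dpi = 120)
    }
    ggplot2::ggsave(file.path(figdir, "coverage_by_mouse.png"),
                    plot_mouse_distributions(study, "vessel"),
                    width = 8, height = 4, dpi = 120)
    if (nrow(study$aggregates))
      ggplot2::ggsave(file.path(figdir, "size_by_mouse.png"),
                      plot_mouse_distributions(study, "aggregate"),
                      width = 8, height = 4, dpi = 120)
    logmsg("report: figures written to %s", figdir)
  }
  logmsg("pipeline done")
  invisible(list(study = study, fits = fits, outdir = config$outdir))
}
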
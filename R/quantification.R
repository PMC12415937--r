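#' Amyloid coverage of a vessel wall
#'
#' Percentage of wall pixels occupied by detected amyloid fluorescence:
#' `100 * |wall AND abeta| / |wall|`.
#'
#' @param wall_mask logical matrix of wall pixels (nonempty).
#' @param abeta_mask logical matrix of detected amyloid pixels, same shape.
#' @return Coverage percentage in `[0, 100]`.
#' @export
vessel_coverage <- function(wall_mask, abeta_mask) {
  if (!identical(dim(wall_mask), dim(abeta_mask)))
    stop("mask shapes differ")
  n_wall <- sum(wall_mask)
  if (n_wall == 0) stop("empty wall mask")
  100 * sum(wall_mask & abeta_mask) / n_wall
}

#' Assign an aggregate to the intramural or extramural compartment
#'
#' Strict-majority rule: an aggregate is intramural when more than half of
#' its pixels lie on the arteriole wall mask, extramural otherwise. With
#' `rule = "any"` a single overlapping pixel suffices.
#'
#' @param agg_mask logical matrix of the aggregate's pixels (nonempty).
#' @param arteriole_wall_mask logical matrix, same shape.
#' @param rule `"majority"` (default) or `"any"`.
#' @return `"intramural"` or `"extramural"`.
#' @export
assign_compartment <- function(agg_mask, arteriole_wall_mask,
                               rule = c("majority", "any")) {
  rule <- match.arg(rule)
  if (!identical(dim(agg_mask), dim(arteriole_wall_mask)))
    stop("mask shapes differ")
  n <- sum(agg_mask)
  if (n == 0) stop("empty aggregate")
  overlap <- sum(agg_mask & arteriole_wall_mask)
  intr <- if (rule == "majority") overlap > 0.5 * n else overlap > 0
  if (intr) "intramural" else "extramural"
}

#' Remove extreme size outliers
#'
#' Prespecified rule: while the largest value is strictly more than
#' `factor` times the next-largest value, remove it. Applied independently
#' per compartment dataset; removed values are returned for audit. The
#' rule is idempotent and leaves sets of fewer than two values unchanged.
#'
#' @param sizes numeric vector of aggregate sizes.
#' @param factor multiplier defining "extreme" (> 1; default 20).
#' @return A list with elements `kept`, `removed` (values, original
#'   relative order) and the corresponding index vectors `kept_idx`,
#'   `removed_idx`.
#' @export
remove_extreme_outliers <- function(sizes, factor = 20) {
  if (!is.numeric(factor) || factor <= 1) stop("`factor` must exceed 1")
  idx <- seq_along(sizes)
  removed_idx <- integer(0)
  repeat {
    if (length(idx) < 2) break
    ord <- order(sizes[idx], decreasing = TRUE)
    if (sizes[idx[ord[1]]] > factor * sizes[idx[ord[2]]]) {
      removed_idx <- c(removed_idx, idx[ord[1]])
      idx <- idx[-ord[1]]
    } else break
  }
  list(kept = sizes[idx], removed = sizes[removed_idx],
       kept_idx = idx, removed_idx = removed_idx)
}

#' Exclude images in which no arteriole was detected
#'
#' Images where segmentation found zero arterioles cannot support
#' arteriole-level analyses (their "extramural" deposits may be
#' misclassified), so their vessel rows of kind `arteriole` and all their
#' aggregate rows are dropped from the respective analyses. Exclusions are
#' logged.
#'
#' @param study a `study_table` (see [build_study_table()]).
#' @return The filtered `study_table` with an `exclusions` tibble attached
#'   (`image_id`, `reason`).
#' @export
exclude_images_without_arterioles <- function(study) {
  stopifnot(inherits(study, "study_table"))
  vess <- study$vessels
  all_imgs <- unique(c(vess$image_id, study$aggregates$image_id))
  art_imgs <- unique(vess$image_id[vess$kind == "arteriole"])
  bad <- setdiff(all_imgs, art_imgs)
  excl <- tibble(image_id = bad,
                 reason = rep("no arterioles detected", length(bad)))
  study$vessels <- vess[!(vess$kind == "arteriole" & vess$image_id %in% bad), ,
                        drop = FALSE]
  study$aggregates <- study$aggregates[!(study$aggregates$image_id %in% bad), ,
                                       drop = FALSE]
  study$exclusions <- rbind(study$exclusions, excl)
  study
}

#' Assemble a hierarchical study table
#'
#' Long-format records feeding the mixed models: one row per vessel
#' (coverage analysis) and one row per aggregate (size analysis), each
#' carrying its group / mouse / image nesting identifiers.
#'
#' @param vessels tibble with columns `group`, `mouse_id`, `image_id`,
#'   `vessel_id`, `kind`, `wall_area_px`, `abeta_px`, `coverage_pct`.
#' @param aggregates tibble with columns `group`, `mouse_id`, `image_id`,
#'   `agg_id`, `size_px`, `compartment`.
#' @return An object of class `study_table`.
#' @export
build_study_table <- function(vessels, aggregates) {
  vessels <- as_tibble(vessels)
  aggregates <- as_tibble(aggregates)
  maps <- rbind(vessels[c("group", "mouse_id", "image_id")],
                aggregates[c("group", "mouse_id", "image_id")])
  img_map <- unique(maps[c("mouse_id", "image_id")])
  if (anyDuplicated(img_map$image_id))
    stop("an image_id maps to more than one mouse_id")
  mouse_map <- unique(maps[c("group", "mouse_id")])
  if (anyDuplicated(mouse_map$mouse_id))
    stop("a mouse_id maps to more than one group")
  if (nrow(vessels) > 0 &&
      any(vessels$abeta_px > vessels$wall_area_px, na.rm = TRUE))
    stop("abeta_px cannot exceed wall_area_px")
  structure(list(vessels = vessels, aggregates = aggregates,
                 exclusions = tibble(image_id = character(),
                                     reason = character())),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d vessel row(s), %d aggregate row(s), %d exclusion(s)\n",
              nrow(x$vessels), nrow(x$aggregates), nrow(x$exclusions)))
  invisible(x)
}

#' Flatten a study table to one tidy data frame
#'
#' One row per analysis unit with columns `group`, `mouse_id`, `image_id`,
#' `unit_id`, `unit` (vessel kind or aggregate compartment) and `value`
#' (coverage percentage or size in pixels).
#'
#' @param study a `study_table`.
#' @return A tibble.
#' @export
study_table_tidy <- function(study) {
  stopifnot(inherits(study, "study_table"))
  v <- study$vessels
  a <- study$aggregates
  rbind(
    tibble(group = v$group, mouse_id = v$mouse_id, image_id = v$image_id,
           unit_id = paste0("vessel_", v$image_id, "_", v$vessel_id),
           unit = v$kind, value = v$coverage_pct),
    tibble(group = a$group, mouse_id = a$mouse_id, image_id = a$image_id,
           unit_id = paste0("agg_", a$image_id, "_", a$agg_id),
           unit = a$compartment, value = as.numeric(a$size_px)))
}

#' Measure one projected image
#'
#' Runs segmentation and amyloid detection on a projected image and
#' returns per-vessel coverage and per-aggregate size/compartment records.
#'
#' @param proj a [projected_image].
#' @param seg_params a [segmentation_params()] list.
#' @param det_params a [detection_params()] list.
#' @param image_id identifier recorded in the output rows.
#' @return A list with `vessels` and `aggregates` tibbles (without group /
#'   mouse identifiers, added by the caller), plus the segmentation and
#'   detection objects.
#' @export
measure_image <- function(proj, seg_params = segmentation_params(),
                          det_params = detection_params(),
                          image_id = "img") {
  stopifnot(inherits(proj, "projected_image"))
  col_mask <- threshold_channel(proj$channels$collagen4,
                                seg_params$threshold_method,
                                seg_params$threshold_value)
  sma_mask <- threshold_channel(proj$channels$sma,
                                seg_params$threshold_method,
                                seg_params$threshold_value)
  arts <- detect_arterioles(col_mask, sma_mask, seg_params,
                            proj$pixel_size_um)
  caps <- derive_capillaries(col_mask, arts, seg_params, proj$pixel_size_um)
  aggs <- detect_amyloid(proj$channels$abeta, det_params)
  abeta_mask <- aggs$labels > 0L

  vrows <- list()
  for (src in list(arts, caps)) {
    if (nrow(src$records) == 0) next
    for (k in seq_len(nrow(src$records))) {
      wall <- src$labels == src$records$vessel_id[k]
      vrows[[length(vrows) + 1L]] <- tibble(
        image_id = image_id,
        vessel_id = paste0(substr(src$records$kind[k], 1, 3), "_",
                           src$records$vessel_id[k]),
        kind = src$records$kind[k],
        wall_area_px = src$records$area_px[k],
        abeta_px = as.integer(sum(wall & abeta_mask)),
        coverage_pct = vessel_coverage(wall, abeta_mask))
    }
  }
  vessels <- if (length(vrows)) dplyr::bind_rows(vrows) else
    tibble(image_id = character(), vessel_id = character(), kind = character(),
           wall_area_px = integer(), abeta_px = integer(),
           coverage_pct = numeric())

  art_mask <- arts$labels > 0L
  arows <- list()
  if (nrow(aggs$records) > 0) {
    for (k in seq_len(nrow(aggs$records))) {
      am <- aggs$labels == aggs$records$agg_id[k]
      arows[[length(arows) + 1L]] <- tibble(
        image_id = image_id, agg_id = aggs$records$agg_id[k],
        size_px = aggs$records$size_px[k],
        compartment = assign_compartment(am, art_mask))
    }
  }
  aggregates <- if (length(arows)) dplyr::bind_rows(arows) else
    tibble(image_id = character(), agg_id = integer(), size_px = integer(),
           compartment = character())

  list(vessels = vessels, aggregates = aggregates,
       arterioles = arts, capillaries = caps, amyloid = aggs)
}
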
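#' Segmentation parameters
#'
#' Thresholds and morphological settings for vessel classification. The
#' area thresholds follow the anatomical rules: an arteriole wall must
#' occupy at least 150 px (about 48.3 um^2 at 0.5676 um/px, derived from
#' the minimum 10-um arteriole diameter) and a capillary fragment at least
#' 29 px (about 9.6 um^2, from a typical 3.5-um capillary). The arteriole
#' mask is dilated by 4 px before subtraction so capillaries are never
#' carved from arteriole edges.
#'
#' @param threshold_method per-channel binarisation: `"otsu"` (default) or
#'   `"fixed"`.
#' @param threshold_value fixed threshold value (required when
#'   `threshold_method = "fixed"`).
#' @param min_arteriole_area_px minimum arteriole wall area, pixels.
#' @param min_capillary_area_px minimum capillary component area, pixels.
#' @param dilation_radius_px radius of the disk used to dilate the
#'   arteriole mask before subtraction.
#' @param copositivity_fraction minimum fraction of an SMA ring's pixels
#'   that must also be Collagen-IV-positive, in (0, 1].
#' @param min_lumen_px minimum enclosed-hole size for a component to count
#'   as a complete ring.
#' @param connectivity pixel connectivity for component labelling (4 or 8).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = "otsu",
                                threshold_value = NULL,
                                min_arteriole_area_px = 150L,
                                min_capillary_area_px = 29L,
                                dilation_radius_px = 4L,
                                copositivity_fraction = 0.5,
                                min_lumen_px = 1L,
                                connectivity = 8L) {
  stopifnot(min_arteriole_area_px >= 0, min_capillary_area_px >= 0,
            dilation_radius_px >= 0, min_lumen_px >= 1,
            connectivity %in% c(4L, 8L))
  if (!(copositivity_fraction > 0 && copositivity_fraction <= 1))
    stop("`copositivity_fraction` must lie in (0, 1]")
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_arteriole_area_px = as.integer(min_arteriole_area_px),
                 min_capillary_area_px = as.integer(min_capillary_area_px),
                 dilation_radius_px = as.integer(dilation_radius_px),
                 copositivity_fraction = copositivity_fraction,
                 min_lumen_px = as.integer(min_lumen_px),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Binarise an intensity channel
#'
#' Pixels strictly above the threshold become `TRUE`. With
#' `method = "otsu"` the threshold is computed from the intensity
#' histogram (Otsu's criterion); with `method = "fixed"` the supplied
#' `value` is used verbatim.
#'
#' @param channel 2D numeric intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return A logical matrix of the same shape, with attribute
#'   `"threshold"` recording the threshold used.
#' @export
threshold_channel <- function(channel, method = c("otsu", "fixed"),
                              value = NULL) {
  method <- match.arg(method)
  if (!is.matrix(channel) || length(channel) == 0)
    stop("`channel` must be a nonempty 2D matrix")
  if (method == "fixed") {
    if (is.null(value)) stop("`method = \"fixed\"` requires a `value`")
    thr <- value
  } else {
    rng <- range(channel)
    if (rng[1] == rng[2]) {
      thr <- rng[1]  # flat image: nothing exceeds the single level
    } else {
      scaled <- (channel - rng[1]) / (rng[2] - rng[1])
      thr <- rng[1] + EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
        (rng[2] - rng[1])
    }
  }
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  mask
}

disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

label_mask <- function(mask, connectivity = 8L) {
  cpp_label_components(mask, as.integer(connectivity))
}

#' Complete-ring test for stained components
#'
#' A connected component of the smooth-muscle mask is a complete ring when
#' filling its holes adds at least `min_lumen_px` enclosed pixels (the
#' unstained lumen). Components touching the image border cannot enclose a
#' hole on the open side and are therefore not rings.
#'
#' @param sma_mask logical matrix (smooth-muscle-actin positive pixels).
#' @param min_lumen_px minimum enclosed-hole pixel count.
#' @param connectivity component connectivity (4 or 8).
#' @return A tibble with one row per component: `component`, `area_px`,
#'   `lumen_px`, `is_ring`; the label matrix is attached as attribute
#'   `"labels"`.
#' @export
find_complete_rings <- function(sma_mask, min_lumen_px = 1L, connectivity = 8L) {
  stopifnot(is.matrix(sma_mask))
  labels <- label_mask(sma_mask, connectivity)
  n <- max(labels)
  if (n == 0L) {
    out <- tibble(component = integer(), area_px = integer(),
                  lumen_px = integer(), is_ring = logical())
    attr(out, "labels") <- labels
    return(out)
  }
  areas <- tabulate(labels[labels > 0L], nbins = n)
  lumen <- integer(n)
  for (k in seq_len(n)) {
    comp <- labels == k
    filled <- EBImage::fillHull(EBImage::Image(comp * 1)) > 0.5
    lumen[k] <- sum(filled) - areas[k]
  }
  out <- tibble(component = seq_len(n), area_px = as.integer(areas),
                lumen_px = lumen, is_ring = lumen >= min_lumen_px)
  attr(out, "labels") <- labels
  out
}

new_labeled_vessels <- function(labels, records, pixel_size_um) {
  structure(list(labels = labels, records = records,
                 pixel_size_um = pixel_size_um),
            class = "labeled_vessels")
}

#' @export
print.labeled_vessels <- function(x, ...) {
  cat(sprintf("<labeled_vessels> %d vessel(s): %s\n", nrow(x$records),
              paste(table(x$records$kind), names(table(x$records$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Detect arteriole walls
#'
#' An arteriole wall is a smooth-muscle-actin connected component that (a)
#' forms a complete ring (encloses a lumen), (b) is co-positive for
#' Collagen IV (at least `copositivity_fraction` of its pixels fall on the
#' Collagen IV mask), and (c) has a stained wall area of at least
#' `min_arteriole_area_px` pixels, the lumen excluded. Each surviving
#' component becomes one labelled arteriole.
#'
#' @param colIV_mask logical Collagen IV mask.
#' @param sma_mask logical smooth-muscle-actin mask of the same shape.
#' @param params a [segmentation_params()] list.
#' @param pixel_size_um calibration used for physical areas.
#' @return A `labeled_vessels` object: integer label matrix (0 background)
#'   plus a record tibble (`vessel_id`, `kind`, `area_px`, `area_um2`,
#'   `lumen_area_px`).
#' @export
detect_arterioles <- function(colIV_mask, sma_mask,
                              params = segmentation_params(),
                              pixel_size_um = 0.5676) {
  if (!identical(dim(colIV_mask), dim(sma_mask)))
    stop("mask shapes differ")
  rings <- find_complete_rings(sma_mask, params$min_lumen_px,
                               params$connectivity)
  labels0 <- attr(rings, "labels")
  out_labels <- matrix(0L, nrow(sma_mask), ncol(sma_mask))
  keep <- integer(0)
  lumen_keep <- integer(0)
  if (nrow(rings) > 0) {
    for (k in seq_len(nrow(rings))) {
      if (!rings$is_ring[k]) next
      comp <- labels0 == rings$component[k]
      frac <- sum(colIV_mask[comp]) / rings$area_px[k]
      if (frac < params$copositivity_fraction) next
      if (rings$area_px[k] < params$min_arteriole_area_px) next
      keep <- c(keep, rings$component[k])
      lumen_keep <- c(lumen_keep, rings$lumen_px[k])
      out_labels[comp] <- length(keep)
    }
  }
  areas <- if (length(keep)) rings$area_px[match(keep, rings$component)] else integer(0)
  records <- tibble(vessel_id = seq_along(keep),
                    kind = rep("arteriole", length(keep)),
                    area_px = as.integer(areas),
                    area_um2 = px_to_um2(as.integer(areas), pixel_size_um),
                    lumen_area_px = as.integer(lumen_keep))
  new_labeled_vessels(out_labels, records, pixel_size_um)
}

#' Derive capillaries by dilation and subtraction
#'
#' The arteriole wall mask is dilated by `dilation_radius_px` (disk
#' element) and removed from the comprehensive Collagen IV mask; remaining
#' connected components of at least `min_capillary_area_px` pixels are
#' labelled capillaries. Capillary pixels are therefore disjoint from
#' arteriole wall pixels by construction.
#'
#' @param colIV_mask logical Collagen IV mask.
#' @param arteriole_vessels `labeled_vessels` from [detect_arterioles()].
#' @param params a [segmentation_params()] list.
#' @param pixel_size_um calibration used for physical areas.
#' @return A `labeled_vessels` object with capillary records.
#' @export
derive_capillaries <- function(colIV_mask, arteriole_vessels,
                               params = segmentation_params(),
                               pixel_size_um = 0.5676) {
  if (!identical(dim(colIV_mask), dim(arteriole_vessels$labels)))
    stop("mask shapes differ")
  art_mask <- arteriole_vessels$labels > 0L
  if (params$dilation_radius_px > 0 && any(art_mask)) {
    art_mask <- EBImage::dilate(EBImage::Image(art_mask * 1),
                                disk_brush(params$dilation_radius_px)) > 0.5
  }
  cap_mask <- colIV_mask & !art_mask
  labels <- label_mask(cap_mask, params$connectivity)
  n <- max(labels)
  if (n > 0) {
    areas <- tabulate(labels[labels > 0L], nbins = n)
    keep <- which(areas >= params$min_capillary_area_px)
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  records <- tibble(vessel_id = seq_along(areas),
                    kind = rep("capillary", length(areas)),
                    area_px = as.integer(areas),
                    area_um2 = px_to_um2(as.integer(areas), pixel_size_um),
                    lumen_area_px = NA_integer_)
  new_labeled_vessels(labels, records, pixel_size_um)
}
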
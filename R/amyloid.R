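#' Aggregate-detection parameters
#'
#' The detector runs three stages in order: white top-hat background
#' removal (suppresses structures wider than the disk), Mexican-hat
#' band-pass filtering (negated scale-normalised Laplacian of Gaussian,
#' enhancing blobs near scale `mexican_hat_sigma_px`), then intensity
#' thresholding of the filtered response and connected-component
#' labelling.
#'
#' @param top_hat_radius_px disk radius for the white top-hat (>= 1);
#'   default 10 px (about 5.7 um) -- larger than typical aggregates,
#'   smaller than vessels.
#' @param mexican_hat_sigma_px Gaussian scale of the Mexican-hat filter in
#'   pixels (> 0).
#' @param threshold_method `"otsu"`, `"fixed"` or `"quantile"`.
#' @param threshold_value fixed threshold, or the quantile probability for
#'   `"quantile"`.
#' @param connectivity 4 or 8 (default 8).
#' @param min_size_px minimum aggregate size in pixels (default 1: no
#'   minimum).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(top_hat_radius_px = 10L,
                             mexican_hat_sigma_px = 2,
                             threshold_method = "otsu",
                             threshold_value = NULL,
                             connectivity = 8L,
                             min_size_px = 1L) {
  stopifnot(top_hat_radius_px >= 1, mexican_hat_sigma_px > 0,
            connectivity %in% c(4L, 8L), min_size_px >= 1)
  if (threshold_method %in% c("fixed", "quantile") && is.null(threshold_value))
    stop("threshold_method \"", threshold_method, "\" requires threshold_value")
  structure(list(top_hat_radius_px = as.integer(top_hat_radius_px),
                 mexican_hat_sigma_px = mexican_hat_sigma_px,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 connectivity = as.integer(connectivity),
                 min_size_px = as.integer(min_size_px)),
            class = "detection_params")
}

#' White top-hat background removal
#'
#' Returns the image minus its morphological opening with a disk of the
#' given radius. The result is nonnegative and retains only bright
#' features narrower than the disk; any constant background is removed
#' exactly.
#'
#' @param channel 2D numeric matrix.
#' @param radius_px disk radius in pixels (>= 1).
#' @return A 2D numeric matrix of the same shape.
#' @export
white_top_hat <- function(channel, radius_px) {
  if (!is.matrix(channel)) stop("`channel` must be a 2D matrix")
  if (!is.numeric(radius_px) || radius_px < 1)
    stop("`radius_px` must be at least 1")
  # grayscale morphology operates on [0, 1]; min/max filters commute with
  # positive affine maps, so rescale, transform, and scale back exactly
  rng <- range(channel)
  if (rng[1] == rng[2]) return(matrix(0, nrow(channel), ncol(channel)))
  scaled <- (channel - rng[1]) / (rng[2] - rng[1])
  out <- EBImage::whiteTopHat(EBImage::Image(scaled), disk_brush(radius_px))
  out <- pmax(as.matrix(EBImage::imageData(out)), 0) * (rng[2] - rng[1])
  dim(out) <- dim(channel)
  out
}

#' Mexican-hat (negated scale-normalised LoG) filter
#'
#' Convolves the image with a negated, scale-normalised Laplacian of
#' Gaussian of scale `sigma_px`, so isolated bright blobs produce positive
#' peaks and the response is (up to boundary effects) zero on constant and
#' linear-ramp images. The kernel is mean-corrected so its coefficients
#' sum exactly to zero.
#'
#' @param channel 2D numeric matrix.
#' @param sigma_px Gaussian scale in pixels (> 0).
#' @return A 2D numeric response matrix of the same shape.
#' @export
mexican_hat_filter <- function(channel, sigma_px) {
  if (!is.matrix(channel)) stop("`channel` must be a 2D matrix")
  if (!is.numeric(sigma_px) || sigma_px <= 0)
    stop("`sigma_px` must be positive")
  half <- max(3L, ceiling(4 * sigma_px))
  xs <- seq(-half, half)
  g <- outer(xs, xs, function(i, j) {
    r2 <- i^2 + j^2
    # negated scale-normalised LoG: -sigma^2 * laplacian(G_sigma)
    #   = -(r^2 - 2 sigma^2) / (2 pi sigma^4) * exp(-r^2 / (2 sigma^2))
    -(r2 - 2 * sigma_px^2) / (2 * pi * sigma_px^4) *
      exp(-r2 / (2 * sigma_px^2))
  })
  g <- g - mean(g)  # exact zero response to constants
  out <- EBImage::filter2(EBImage::Image(channel), g, boundary = "replicate")
  out <- as.matrix(EBImage::imageData(out))
  dim(out) <- dim(channel)
  out
}

#' Detect amyloid aggregates in a filtered response
#'
#' Thresholds the response, labels connected components at the configured
#' connectivity, removes components below `min_size_px`, and records each
#' component's pixel size, centroid and mean intensity (taken from
#' `intensity`, normally the unfiltered amyloid channel).
#'
#' @param response 2D numeric matrix (typically top-hat + Mexican-hat
#'   output).
#' @param params a [detection_params()] list.
#' @param intensity optional 2D matrix from which `mean_intensity` is
#'   measured; defaults to `response`.
#' @return An object of class `aggregate_set`: integer label matrix plus a
#'   record tibble (`agg_id`, `size_px`, `centroid_y`, `centroid_x`,
#'   `mean_intensity`). Coordinates are 0-based (row, column).
#' @export
detect_aggregates <- function(response, params = detection_params(),
                              intensity = response) {
  if (!is.matrix(response)) stop("`response` must be a 2D matrix")
  if (!identical(dim(response), dim(intensity)))
    stop("`intensity` shape differs from `response`")
  thr <- switch(params$threshold_method,
    fixed = params$threshold_value,
    quantile = quantile(response, probs = params$threshold_value, names = FALSE),
    otsu = attr(threshold_channel(response, "otsu"), "threshold"),
    stop("unknown threshold method: ", params$threshold_method))
  mask <- response > thr
  labels <- label_mask(mask, params$connectivity)
  n <- max(labels)
  if (n > 0) {
    sizes <- tabulate(labels[labels > 0L], nbins = n)
    keep <- which(sizes >= params$min_size_px)
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
    n <- length(keep)
  }
  if (n == 0L) {
    records <- tibble(agg_id = integer(), size_px = integer(),
                      centroid_y = numeric(), centroid_x = numeric(),
                      mean_intensity = numeric())
  } else {
    pos <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    sizes <- tabulate(lab, nbins = n)
    # 0-based (row, column) centroids
    cy <- vapply(split(pos[, 1] - 1, lab), mean, numeric(1))
    cx <- vapply(split(pos[, 2] - 1, lab), mean, numeric(1))
    mi <- vapply(split(intensity[labels > 0L], lab), mean, numeric(1))
    records <- tibble(agg_id = seq_len(n), size_px = as.integer(sizes),
                      centroid_y = unname(cy), centroid_x = unname(cx),
                      mean_intensity = unname(mi))
  }
  structure(list(labels = labels, records = records, threshold = thr),
            class = "aggregate_set")
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat(sprintf("<aggregate_set> %d aggregate(s), threshold %.4g\n",
              nrow(x$records), x$threshold))
  invisible(x)
}

#' Full amyloid detection pipeline on one channel
#'
#' Applies white top-hat, Mexican-hat filtering and thresholding in
#' sequence.
#'
#' @param abeta 2D numeric amyloid channel.
#' @param params a [detection_params()] list.
#' @return An `aggregate_set` (see [detect_aggregates()]).
#' @export
detect_amyloid <- function(abeta, params = detection_params()) {
  th <- white_top_hat(abeta, params$top_hat_radius_px)
  resp <- mexican_hat_filter(th, params$mexican_hat_sigma_px)
  detect_aggregates(resp, params, intensity = abeta)
}
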
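# Membrane-layer profiling of TEM-like images and ratiometric fluorescence
# uniformity analysis.
#
# Membranes are electron-dense, i.e. dark lines; detection therefore works
# on the inverted intensity profile (configurable polarity).  All spacing
# output is in nanometres when a pixel size is calibrated and in pixels
# (explicitly tagged) otherwise.

#' Grayscale image container
#'
#' @param data Numeric matrix (rows x cols) of finite, non-negative
#'   intensities.
#' @param pixel_size Optional calibration in nm per pixel.
#' @return Object of class \code{gray_image}.
#' @export
gray_image <- function(data, pixel_size = NULL) {
  stopifnot(is.matrix(data), length(data) > 0, all(is.finite(data)),
            all(data >= 0))
  structure(list(data = data, pixel_size = pixel_size), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("Gray image %d x %d px%s\n", nrow(x$data), ncol(x$data),
              if (is.null(x$pixel_size)) " (uncalibrated)"
              else sprintf(" (%.3g nm/px)", x$pixel_size)))
  invisible(x)
}

#' Read a grayscale PNG or TIFF image
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path Image path (.png, .tif, .tiff).
#' @param pixel_size Optional nm-per-pixel calibration.
#' @return A \code{\link{gray_image}} with intensities in [0, 1].
#' @export
read_gray_image <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  gray_image(arr, pixel_size)
}

#' Write a grayscale image as PNG or TIFF
#'
#' Intensities are rescaled to [0, 1] when outside that range.
#'
#' @param image A \code{\link{gray_image}} or numeric matrix.
#' @param path Output path (.png, .tif, .tiff).
#' @return \code{path}, invisibly.
#' @export
write_gray_image <- function(image, path) {
  m <- if (inherits(image, "gray_image")) image$data else image
  if (max(m) > 1) m <- (m - min(m)) / (max(m) - min(m) + .Machine$double.eps)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m, path),
         tif = , tiff = tiff::writeTIFF(m, path),
         stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' FFT bandpass filter on feature size
#'
#' Keeps spatial features with characteristic sizes between \code{small_px}
#' and \code{large_px} pixels, using a smooth (fourth-order Gaussian)
#' annulus in frequency space.  The DC component (image mean) is removed by
#' the band and re-added by default so that a uniform image passes through
#' unchanged.  Deterministic.
#'
#' @param image A \code{\link{gray_image}} or numeric matrix.
#' @param small_px,large_px Feature-size band in pixels; 0 < small < large.
#' @param keep_mean Re-add the image mean after filtering (default TRUE).
#' @return A \code{gray_image} of the same shape (intensities clipped at 0).
#' @export
fft_bandpass <- function(image, small_px, large_px, keep_mean = TRUE) {
  if (!(small_px > 0 && small_px < large_px))
    stop("invalid band: need 0 < small_px < large_px", call. = FALSE)
  m <- if (inherits(image, "gray_image")) image$data else image
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  r <- sqrt(outer(fr^2, fc^2, `+`))
  f_hi <- 1 / small_px  # cycles/px above which features are too small
  f_lo <- 1 / large_px  # cycles/px below which features are too large
  H <- exp(-(r / f_hi)^4) * (1 - exp(-(r / f_lo)^4))
  Fm <- stats::fft(m)
  out <- Re(stats::fft(Fm * H, inverse = TRUE)) / (nr * nc)
  if (keep_mean) out <- out + mean(m)
  out <- pmax(out, 0)
  gray_image(matrix(out, nr, nc),
             if (inherits(image, "gray_image")) image$pixel_size else NULL)
}

#' Rectangular ROI crossing a set of parallel membranes
#'
#' Membranes are assumed oriented parallel to image rows, so the row axis of
#' the ROI crosses them and the column axis runs along them.
#'
#' @param rows,cols Integer ranges (e.g. \code{20:90}) within the image.
#' @return Object of class \code{roi_band}.
#' @export
roi_band <- function(rows, cols) {
  stopifnot(length(rows) >= 5, length(cols) >= 3,
            all(rows >= 1), all(cols >= 1))
  structure(list(rows = rows, cols = cols), class = "roi_band")
}

#' Column-averaged intensity profile of an ROI
#'
#' Averages the ROI along the membrane direction (columns), giving one mean
#' intensity per crossing-axis position (row).
#'
#' @param image A \code{\link{gray_image}} or numeric matrix.
#' @param roi A \code{\link{roi_band}}.
#' @return Object of class \code{membrane_profile}: list with
#'   \code{intensity} (numeric vector, one value per ROI row) and
#'   \code{pixel_size}.
#' @export
roi_profile <- function(image, roi) {
  m <- if (inherits(image, "gray_image")) image$data else image
  if (max(roi$rows) > nrow(m) || max(roi$cols) > ncol(m))
    stop("ROI out of image bounds", call. = FALSE)
  prof <- rowMeans(m[roi$rows, roi$cols, drop = FALSE])
  structure(list(intensity = unname(prof),
                 pixel_size = if (inherits(image, "gray_image"))
                   image$pixel_size else NULL),
            class = "membrane_profile")
}

#' Detect membranes as troughs of an intensity profile
#'
#' A trough counts as a membrane when its prominence (depth relative to the
#' higher of the two flanking ridges, on the inverted profile) is at least
#' \code{min_prominence_sd} profile standard deviations, and when it lies at
#' least \code{min_separation_px} pixels from any stronger accepted trough.
#' Sub-pixel positions come from a 3-point parabolic fit (ties broken toward
#' the smaller index); spacings are consecutive position differences, in nm
#' when the profile is calibrated and in px otherwise.
#'
#' @param profile A \code{\link{roi_profile}} result or numeric vector
#'   (length at least 5).
#' @param min_prominence_sd Prominence threshold in profile SD units
#'   (default 1.0).
#' @param min_separation_px Minimum distance between accepted troughs
#'   (default 4).
#' @param pixel_size Optional nm-per-pixel calibration, overriding the
#'   profile's.
#' @param dark_lines Membranes are dark (default TRUE); set FALSE for bright
#'   lines.
#' @return Object of class \code{membrane_call}: list with \code{count},
#'   \code{positions_px} (strictly increasing, sub-pixel), \code{spacings},
#'   \code{mean_spacing}, \code{sd_spacing}, \code{spacing_unit}
#'   (\code{"nm"} or \code{"px"}) and the parameters used.
#' @export
detect_membranes <- function(profile, min_prominence_sd = 1.0,
                             min_separation_px = 4, pixel_size = NULL,
                             dark_lines = TRUE) {
  if (inherits(profile, "membrane_profile")) {
    pixel_size <- pixel_size %||% profile$pixel_size
    y <- profile$intensity
  } else y <- as.numeric(profile)
  stopifnot(length(y) >= 5)
  v <- if (dark_lines) -y else y   # troughs become peaks
  n <- length(v)
  s <- sd(y)
  empty_call <- function() structure(
    list(count = 0L, positions_px = numeric(0), spacings = numeric(0),
         mean_spacing = NA_real_, sd_spacing = NA_real_,
         spacing_unit = if (is.null(pixel_size)) "px" else "nm",
         min_prominence_sd = min_prominence_sd,
         min_separation_px = min_separation_px), class = "membrane_call")
  if (s == 0) return(empty_call())

  # local maxima of v (plateau-tolerant: first index of the plateau)
  is_peak <- vapply(seq_len(n), function(i) {
    if (i == 1L || i == n) return(FALSE)
    left <- v[i] - v[i - 1L]
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    right <- if (j == n) -1 else v[j + 1L] - v[i]
    left > 0 && right < 0
  }, TRUE)
  peaks <- which(is_peak)
  if (!length(peaks)) return(empty_call())

  # prominence: height above the higher of the two valley minima between
  # this peak and the nearest higher peaks (or profile ends)
  prominence <- vapply(peaks, function(p) {
    higher <- which(v > v[p])
    lo <- higher[higher < p]; hi <- higher[higher > p]
    left_min <- min(v[(if (length(lo)) max(lo) else 1L):p])
    right_min <- min(v[p:(if (length(hi)) min(hi) else n)])
    v[p] - max(left_min, right_min)
  }, 1)

  keep <- prominence >= min_prominence_sd * s
  peaks <- peaks[keep]; prominence <- prominence[keep]
  if (!length(peaks)) return(empty_call())

  # enforce separation: accept in decreasing prominence order
  ord <- order(-prominence, peaks)
  accepted <- integer(0)
  for (p in peaks[ord]) {
    if (!length(accepted) || all(abs(accepted - p) >= min_separation_px))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)

  # sub-pixel refinement by 3-point parabola on v
  pos <- vapply(accepted, function(p) {
    if (p <= 1L || p >= n) return(as.numeric(p))
    denom <- v[p - 1L] - 2 * v[p] + v[p + 1L]
    if (denom >= 0) return(as.numeric(p))
    delta <- 0.5 * (v[p - 1L] - v[p + 1L]) / denom
    p + max(-0.5, min(0.5, delta))
  }, 1)

  scale <- if (is.null(pixel_size)) 1 else pixel_size
  spacings <- diff(pos) * scale
  structure(list(
    count = length(pos), positions_px = pos, spacings = spacings,
    mean_spacing = if (length(spacings)) mean(spacings) else NA_real_,
    sd_spacing = if (length(spacings) > 1) sd(spacings) else NA_real_,
    spacing_unit = if (is.null(pixel_size)) "px" else "nm",
    min_prominence_sd = min_prominence_sd,
    min_separation_px = min_separation_px), class = "membrane_call")
}

#' @export
print.membrane_call <- function(x, ...) {
  cat(sprintf("Membrane call: %d line(s)", x$count))
  if (x$count >= 2)
    cat(sprintf("; mean spacing %.2f %s", x$mean_spacing, x$spacing_unit))
  cat("\n")
  invisible(x)
}

#' Classify a membrane system by layer count
#'
#' @param call A \code{\link{detect_membranes}} result.
#' @return \code{"two_layer"}, \code{"three_layer"} or \code{"other"}.
#' @export
classify_membrane_system <- function(call) {
  switch(as.character(call$count), "2" = "two_layer", "3" = "three_layer",
         "other")
}

#' Is an intermembrane spacing compatible with transport contact points?
#'
#' Mitochondrial contact sites (TIM/TOM-scale complexes) span intermembrane
#' distances around 15 nm; symbiosomal spacings measured around 37-41 nm are
#' too wide for such integrated systems.  The default 20 nm threshold sits
#' between those two reference regimes.
#'
#' @param mean_spacing_nm Non-negative spacing in nm.
#' @param threshold_nm Decision threshold (default 20 nm).
#' @return TRUE iff \code{mean_spacing_nm <= threshold_nm}.
#' @export
contact_point_compatible <- function(mean_spacing_nm, threshold_nm = 20) {
  stopifnot(mean_spacing_nm >= 0)
  mean_spacing_nm <= threshold_nm
}

#' Weighted ratiometric image with offset and uniformity check
#'
#' Computes \code{ratio = weight * a / (b + offset)} pixel-wise (the 585/640
#' emission ratio of a pH-sensitive dye), its coefficient of variation over
#' a mask, and the connected regions whose local ratio deviates from the
#' global mean by more than \code{k} standard deviations (candidate
#' pH-contrast regions).
#'
#' @param img_a,img_b \code{\link{gray_image}}s or matrices of equal shape.
#' @param offset Added to the denominator; \code{b + offset} must be
#'   strictly positive everywhere.
#' @param weight Multiplicative scaling of the ratio (default 1).
#' @param k Contrast threshold in SD units (default 3).
#' @param min_region_px Minimum connected-region area in pixels to report
#'   (default 9).
#' @param mask Optional logical matrix restricting the uniformity statistics.
#' @return List with \code{ratio} (matrix), \code{cv} (sd/mean over the
#'   mask), and \code{contrast_regions} (data frame label/area/mean_ratio,
#'   with a list-column of pixel indices).
#' @export
ratiometric_image <- function(img_a, img_b, offset = 0, weight = 1, k = 3,
                              min_region_px = 9, mask = NULL) {
  a <- if (inherits(img_a, "gray_image")) img_a$data else img_a
  b <- if (inherits(img_b, "gray_image")) img_b$data else img_b
  stopifnot(all(dim(a) == dim(b)))
  denom <- b + offset
  if (any(denom <= 0))
    stop("denominator image plus offset must be positive everywhere",
         call. = FALSE)
  ratio <- weight * a / denom
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ratio), ncol(ratio))
  vals <- ratio[mask]
  mu <- mean(vals); sigma <- sd(vals)
  cv <- if (mu == 0) NA_real_ else sigma / mu
  if (sigma == 0) {
    regions <- data.frame(label = integer(), area = integer(),
                          mean_ratio = numeric())
    regions$pixels <- list()
    return(list(ratio = ratio, cv = cv, contrast_regions = regions))
  }
  outlier <- abs(ratio - mu) > k * sigma & mask
  labels <- EBImage::bwlabel(matrix(as.numeric(outlier), nrow(outlier)))
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rows <- lapply(ids, function(id) {
    px <- which(labels == id)
    if (length(px) < min_region_px) return(NULL)
    data.frame(label = id, area = length(px), mean_ratio = mean(ratio[px]))
  })
  regions <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(regions))
    regions <- data.frame(label = integer(), area = integer(),
                          mean_ratio = numeric())
  regions$pixels <- lapply(regions$label, function(id) which(labels == id))
  list(ratio = ratio, cv = cv, contrast_regions = regions)
}
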
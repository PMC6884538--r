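#' In-plane 3x3 Gaussian smoothing
#'
#' Slice-by-slice 2-D Gaussian convolution with a 3x3 kernel (sigma = 0.8
#' pixels, truncated to 3x3 and renormalized to unit sum), the conditioning
#' step applied to every volume before T1 and MT fitting. Edges are handled
#' by replication so that tendon ROIs near the volume border are not
#' darkened; a constant image passes through unchanged and the mean of an
#' interior homogeneous region is preserved.
#'
#' @param volume 2-D matrix or 3-D array, at least 3x3 in plane.
#' @param sigma Kernel standard deviation in pixels.
#' @return Array of the same shape.
#' @export
gaussian_smooth_inplane <- function(volume, sigma = 0.8) {
  d <- dim(volume)
  if (is.null(d) || length(d) < 2 || d[1] < 3 || d[2] < 3) {
    stop("volume must be at least 3 x 3 in plane")
  }
  k <- gaussian_kernel_3x3(sigma)
  if (length(d) == 2) {
    return(EBImage::filter2(volume, k, boundary = "replicate"))
  }
  out <- volume
  for (s in seq_len(d[3])) {
    out[, , s] <- EBImage::filter2(volume[, , s], k, boundary = "replicate")
  }
  out
}

#' @rdname gaussian_smooth_inplane
#' @return `gaussian_kernel_3x3` returns the 3x3 kernel matrix (unit sum).
#' @export
gaussian_kernel_3x3 <- function(sigma = 0.8) {
  stopifnot(sigma > 0)
  x <- -1:1
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' ROI mask over a parameter map or volume
#'
#' @param mask Logical 3-D (or 2-D) array.
#' @param label Tendon identifier, `"ATT"` or `"PTT"`.
#' @param reader_id Identifier of the reader who placed the ROI.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("ATT", "PTT"), reader_id = "truth") {
  label <- match.arg(label)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(mask = mask, label = label, reader_id = reader_id),
            class = "roi_mask")
}

#' ROI summary statistics
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator, the
#' cohort-summary convention) and voxel count over the in-mask, non-missing
#' voxels of a map. Invariant to voxel order.
#'
#' @param map Numeric array (e.g. one plane of a `parameter_map`), or a
#'   `parameter_map` together with `field`.
#' @param roi An [roi_mask] (or a plain logical array).
#' @param field When `map` is a `parameter_map`, which map to summarize
#'   (`"mmf_map"`, `"t2mm_map"`, ...).
#' @return List with `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(map, roi, field = "mmf_map") {
  if (inherits(map, "parameter_map")) map <- map[[field]]
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!all(dim(m) == dim(map))) stop("ROI shape does not match the map")
  v <- map[m]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all in-mask voxels are missing")
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v))
}
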
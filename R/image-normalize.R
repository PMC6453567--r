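# Images are numeric matrices, [row = y, col = x], pixel-centred 0-based
# coordinates: pixel (i, j) sits at (x, y) = (j - 1, i - 1) pixel units.

# 256-bin histogram; the background of a transmission image is its brightest
# substantial peak (colonies are dark), the threshold the first local
# minimum scanning downward from it. Counts are lightly smoothed so that
# shot noise in the histogram does not fake peaks or valleys.
intensity_landmarks <- function(img, nbins = 256, min_mass = 0.001) {
  rng <- range(img)
  if (diff(rng) == 0) abort("Image is constant; no histogram structure.",
                            class = "biofilmorph_segmentation_error")
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- graphics::hist(img, breaks = br, plot = FALSE)
  mids <- h$mids
  counts <- as.numeric(stats::filter(c(0, 0, h$counts, 0, 0), rep(1 / 5, 5),
                                     sides = 2))[3:(nbins + 2)]
  floor_ct <- min_mass * length(img)
  up <- c(TRUE, counts[-1] >= counts[-nbins])    # not below left neighbour
  down <- c(counts[-nbins] > counts[-1], TRUE)   # above right neighbour
  peaks <- which(up & down & counts >= floor_ct)
  if (length(peaks) == 0) peaks <- which.max(counts)
  peak <- max(peaks)  # highest-intensity peak = background
  # refine the mode beyond bin resolution: median of the pixels in the bin
  in_bin <- img >= br[peak] & img <= br[peak + 1]
  mode_value <- if (any(in_bin)) median(img[in_bin]) else mids[peak]
  valley <- NA_integer_
  if (peak > 2) {
    for (i in seq(peak - 1, 2, by = -1)) {
      if (counts[i] <= counts[i - 1] && counts[i] <= counts[i + 1]) {
        valley <- i
        break
      }
    }
  }
  list(mode = mode_value, valley = if (is.na(valley)) NA_real_ else mids[valley],
       counts = counts, mids = mids)
}

# 3x3 median filter with edge replication
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  shifts <- vector("list", 9)
  k <- 0
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1
    shifts[[k]] <- pad[di + 1:nr, dj + 1:nc]
  }
  arr <- array(unlist(shifts), dim = c(nr, nc, 9))
  apply(arr, c(1, 2), median)
}

#' Normalise and segment a colony transmission image
#'
#' Standardises image contrast and extracts the colony object. The pixel
#' intensity histogram (256 bins) is used to identify the background as its
#' brightest substantial peak (colonies are dark under transmission
#' illumination); an affine rescale then maps the
#' image minimum to 0 and the background mode to 0.9. After a 3x3 median
#' filter, the first histogram valley below the background peak gives the
#' binarisation threshold; the colony is the largest connected dark
#' component, with holes filled.
#'
#' @param img Numeric matrix (single-channel image, any intensity range).
#'   Background must occupy a substantial fraction of the frame.
#' @param pixel_size Physical size of one pixel (any length unit); stored on
#'   the output.
#' @param timestamp Acquisition time in hours, stored on the output.
#' @return A list of class `colony_frame` with elements `image` (normalised
#'   matrix), `mask` (logical matrix), `I_b` (0.9), `I_V` (threshold used),
#'   `pixel_size`, `timestamp`.
#' @export
normalize_and_segment <- function(img, pixel_size = 1, timestamp = NA_real_) {
  stopifnot(is.matrix(img), is.numeric(img))
  lm0 <- intensity_landmarks(img)
  lo <- min(img)
  if (lm0$mode <= lo) abort("Degenerate histogram: background mode at the minimum.",
                            class = "biofilmorph_segmentation_error")
  norm <- 0.9 * (img - lo) / (lm0$mode - lo)
  filt <- median_filter3(norm)
  lm1 <- intensity_landmarks(filt)
  if (is.na(lm1$valley))
    abort("No histogram valley found below the background peak; supply a manual threshold.",
          class = "biofilmorph_segmentation_error")
  binary <- filt < lm1$valley
  if (!any(binary))
    abort("Segmentation found no object below the threshold.",
          class = "biofilmorph_segmentation_error")
  lab <- EBImage::bwlabel(binary * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- EBImage::fillHull((lab == keep) * 1) > 0
  structure(list(image = filt, mask = mask, I_b = 0.9, I_V = lm1$valley,
                 pixel_size = pixel_size, timestamp = timestamp),
            class = "colony_frame")
}

#' @export
print.colony_frame <- function(x, ...) {
  cat(sprintf("<colony_frame> %d x %d px, object %d px, I_V = %.3f, t = %s hr\n",
              nrow(x$image), ncol(x$image), sum(x$mask), x$I_V,
              format(x$timestamp)))
  invisible(x)
}

# centroid of a logical mask in pixel-centred 0-based (x, y)
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' Colony centre from a time series
#'
#' The colony centre used for all ring and contour analyses is fixed from
#' the frame at (or nearest to) 12 hr after inoculation, so that later
#' morphology changes do not move the reference point.
#'
#' @param frames List of `colony_frame` objects (see
#'   [normalize_and_segment()]) or of logical masks.
#' @param times Frame times in hours; defaults to the frames' `timestamp`s.
#' @param reference_time Target time (default 12 hr).
#' @return Named numeric `c(x, y)` centre in pixel coordinates, with
#'   attribute `frame` (index used).
#' @export
colony_center <- function(frames, times = NULL, reference_time = 12) {
  if (is.null(times))
    times <- vapply(frames, function(f)
      if (inherits(f, "colony_frame")) f$timestamp else NA_real_, 0)
  if (all(is.na(times))) abort("No frame times available.")
  dt <- abs(times - reference_time)
  i <- which.min(dt)
  if (dt[i] > 3) {
    warn(sprintf("No frame within 3 hr of t = %g hr; using the earliest frame.",
                 reference_time))
    i <- which.min(times)
  }
  f <- frames[[i]]
  mask <- if (inherits(f, "colony_frame")) f$mask else f
  ctr <- mask_centroid(mask)
  attr(ctr, "frame") <- i
  ctr
}
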
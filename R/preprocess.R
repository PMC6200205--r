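#' Bilinear resize of a grayscale chip
#'
#' Thin wrapper over \code{EBImage::resize} (bilinear, no corner alignment).
#' Resizing to the input size is an exact identity.
#'
#' @param chip numeric matrix in [0,1].
#' @param height,width output size in pixels; a single \code{height} with
#'   \code{width = NULL} gives a square output.
#' @return numeric matrix \code{height} x \code{width}.
#' @export
resize_chip <- function(chip, height, width = NULL) {
  stopifnot(is.matrix(chip))
  if (is.null(width)) width <- height
  if (nrow(chip) == height && ncol(chip) == width) return(chip)
  out <- EBImage::resize(chip, w = height, h = width, filter = "bilinear")
  as.matrix(out)
}

#' Centre crop with fixed top-left-biased offsets
#'
#' When the size difference is odd the extra discarded pixel comes from the
#' bottom/right, i.e. offsets are \code{floor((in - out)/2)}; this convention
#' is fixed so results are identical across platforms.
#'
#' @inheritParams resize_chip
#' @export
centre_crop <- function(chip, height, width = NULL) {
  if (is.null(width)) width <- height
  H <- nrow(chip); W <- ncol(chip)
  if (H < height || W < width)
    stop("cannot crop ", H, "x", W, " to ", height, "x", width)
  ro <- (H - height) %/% 2L
  co <- (W - width) %/% 2L
  chip[ro + seq_len(height), co + seq_len(width), drop = FALSE]
}

#' Centre pad with a constant fill, floor-biased like [centre_crop()]
#' @inheritParams centre_crop
#' @param fill pad value (default 0).
#' @export
centre_pad <- function(chip, height, width = NULL, fill = 0) {
  if (is.null(width)) width <- height
  H <- nrow(chip); W <- ncol(chip)
  if (H > height || W > width)
    stop("cannot pad ", H, "x", W, " to smaller ", height, "x", width)
  out <- matrix(fill, height, width)
  ro <- (height - H) %/% 2L
  co <- (width - W) %/% 2L
  out[ro + seq_len(H), co + seq_len(W)] <- chip
  out
}

# crop dimensions above target, pad dimensions below it
fit_to_size <- function(chip, height, width = height, fill = 0) {
  h2 <- min(nrow(chip), height); w2 <- min(ncol(chip), width)
  centre_pad(centre_crop(chip, h2, w2), height, width, fill = fill)
}

#' The retinal bottleneck: resize to 33x33, centre-crop to 29x29
#'
#' The low-resolution pathway of the fly-eye pipeline: the chip is reduced to
#' the ommatidial sampling grid (about 850 lens units, a 29x29 grid) by a
#' bilinear resize to 33x33 followed by an exact centre crop to 29x29. A
#' 33x33 input is passed through the crop without resampling.
#'
#' @param chip numeric matrix, at least 33x33, values in [0,1].
#' @return 29x29 matrix with intensities still in [0,1].
#' @export
bottleneck_29 <- function(chip) {
  if (nrow(chip) < 33L || ncol(chip) < 33L)
    stop("bottleneck_29 needs at least a 33x33 chip, got ",
         nrow(chip), "x", ncol(chip))
  centre_crop(resize_chip(chip, 33L, 33L), 29L, 29L)
}

#' High-resolution comparator path: resize to 256, centre-crop to 224
#'
#' Returns the 224x224 chip; its \code{"effective_extent"} attribute reports
#' how many pixels of the original chip the crop effectively retains
#' (158 for a 181-pixel chip: \code{round(181 * 224 / 256)}).
#'
#' @param chip square numeric matrix (native chips are 181x181).
#' @return 224x224 matrix with attribute \code{effective_extent}.
#' @export
highres_path <- function(chip) {
  stopifnot(is.matrix(chip), nrow(chip) == ncol(chip))
  out <- centre_crop(resize_chip(chip, 256L, 256L), 224L, 224L)
  attr(out, "effective_extent") <- effective_extent(nrow(chip), 256L, 224L)
  out
}

#' Effective original extent of a resize-then-crop path
#'
#' \code{round(original * crop / resized)} with halves rounded up, e.g.
#' 181 resized to 256 then cropped to 224 effectively uses the centre
#' 158x158 original pixels.
#'
#' @param original,resized,crop side lengths in pixels.
#' @export
effective_extent <- function(original, resized, crop) {
  as.integer(floor(original * crop / resized + 0.5))
}

#' Bottleneck then upsize to the comparator input size
#'
#' [bottleneck_29()] followed by a bilinear upsize to 224x224, so comparator
#' architectures receive an image whose information content is fixed at the
#' 29x29 = 841 retinal sampling sites.
#'
#' @inheritParams bottleneck_29
#' @return 224x224 matrix.
#' @export
bottleneck_then_upsize <- function(chip) {
  resize_chip(bottleneck_29(chip), 224L, 224L)
}

#' Acuity parameters for the eye's modulation transfer function
#'
#' @param min_resolvable_angle_deg the minimum resolvable angle in degrees:
#'   4.8 for the classical inter-ommatidial limit, about 1.5 for the
#'   hyper-acuity estimate.
#' @param viewing_distance_bodylengths distance from eye to subject, in body
#'   lengths of the viewed fly (default 3).
#' @param body_length_fraction_of_chip fraction of the chip width spanned by
#'   the body (default 1: the fly fills the chip).
#' @return object of class \code{acuity_params}.
#' @export
acuity_params <- function(min_resolvable_angle_deg,
                          viewing_distance_bodylengths = 3,
                          body_length_fraction_of_chip = 1) {
  if (min_resolvable_angle_deg <= 0) stop("minimum resolvable angle must be > 0")
  if (viewing_distance_bodylengths <= 0) stop("viewing distance must be > 0")
  structure(list(min_resolvable_angle_deg = min_resolvable_angle_deg,
                 viewing_distance_bodylengths = viewing_distance_bodylengths,
                 body_length_fraction_of_chip = body_length_fraction_of_chip),
            class = "acuity_params")
}

# angular width of the chip in degrees: the chip spans 1/f body lengths seen
# from d body lengths away
chip_angular_width <- function(params) {
  d <- params$viewing_distance_bodylengths
  f <- params$body_length_fraction_of_chip
  2 * atan(1 / (2 * d * f)) * 180 / pi
}

#' Modulation transfer function matrix for an n x n chip
#'
#' \code{MTF(nu) = exp(-3.56 * (dphi * nu)^2)} where \code{nu} is spatial
#' frequency in cycles/degree and \code{dphi} the minimum resolvable angle;
#' the DC gain is exactly 1. Frequencies follow the unshifted FFT layout.
#'
#' @param n chip side length in pixels.
#' @param params an [acuity_params()].
#' @return n x n matrix of attenuation factors in (0, 1].
#' @export
acuity_mtf <- function(n, params) {
  stopifnot(inherits(params, "acuity_params"))
  theta <- chip_angular_width(params)
  k <- 0:(n - 1)
  k <- ifelse(k > n / 2, k - n, k)         # cycles per image width
  nu <- sqrt(outer(k^2, k^2, "+")) / theta # cycles per degree
  exp(-3.56 * (params$min_resolvable_angle_deg * nu)^2)
}

#' Simulate the spatial acuity of the fly eye by Fourier low-pass filtering
#'
#' Attenuates each spatial frequency of a square chip by the eye's modulation
#' transfer function for a given minimum resolvable angle and viewing
#' distance (see [acuity_params()]). The DC component is untouched, so the
#' mean intensity is preserved before clipping; the operation is linear in
#' the image when \code{clip = FALSE}.
#'
#' @param chip square numeric matrix.
#' @param params an [acuity_params()].
#' @param clip clamp the output to [0,1] (default TRUE).
#' @return filtered matrix of the same size.
#' @export
acuity_filter <- function(chip, params, clip = TRUE) {
  stopifnot(is.matrix(chip))
  if (nrow(chip) != ncol(chip))
    stop("acuity_filter expects a square chip, got ",
         nrow(chip), "x", ncol(chip))
  mtf <- acuity_mtf(nrow(chip), params)
  f <- stats::fft(chip) * mtf
  out <- Re(stats::fft(f, inverse = TRUE)) / length(chip)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Training-set standardization statistics
#'
#' Pools every pixel of the training images and records their mean and
#' standard deviation; validation and test images must be standardized with
#' these training statistics, never their own.
#'
#' @param x a numeric matrix/array of pixels, a list of chips, or a
#'   \code{chip_stack}.
#' @return object of class \code{norm_stats} with fields \code{mean},
#'   \code{sd}.
#' @export
fit_norm <- function(x) {
  v <- pool_pixels(x)
  if (length(v) < 2) stop("need at least 2 training pixels")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))   # population sd: a standardized set has sd 1
  if (!is.finite(s) || s == 0)
    stop("training pixels have zero variance; cannot standardize")
  structure(list(mean = m, sd = s), class = "norm_stats")
}

pool_pixels <- function(x) {
  if (inherits(x, "chip_stack")) return(as.numeric(x$images))
  if (is.list(x)) return(unlist(lapply(x, as.numeric), use.names = FALSE))
  as.numeric(x)
}

#' Apply (or invert) standardization
#'
#' @param x chip, array or \code{chip_stack}.
#' @param stats a [fit_norm()] result.
#' @return standardized object of the same shape.
#' @export
apply_norm <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (inherits(x, "chip_stack")) {
    x$images <- (x$images - stats$mean) / stats$sd
    return(x)
  }
  (x - stats$mean) / stats$sd
}

#' @rdname apply_norm
#' @export
invert_norm <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (inherits(x, "chip_stack")) {
    x$images <- x$images * stats$sd + stats$mean
    return(x)
  }
  x * stats$sd + stats$mean
}

#' Random non-aspect-preserving zoom
#'
#' Draws independent height and width scale factors from
#' \code{Uniform(1 - max_frac, 1 + max_frac)}, resizes, and restores the
#' input size by centre-cropping enlarged dimensions and zero-padding shrunk
#' ones. Used as the size/shape ablation: because the two factors are drawn
#' independently the aspect ratio is almost never preserved, removing
#' absolute size and proportion as identity cues.
#'
#' @param chip numeric matrix.
#' @param max_frac maximal relative size change, in (0, 1); default 0.25.
#' @param seed optional integer; when given, the draw is made under this seed
#'   with the caller's RNG state restored afterwards.
#' @return matrix of the same size as the input.
#' @export
random_zoom <- function(chip, max_frac = 0.25, seed = NULL) {
  if (max_frac <= 0 || max_frac >= 1) stop("max_frac must be in (0, 1)")
  draw <- function() {
    s <- runif(2, 1 - max_frac, 1 + max_frac)
    list(h = s[1], w = s[2])
  }
  s <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- zoom_chip(chip, s$h, s$w)
  attr(out, "scales") <- c(h = s$h, w = s$w)
  out
}

#' Deterministic anisotropic zoom back to the input size
#'
#' The resampling core of [random_zoom()]: rescales by the given factors and
#' restores the input size (centre crop when enlarged, zero pad when shrunk).
#' Scale factors of exactly 1 return the input unchanged.
#'
#' @inheritParams random_zoom
#' @param s_h,s_w height and width scale factors.
#' @export
zoom_chip <- function(chip, s_h, s_w) {
  nh <- max(1L, as.integer(floor(nrow(chip) * s_h + 0.5)))
  nw <- max(1L, as.integer(floor(ncol(chip) * s_w + 0.5)))
  fit_to_size(resize_chip(chip, nh, nw), nrow(chip), ncol(chip), fill = 0)
}
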
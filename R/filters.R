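# Coiflet-1 decomposition filters, normalised so the lowpass sums to 1
# (a constant volume is preserved by the LLL band).
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645) / sqrt(2)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993) / sqrt(2)

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

log_filter <- function(arr, dim, spacing, sigma_mm) {
  if (sigma_mm < max(spacing))
    warning(sprintf("LoG sigma %.2f mm smaller than voxel spacing; proceeding", sigma_mm))
  sm <- arr
  for (ax in 0:2) {
    k <- gaussian_kernel(sigma_mm / spacing[ax + 1])
    sm <- cpp_conv_axis(sm, dim, k, ax, 0L)
  }
  out <- numeric(length(arr))
  for (ax in 0:2) {
    lap <- cpp_conv_axis(sm, dim, c(1, -2, 1) / spacing[ax + 1]^2, ax, 0L)
    out <- out + lap
  }
  out * sigma_mm^2   # scale-normalised
}

wavelet_band <- function(arr, dim, band) {
  out <- arr
  letters3 <- strsplit(band, "")[[1]]   # letter k applies to axis k (x,y,z)
  for (ax in 0:2) {
    k <- if (letters3[ax + 1] == "L") COIF1_LO else COIF1_HI
    out <- cpp_conv_axis(out, dim, k, ax, 1L)   # periodic, undecimated
  }
  out
}

#' Compute the filtered image bank
#'
#' Produces one volume per catalog image type: the original passthrough,
#' Laplacian-of-Gaussian responses at sigma = 1 and 3 mm (scale-normalised,
#' separable Gaussian followed by a discrete spacing-aware Laplacian), and
#' the eight sub-bands of a one-level undecimated separable coiflet-1
#' wavelet transform, all at the input shape.
#'
#' @param volume an isotropically-resampled `fg_volume`.
#' @param image_types character subset of the default image types.
#' @return named list of 3D arrays, one per requested image type.
#' @export
apply_filters <- function(volume, image_types = DEFAULT_IMAGE_TYPES) {
  stopifnot(inherits(volume, "fg_volume"))
  d <- dim(volume$data)
  arr <- as.numeric(volume$data)
  out <- list()
  for (it in image_types) {
    if (it == "original") {
      out[[it]] <- volume$data
    } else if (grepl("^log-sigma-", it)) {
      sig <- as.numeric(sub("log-sigma-(\\d+)-(\\d+)-mm-3D", "\\1.\\2", it))
      out[[it]] <- array(log_filter(arr, d, volume$spacing, sig), d)
    } else if (grepl("^wavelet-", it)) {
      out[[it]] <- array(wavelet_band(arr, d, sub("wavelet-", "", it)), d)
    } else stop("unknown image type: ", it)
  }
  out
}

#' Discretise intensities into integer gray levels
#'
#' Min-referenced fixed binning: `level = floor((v - min) / bin_width) + 1`.
#' With `n_bins` given instead, the bin width is `(max - min) / n_bins` and
#' the top value is clamped into the last bin. Shifting all values by a
#' constant leaves levels unchanged.
#'
#' @param values numeric vector (at least one value).
#' @param bin_width fixed bin width (> 0), or NULL to use `n_bins`.
#' @param n_bins fixed number of bins (> 0).
#' @return integer vector of gray levels >= 1.
#' @export
discretize <- function(values, bin_width = NULL, n_bins = NULL) {
  if (length(values) < 1) stop("at least one value required")
  rng <- range(values)
  if (is.null(bin_width)) {
    if (is.null(n_bins) || n_bins <= 0) stop("bin_width or n_bins must be given and positive")
    if (rng[2] - rng[1] <= 0) return(rep.int(1L, length(values)))
    bin_width <- (rng[2] - rng[1]) / n_bins
    lev <- pmin(as.integer(floor((values - rng[1]) / bin_width)) + 1L, as.integer(n_bins))
  } else {
    if (bin_width <= 0) stop("bin_width must be positive")
    lev <- as.integer(floor((values - rng[1]) / bin_width)) + 1L
  }
  lev
}
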
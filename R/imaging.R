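#' Single-channel fluorescence scan
#'
#' A 2-D grayscale intensity grid, or a 3-D stack awaiting Z-projection,
#' together with the scan condition (e.g. "HL3", "HL3-pH5.5", "HL3-NH4Cl").
#'
#' @param pixels numeric matrix (2-D) or array (3-D, planes in the third
#'   dimension) of nonnegative intensities.
#' @param condition condition label.
#' @param pixel_size optional pixel size in micrometers.
#' @return An object of class `image_scan`.
#' @export
image_scan <- function(pixels, condition = "HL3", pixel_size = NULL) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3)))
    stop("image_scan: pixels must be a 2-D matrix or 3-D array", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("image_scan: intensities must be finite and >= 0", call. = FALSE)
  structure(list(pixels = pixels, condition = condition,
                 pixel_size = pixel_size),
            class = "image_scan")
}

#' @export
print.image_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_scan> %s: %s\n", x$condition,
              paste(d, collapse = " x ")))
  invisible(x)
}

#' Maximum-intensity Z-projection
#'
#' @param stack an [image_scan] holding a 3-D stack (or an already-projected
#'   2-D image, returned unchanged), or a bare array.
#' @return An [image_scan] with the per-pixel maximum across planes.
#' @export
max_project <- function(stack) {
  px <- if (inherits(stack, "image_scan")) stack$pixels else stack
  cond <- if (inherits(stack, "image_scan")) stack$condition else "HL3"
  if (is.matrix(px)) return(image_scan(px, cond))
  if (!(is.array(px) && length(dim(px)) == 3) || dim(px)[3] < 1)
    stop("max_project: need a stack with >= 1 plane", call. = FALSE)
  image_scan(apply(px, c(1, 2), max), cond)
}

#' Fraction of image area above a fixed threshold
#'
#' The quantification used for pHluorin scans: after a fixed threshold removes
#' background, the percentage of area above the threshold measures the signal.
#' The comparison is strict (`> threshold`).
#'
#' @param image an [image_scan] (2-D) or numeric matrix.
#' @param threshold intensity threshold, >= 0.
#' @return Fraction of pixels strictly above the threshold, in `[0, 1]`.
#' @export
area_fraction_above <- function(image, threshold) {
  px <- if (inherits(image, "image_scan")) image$pixels else image
  if (!is.matrix(px)) stop("area_fraction_above: need a 2-D image", call. = FALSE)
  if (threshold < 0) stop("area_fraction_above: threshold must be >= 0", call. = FALSE)
  mean(px > threshold)
}

#' Otsu threshold suggestion
#'
#' Histogram-based between-class-variance maximization, offered only as a
#' starting suggestion; quantification always uses an explicitly supplied
#' fixed threshold.
#'
#' @param image an [image_scan] or matrix.
#' @param nbins number of histogram bins (default 256).
#' @return Suggested threshold on the image intensity scale.
#' @export
suggest_threshold_otsu <- function(image, nbins = 256L) {
  px <- as.numeric(if (inherits(image, "image_scan")) image$pixels else image)
  rng <- range(px)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(px, breaks, all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[nbins]
  bcv <- (mt * cw - cm)^2 / (cw * (1 - cw))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Paired-scan area-fraction ratio
#'
#' The pH-probe quantification: the same fixed threshold is applied to the
#' scan in the modified solution (second) and the scan in standard HL3
#' (first), and the ratio of above-threshold area fractions second/first is
#' reported. A ratio near 0 after acid quench means normally acidified
#' vesicles; a residual ratio reveals quench-resistant (intravesicular)
#' signal.
#'
#' @param first,second [image_scan]s (or matrices) of identical dimensions.
#' @param threshold fixed threshold applied to both scans.
#' @return List of class `paired_quantification` with `threshold`,
#'   `fraction_first`, `fraction_second`, `ratio` (NA with `undefined = TRUE`
#'   when the first fraction is 0).
#' @export
paired_ratio <- function(first, second, threshold) {
  p1 <- if (inherits(first, "image_scan")) first$pixels else first
  p2 <- if (inherits(second, "image_scan")) second$pixels else second
  if (!identical(dim(p1), dim(p2)))
    stop("paired_ratio: scans have different dimensions", call. = FALSE)
  f1 <- area_fraction_above(p1, threshold)
  f2 <- area_fraction_above(p2, threshold)
  structure(
    list(threshold = threshold, fraction_first = f1, fraction_second = f2,
         ratio = if (f1 > 0) f2 / f1 else NA_real_, undefined = f1 == 0),
    class = "paired_quantification")
}

#' Intensity within a binary mask
#'
#' Restricts the measurement to a region of interest, e.g. the FM-dye signal
#' within the mCD8::GFP-labeled synaptic area.
#'
#' @param image an [image_scan] or matrix.
#' @param mask logical (or 0/1) matrix of the same dimensions with at least
#'   one `TRUE` pixel.
#' @return List with `sum` and `mean` intensity over the mask.
#' @export
masked_intensity <- function(image, mask) {
  px <- if (inherits(image, "image_scan")) image$pixels else image
  mask <- mask > 0
  if (!identical(dim(px), dim(mask)))
    stop("masked_intensity: mask dimensions differ from image", call. = FALSE)
  if (!any(mask)) stop("masked_intensity: empty mask", call. = FALSE)
  v <- px[mask]
  list(sum = sum(v), mean = mean(v))
}

#' FM-dye released fraction from loaded/unloaded scans
#'
#' The fraction of previously loaded dye released during unloading:
#' `1 - unloaded/loaded`, where both intensities are measured within the GFP
#' mask. Both summed- and mean-intensity versions of the raw ratio are
#' reported (they coincide for a common mask).
#'
#' @param loaded,unloaded [image_scan]s or matrices of identical dimensions.
#' @param mask binary matrix restricting the measurement.
#' @return List with `released` (fraction), `ratio_sum`, `ratio_mean` (raw
#'   unloaded/loaded ratios) and `undefined` (TRUE when the loaded intensity
#'   is 0).
#' @export
unload_fraction <- function(loaded, unloaded, mask) {
  pl <- if (inherits(loaded, "image_scan")) loaded$pixels else loaded
  pu <- if (inherits(unloaded, "image_scan")) unloaded$pixels else unloaded
  if (!identical(dim(pl), dim(pu)))
    stop("unload_fraction: scans have different dimensions", call. = FALSE)
  ml <- masked_intensity(pl, mask)
  mu <- masked_intensity(pu, mask)
  if (ml$sum == 0)
    return(list(released = NA_real_, ratio_sum = NA_real_,
                ratio_mean = NA_real_, undefined = TRUE))
  list(released = 1 - mu$sum / ml$sum, ratio_sum = mu$sum / ml$sum,
       ratio_mean = mu$mean / ml$mean, undefined = FALSE)
}

#' Fraction of synaptic boutons larger than a diameter cutoff
#'
#' @param diameters numeric vector of bouton diameters in micrometers, > 0.
#' @param cutoff diameter cutoff in micrometers (default 4); the comparison is
#'   strict, so a bouton exactly at the cutoff is excluded.
#' @return Fraction of boutons with diameter strictly above the cutoff.
#' @export
large_bouton_fraction <- function(diameters, cutoff = 4) {
  if (length(diameters) == 0)
    stop("large_bouton_fraction: empty diameter list", call. = FALSE)
  if (any(diameters <= 0))
    stop("large_bouton_fraction: diameters must be > 0", call. = FALSE)
  mean(diameters > cutoff)
}
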
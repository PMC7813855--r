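# Tomogram reconstruction: the two processing pipelines for comb-illuminated
# SD-OCT data. The "full" pipeline Fourier-transforms the entire (k-space
# resampled) interferogram, non-illuminated pixels included, giving an
# A-scan of n_pixels/2 depths within the spectrometer's imaging range. The
# "subsampled" pipeline keeps only the comb-tone pixels, giving a short
# A-scan whose depth axis spans exactly one ambiguity range: reflectors
# beyond it fold back (optical-domain subsampling / circular ranging).

#' Subtract the mean spectrum of a B-scan
#'
#' Averages all spectra of a B-scan into a single background vector and
#' subtracts it from every A-scan, removing the reference DC and static
#' autocorrelation terms. Applied independently per B-scan; at an A-scan
#' rate \eqn{f_{\mathrm{line}}} with \eqn{N} lines per B-scan the operation
#' acts as a temporal high-pass of characteristic frequency
#' \eqn{f_{\mathrm{line}}/N}.
#'
#' @param bscan A `bscan` with at least two A-scans.
#' @return The `bscan` with the per-pixel mean removed (counts may be
#'   negative afterwards).
#' @export
background_subtract <- function(bscan) {
  stopifnot(inherits(bscan, "bscan"))
  if (ncol(bscan$counts) < 2L) {
    stop("background subtraction needs at least 2 A-scans per B-scan",
         call. = FALSE)
  }
  bscan$counts <- bscan$counts - rowMeans(bscan$counts)
  bscan$meta$background_subtracted <- TRUE
  bscan
}

#' Resample an interferogram to a uniform wavenumber grid
#'
#' Grating spectrometers sample uniformly in wavelength; Fourier-domain
#' reconstruction requires samples uniform in spectroscopic wavenumber
#' \eqn{\tilde\nu = 1/\lambda}. Cubic-spline interpolation onto a uniform
#' \eqn{\tilde\nu} grid of the same length, endpoints preserved. Inputs
#' already uniform in wavenumber pass through unchanged (to numerical
#' precision).
#'
#' @param x An `interferogram`, `bscan`, or numeric vector/matrix of counts
#'   (pixels in rows).
#' @param wavelength_axis Pixel wavelengths [m]; taken from the object when
#'   `x` is an `interferogram`/`bscan`. Must be strictly monotone.
#' @return Same class as the input, with `wavenumber` strictly increasing
#'   and uniform, and counts interpolated. For raw numeric input, a list
#'   with `counts` and `wavenumber`.
#' @export
resample_to_k <- function(x, wavelength_axis = NULL) {
  if (inherits(x, c("interferogram", "bscan"))) {
    wavelength_axis <- x$wavelength
    counts <- x$counts
  } else {
    counts <- x
  }
  if (is.null(wavelength_axis)) {
    stop("`wavelength_axis` is required for raw numeric input", call. = FALSE)
  }
  if (is.unsorted(wavelength_axis, strictly = TRUE) &&
      is.unsorted(rev(wavelength_axis), strictly = TRUE)) {
    stop("`wavelength_axis` must be strictly monotone", call. = FALSE)
  }
  k_in <- 1 / wavelength_axis
  n <- length(k_in)
  k_u <- seq(min(k_in), max(k_in), length.out = n)
  o <- order(k_in)
  resample_vec <- function(v) {
    stats::spline(k_in[o], v[o], xout = k_u, method = "fmm")$y
  }
  counts_u <- if (is.matrix(counts)) {
    apply(counts, 2L, resample_vec)
  } else {
    resample_vec(counts)
  }
  if (inherits(x, c("interferogram", "bscan"))) {
    x$counts <- counts_u
    x$wavenumber <- k_u
    x$wavelength <- 1 / k_u
    x$meta$resampled <- TRUE
    x
  } else {
    list(counts = counts_u, wavenumber = k_u)
  }
}

uniform_spacing <- function(k, tol = 1e-8) {
  d <- diff(k)
  if (max(abs(d - mean(d))) > tol * abs(mean(d))) NULL else mean(d)
}

#' Full-interferogram A-scan reconstruction
#'
#' Magnitude of the unitary discrete Fourier transform of a
#' uniform-wavenumber interferogram; positive depths only (bins 0 to
#' N/2 - 1, DC retained in bin 0 but excluded from image metrics). The
#' depth axis follows from the wavenumber sample spacing \eqn{\Delta k} as
#' \eqn{z_j = j / (2 N \Delta k)}, so the deepest bin sits at the
#' spectrometer limit \eqn{1/(4\Delta k)}.
#'
#' @param x An `interferogram`, a `bscan`, or a numeric vector/matrix of
#'   counts uniform in wavenumber.
#' @param wavenumber Uniform wavenumber axis [1/m] for raw numeric input.
#' @return Object of class `tomogram` with `method = "full"`: `amplitude`
#'   (depth x A-scans), `depth_axis` [m].
#' @export
ascan_full <- function(x, wavenumber = NULL) {
  if (inherits(x, c("interferogram", "bscan"))) {
    wavenumber <- x$wavenumber
    counts <- x$counts
  } else {
    counts <- x
  }
  if (is.null(wavenumber)) {
    stop("`wavenumber` axis required for raw numeric input", call. = FALSE)
  }
  if (wavenumber[1] > wavenumber[length(wavenumber)]) {
    wavenumber <- rev(wavenumber)
    counts <- if (is.matrix(counts)) counts[rev(seq_len(nrow(counts))), ,
                                            drop = FALSE] else rev(counts)
  }
  dk <- uniform_spacing(wavenumber)
  if (is.null(dk)) {
    stop("interferogram is not uniform in wavenumber; apply resample_to_k()",
         call. = FALSE)
  }
  counts <- as.matrix(counts)
  n <- nrow(counts)
  half <- n %/% 2L
  amp <- apply(counts, 2L, function(v) Mod(stats::fft(v))[seq_len(half)]) /
    sqrt(n)
  depth <- (seq_len(half) - 1L) / (2 * n * dk)
  new_tomogram(amp, depth, method = "full", ambiguity_depth = NULL)
}

new_tomogram <- function(amplitude, depth_axis, method, ambiguity_depth,
                         meta = list()) {
  structure(
    list(amplitude = as.matrix(amplitude), depth_axis = depth_axis,
         method = method, ambiguity_depth = ambiguity_depth, meta = meta),
    class = "tomogram")
}

#' @exportS3Method print tomogram
print.tomogram <- function(x, ...) {
  cat(sprintf("<tomogram [%s]: %d depths x %d A-scans, z up to %.3g mm%s>\n",
              x$method, nrow(x$amplitude), ncol(x$amplitude),
              max(x$depth_axis) * 1e3,
              if (!is.null(x$ambiguity_depth))
                sprintf(", ambiguity %.3g um", x$ambiguity_depth * 1e6)
              else ""))
  invisible(x)
}

#' @exportS3Method plot tomogram
plot.tomogram <- function(x, ...) {
  img <- 20 * log10(pmax(x$amplitude, max(x$amplitude) * 1e-6))
  graphics::image(seq_len(ncol(img)), x$depth_axis * 1e6, t(img),
                  col = gray.colors(256), xlab = "A-scan",
                  ylab = "depth [um]", ylim = rev(range(x$depth_axis * 1e6)),
                  ...)
  invisible(x)
}

#' Locate comb-tone pixels on the spectrometer
#'
#' Identifies one pixel per illuminated comb line: starting from the
#' brightest pixel, the detector is marched in both directions in steps of
#' the locally updated inter-tone spacing (initialized from
#' `expected_fsr_pixels`), taking the local maximum within half a spacing
#' of each predicted position. On ties the lower pixel index wins. The
#' march stops when candidate peaks fall below the noise floor or the local
#' spacing departs grossly from the running estimate. Inputs without comb
#' structure (e.g. a smooth SLD spectrum) are rejected via a peak-contrast
#' check.
#'
#' @param x An `interferogram`, `bscan` (mean spectrum used), or numeric
#'   reference spectrum.
#' @param expected_fsr_pixels Expected per-line pixel spacing; must be at
#'   least 2.
#' @param min_contrast Minimum ratio of median peak value to median
#'   mid-gap value for the input to count as comb-structured.
#' @return Object of class `comb_pixel_map`: data frame with columns
#'   `line`, `pixel` and `wavenumber` (strictly increasing pixel indices).
#' @export
detect_comb_pixels <- function(x, expected_fsr_pixels, min_contrast = 2) {
  if (inherits(x, "bscan")) {
    spec <- rowMeans(x$counts)
    k_axis <- x$wavenumber
  } else if (inherits(x, "interferogram")) {
    spec <- x$counts
    k_axis <- x$wavenumber
  } else {
    spec <- as.numeric(x)
    k_axis <- NULL
  }
  if (expected_fsr_pixels < 2) {
    stop("`expected_fsr_pixels` must be at least 2", call. = FALSE)
  }
  n <- length(spec)
  local_peak <- function(center, spacing) {
    lo <- max(1L, as.integer(round(center - spacing / 2)))
    hi <- min(n, as.integer(round(center + spacing / 2)))
    if (hi <= lo) return(NA_integer_)
    win <- spec[lo:hi]
    # a tone must stand well proud of the surrounding (gap) level;
    # which.max takes the first (lowest index) on ties
    cand <- lo + which.max(win) - 1L
    if (max(win) <= 6 * stats::median(win)) return(NA_integer_)
    cand
  }
  march <- function(start, dir) {
    out <- integer(0)
    pos <- start
    spacing <- expected_fsr_pixels
    repeat {
      cand <- local_peak(pos + dir * spacing, spacing)
      if (is.na(cand) || cand == pos) break
      new_spacing <- abs(cand - pos)
      if (abs(new_spacing - spacing) > 0.35 * spacing) break
      out <- c(out, cand)
      spacing <- new_spacing
      pos <- cand
    }
    out
  }
  p0 <- which.max(spec)
  pixels <- sort(unique(c(rev(march(p0, -1L)), p0, march(p0, +1L))))
  if (length(pixels) < 3L) {
    stop("fewer than 3 comb tones detected: input lacks comb structure",
         call. = FALSE)
  }
  mid <- floor((head(pixels, -1) + tail(pixels, -1)) / 2)
  peak_level <- stats::median(spec[pixels])
  gap_level <- max(stats::median(spec[mid]), abs(peak_level) * 1e-12,
                   .Machine$double.xmin)
  contrast <- peak_level / gap_level
  if (is.nan(contrast) || contrast < min_contrast) {
    stop("input lacks comb structure (peak/gap contrast too low)",
         call. = FALSE)
  }
  structure(
    data.frame(line = seq_along(pixels) - which(pixels == p0),
               pixel = pixels,
               wavenumber = if (is.null(k_axis)) NA_real_ else
                 k_axis[pixels]),
    class = c("comb_pixel_map", "data.frame"))
}

#' Comb-tone-subsampled A-scan reconstruction
#'
#' Optical-domain subsampling: all non-comb-tone pixels are discarded and
#' the magnitude DFT is taken over the comb-pixel vector alone. The A-scan
#' length equals the number of comb lines and its depth axis spans exactly
#' one ambiguity range \eqn{c / (2 f_{\mathrm{rep}})}; reflectors beyond it
#' appear folded back into the window (modulo the ambiguity range, with the
#' usual complex-conjugate mirror of magnitude reconstructions).
#'
#' @param x An `interferogram`, `bscan`, or numeric vector/matrix of counts.
#' @param map A `comb_pixel_map` from [detect_comb_pixels()].
#' @return Object of class `tomogram` with `method = "subsampled"` and
#'   `ambiguity_depth` set.
#' @export
ascan_subsampled <- function(x, map) {
  stopifnot(inherits(map, "comb_pixel_map"))
  if (nrow(map) < 3L) stop("comb pixel map has fewer than 3 lines",
                           call. = FALSE)
  if (is.unsorted(map$pixel, strictly = TRUE)) {
    stop("comb pixel map indices must be strictly increasing", call. = FALSE)
  }
  counts <- if (inherits(x, c("interferogram", "bscan"))) x$counts else x
  counts <- as.matrix(counts)
  v <- counts[map$pixel, , drop = FALSE]
  k <- map$wavenumber
  dk <- abs(stats::median(diff(k)))
  if (!is.finite(dk) || dk == 0) {
    stop("comb pixel map lacks a usable wavenumber axis", call. = FALSE)
  }
  if (k[1] > k[nrow(map)]) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  m <- nrow(v)
  amp <- apply(v, 2L, function(col) Mod(stats::fft(col))) / sqrt(m)
  amp <- matrix(amp, m, ncol(v))
  z_amb <- 1 / (2 * dk)
  depth <- (seq_len(m) - 1L) / m * z_amb
  new_tomogram(amp, depth, method = "subsampled", ambiguity_depth = z_amb)
}

#' Reconstruct a B-scan with either pipeline
#'
#' End-to-end wrapper: per-B-scan background subtraction, then either
#' k-space resampling plus full-length DFT (`method = "full"`) or comb-tone
#' selection plus short DFT (`method = "subsampled"`). Comb tones are
#' detected on the mean raw spectrum when no map is supplied.
#'
#' @param bscan A `bscan`.
#' @param method `"full"` or `"subsampled"`.
#' @param map Optional `comb_pixel_map` (subsampled method).
#' @param expected_fsr_pixels Expected tone spacing for automatic
#'   detection; derived from the acquisition FSR when available.
#' @param background Subtract the B-scan mean spectrum first (default TRUE;
#'   requires >= 2 A-scans).
#' @return A `tomogram`.
#' @export
reconstruct_bscan <- function(bscan, method = c("full", "subsampled"),
                              map = NULL, expected_fsr_pixels = NULL,
                              background = TRUE) {
  stopifnot(inherits(bscan, "bscan"))
  method <- match.arg(method)
  raw <- bscan
  if (background) bscan <- background_subtract(bscan)
  if (method == "full") {
    ascan_full(resample_to_k(bscan))
  } else {
    if (is.null(map)) {
      if (is.null(expected_fsr_pixels)) {
        fsr <- raw$meta$fsr
        if (is.null(fsr)) {
          stop("supply `map` or `expected_fsr_pixels` for subsampled method",
               call. = FALSE)
        }
        lam0 <- stats::median(raw$wavelength)
        dlam_pix <- abs(stats::median(diff(raw$wavelength)))
        expected_fsr_pixels <- (lam0^2 * fsr / .c0) / dlam_pix
      }
      map <- detect_comb_pixels(raw, expected_fsr_pixels)
    }
    ascan_subsampled(bscan, map)
  }
}

#' Logarithmic compression, median filtering and percentile clipping
#'
#' Display post-processing identical for every source type: the amplitude
#' is squared and compressed as \eqn{10\log_{10}}, each plane is smoothed
#' with a 3x3 median filter, and the result is clipped to the 0.01 % and
#' 99.9 % intensity percentiles of the filtered plane.
#'
#' @param x A `tomogram`, a numeric matrix (one plane), or a 3D array whose
#'   third dimension indexes planes.
#' @return Same shape as the input, in clipped dB units, with attribute
#'   `clip_bounds` (per plane). An all-constant plane is returned unclipped
#'   with attribute `degenerate = TRUE`.
#' @export
log_clip_filter <- function(x) {
  amp <- if (inherits(x, "tomogram")) x$amplitude else x
  check_nonnegative(amp, "amplitude")
  process_plane <- function(p) {
    eps <- max(p) * 1e-12
    if (max(p) == 0) eps <- .Machine$double.xmin
    db <- median_filter_3x3(10 * log10(pmax(p, eps)^2))
    b <- stats::quantile(db, c(1e-4, 0.999), names = FALSE)
    if (b[1] == b[2]) {
      return(structure(db, clip_bounds = b, degenerate = TRUE))
    }
    structure(pmin(pmax(db, b[1]), b[2]), clip_bounds = b)
  }
  if (is.matrix(amp)) {
    process_plane(amp)
  } else if (length(dim(amp)) == 3L) {
    res <- array(NA_real_, dim(amp))
    bounds <- matrix(NA_real_, dim(amp)[3], 2L)
    for (i in seq_len(dim(amp)[3])) {
      pl <- process_plane(amp[, , i])
      bounds[i, ] <- attr(pl, "clip_bounds")
      res[, , i] <- pl
    }
    attr(res, "clip_bounds") <- bounds
    res
  } else {
    stop("`x` must be a matrix, 3D array or tomogram", call. = FALSE)
  }
}

# 3x3 median filter with replicated borders (shift-and-stack construction).
median_filter_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  stack <- array(NA_real_, c(nr, nc, 9L))
  idx <- 1L
  for (dr in 0:2) {
    for (dc in 0:2) {
      stack[, , idx] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
      idx <- idx + 1L
    }
  }
  apply(stack, c(1L, 2L), stats::median)
}

#' Axial resolution from a mirror tomogram
#'
#' Full width at half maximum of the dominant peak of a mirror A-scan,
#' measured on the linear (non-logarithmic) amplitude scale; the peak
#' height is refined by parabolic interpolation over the three samples
#' around the maximum and the half-maximum crossings are located by linear
#' interpolation. The DC bin is excluded.
#'
#' @param x A `tomogram` (first A-scan used) or numeric amplitude vector.
#' @param depth_axis Depth axis [m] for raw numeric input.
#' @param min_peak_ratio The peak must exceed this multiple of the median
#'   amplitude (default 10), otherwise the measurement is rejected.
#' @return FWHM in metres.
#' @export
axial_resolution <- function(x, depth_axis = NULL, min_peak_ratio = 10) {
  if (inherits(x, "tomogram")) {
    a <- x$amplitude[, 1L]
    depth_axis <- x$depth_axis
  } else {
    a <- as.numeric(x)
  }
  if (is.null(depth_axis)) {
    stop("`depth_axis` required for raw numeric input", call. = FALSE)
  }
  a <- a[-1L]; depth_axis <- depth_axis[-1L]  # drop the DC bin
  i0 <- which.max(a)
  if (a[i0] < min_peak_ratio * stats::median(a)) {
    stop("no peak above 10x the median floor: not a mirror tomogram",
         call. = FALSE)
  }
  peak <- a[i0]
  if (i0 > 1L && i0 < length(a)) {
    y1 <- a[i0 - 1L]; y2 <- a[i0]; y3 <- a[i0 + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) peak <- y2 - (y1 - y3)^2 / (8 * denom)
  }
  fwhm_interp(depth_axis, a, half = peak / 2)
}

#' Dynamic range of a tomogram plane
#'
#' \eqn{10 \log_{10}} of the ratio between the maximum power (squared
#' amplitude) of the plane and the median power in a user-designated empty
#' (noise-only) region.
#'
#' @param plane Numeric amplitude vector or matrix (one plane), or a
#'   `tomogram` (its amplitude matrix).
#' @param noise_region Integer or logical index into `plane` designating
#'   the empty region.
#' @return Dynamic range in dB.
#' @export
dynamic_range <- function(plane, noise_region) {
  if (inherits(plane, "tomogram")) plane <- plane$amplitude
  p <- as.numeric(plane)^2
  if (length(p) == 0) stop("`plane` is empty", call. = FALSE)
  noise <- p[noise_region]
  if (length(noise) == 0) stop("`noise_region` selects nothing", call. = FALSE)
  has_signal <- max(p) > 2 * stats::median(p)
  if (has_signal && any(noise >= max(p) / 2)) {
    stop("`noise_region` overlaps the signal (contains near-peak power)",
         call. = FALSE)
  }
  10 * log10(max(p) / stats::median(noise))
}
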
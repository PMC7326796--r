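#' Scattering vector of a pixel at radial distance r from the beam center
#'
#' Uses the exact relation q = 4 pi sin(theta) / lambda with
#' theta = arctan(r / L) / 2 (the detector sits at scattering angle
#' 2 theta). Monotone increasing in r, decreasing in L and lambda.
#'
#' @param r radial distance from the beam center, metres, >= 0.
#' @param config an [instrument_config()].
#' @return q in 1/Angstrom, same length as `r`.
#' @export
pixel_q <- function(r, config) {
  if (any(r < 0)) stop("pixel_q: r must be >= 0")
  theta <- atan2(r, config$sdd) / 2
  4 * pi * sin(theta) / config$wavelength
}

# per-pixel geometry for a configuration: radial distance (m), azimuth (deg
# CCW from +x), q (1/A). Pixel centers at 0-based integer coordinates.
pixel_geometry <- function(config) {
  nx <- config$detector_shape[1]; ny <- config$detector_shape[2]
  px <- config$pixel_pitch / 1000  # m
  dx <- (seq_len(nx) - 1 - config$beam_center[1]) * px
  dy <- (seq_len(ny) - 1 - config$beam_center[2]) * px
  X <- matrix(dx, nx, ny)
  Y <- matrix(dy, nx, ny, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  list(r = r, phi = (atan2(Y, X) * 180 / pi) %% 360,
       q = pixel_q(r, config))
}

#' Apply detector corrections to a raw frame
#'
#' Implements the reduction arithmetic
#' \deqn{I = \frac{(counts - dark)/sensitivity}{monitor} - background,}
#' i.e. normalization to the incident-beam monitor counts with pixel
#' sensitivity, dark current and background corrections. Uncertainties come
#' from Poisson statistics on the raw counts only (sigma_counts =
#' sqrt(counts)) propagated through the same arithmetic; dark, sensitivity
#' and background are treated as exact.
#'
#' @param frame a [detector_frame()].
#' @return a `corrected_frame`: list with matrices `I`, `sigma`, `counts`
#'   plus `config` and `sample_id`.
#' @export
correct_frame <- function(frame) {
  stopifnot(inherits(frame, "detector_frame"))
  counts <- frame$counts
  dark <- if (is.null(frame$dark)) 0 else frame$dark
  sens <- if (is.null(frame$sensitivity)) 1 else frame$sensitivity
  bkg <- if (is.null(frame$background)) 0 else frame$background
  I <- ((counts - dark) / sens) / frame$monitor - bkg
  sigma <- (sqrt(counts) / sens) / frame$monitor
  structure(list(I = I, sigma = sigma, counts = counts,
                 config = frame$config, sample_id = frame$sample_id),
            class = "corrected_frame")
}

as_corrected <- function(x) {
  if (inherits(x, "detector_frame")) correct_frame(x)
  else if (inherits(x, "corrected_frame")) x
  else stop("expected a detector_frame or corrected_frame")
}

#' Detect scattering anisotropy in an annulus
#'
#' Computes the azimuthal intensity distribution of all pixels whose q falls
#' in `q_window` and measures the amplitude of its second circular harmonic
#' relative to the azimuthal mean (fibre scattering is two-fold symmetric).
#' Frames scoring above `threshold` are anisotropic and the harmonic phase
#' gives the lobe azimuth; otherwise the frame is reduced isotropically into
#' one scattering curve.
#'
#' @param x a [detector_frame()] or corrected frame.
#' @param q_window c(lo, hi) annulus in q, 1/Angstrom.
#' @param threshold anisotropy score threshold (default 0.1).
#' @return list with `isotropic` (logical), `score`, and `phi0` (lobe
#'   azimuth in degrees, in [0, 180)).
#' @export
detect_anisotropy <- function(x, q_window, threshold = 0.1) {
  cf <- as_corrected(x)
  geo <- pixel_geometry(cf$config)
  sel <- geo$q >= q_window[1] & geo$q <= q_window[2]
  if (!any(sel)) stop("detect_anisotropy: empty annulus")
  I <- cf$I[sel]
  phi <- geo$phi[sel] * pi / 180
  m <- mean(I)
  if (m <= 0) stop("detect_anisotropy: non-positive mean intensity in annulus")
  a2 <- 2 * mean(I * cos(2 * phi))
  b2 <- 2 * mean(I * sin(2 * phi))
  score <- sqrt(a2^2 + b2^2) / m
  phi0 <- (atan2(b2, a2) / 2 * 180 / pi) %% 180
  list(isotropic = score <= threshold, score = score, phi0 = phi0)
}

#' Reduce a corrected frame to a 1D profile over a sector
#'
#' Each in-range pixel is assigned to the nearest q bin center (no sub-pixel
#' splitting) and, when a sector is given, kept only if its azimuth falls in
#' the sector (pooling the 180-degree mirror wedge when the sector is
#' two-fold). Bin intensity is the mean of contributing pixel intensities
#' and the reported q is the mean pixel q of the bin (removing the
#' first-order binning bias on steep curves); the uncertainty is the
#' propagated Poisson error of that mean. Bins with no contributing pixels
#' are dropped. `sector = NULL` averages over all
#' azimuths (isotropic reduction).
#'
#' @param x a [detector_frame()] or corrected frame.
#' @param sector a [sector_def()] or NULL.
#' @param q_bins strictly increasing vector of bin centers, 1/Angstrom;
#'   default 100 linear bins over the configuration q_range.
#' @param label profile label; defaults to "isotropic" without a sector and
#'   "aligned" with one.
#' @return a [profile1d()]; provenance carries per-bin pixel counts
#'   (`n_pix`), pooled raw counts (`counts_sum`) and the sector definition.
#' @export
sector_reduce <- function(x, sector = NULL, q_bins = NULL, label = NULL) {
  cf <- as_corrected(x)
  cfg <- cf$config
  if (is.null(q_bins))
    q_bins <- seq(cfg$q_range[1], cfg$q_range[2], length.out = 100)
  if (is.unsorted(q_bins, strictly = TRUE))
    stop("sector_reduce: q_bins must be strictly increasing")
  if (is.null(label)) label <- if (is.null(sector)) "isotropic" else "aligned"
  geo <- pixel_geometry(cfg)
  nb <- length(q_bins)
  # nearest-center assignment: breaks midway between centers, half-spacing
  # margins at the ends
  breaks <- c(q_bins[1] - diff(q_bins[1:2]) / 2,
              q_bins[-nb] + diff(q_bins) / 2,
              q_bins[nb] + diff(q_bins[(nb - 1):nb]) / 2)
  idx <- findInterval(geo$q, breaks, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= nb
  if (!is.null(sector)) {
    period <- if (sector$twofold) 180 else 360
    dphi <- (geo$phi - sector$center + period / 2) %% period - period / 2
    keep <- keep & abs(dphi) <= sector$half_width
  }
  if (!any(keep)) stop("sector_reduce: sector covers no pixels in any bin")
  idxk <- idx[keep]
  n <- tabulate(idxk, nbins = nb)
  Isum <- as.vector(rowsum(cf$I[keep], idxk, reorder = TRUE))
  Vsum <- as.vector(rowsum(cf$sigma[keep]^2, idxk, reorder = TRUE))
  Csum <- as.vector(rowsum(as.numeric(cf$counts[keep]), idxk,
                           reorder = TRUE))
  Qsum <- as.vector(rowsum(geo$q[keep], idxk, reorder = TRUE))
  occ <- sort(unique(idxk))
  full_I <- full_V <- full_C <- full_Q <- numeric(nb)
  full_I[occ] <- Isum; full_V[occ] <- Vsum; full_C[occ] <- Csum
  full_Q[occ] <- Qsum
  nz <- n > 0
  profile1d(q = full_Q[nz] / n[nz],
            I = full_I[nz] / n[nz],
            sigma = sqrt(full_V[nz]) / n[nz],
            label = label, sample_id = cf$sample_id,
            provenance = list(n_pix = n[nz], counts_sum = full_C[nz],
                              bin_index = which(nz),
                              sector_center = if (is.null(sector)) NA
                                              else sector$center,
                              sector_half_width = if (is.null(sector)) NA
                                                  else sector$half_width,
                              sdd_m = cfg$sdd))
}

#' Merge profiles from the two instrument configurations
#'
#' The short-distance (high-q) curve is scaled onto the long-distance
#' (low-q) curve by the median intensity ratio over the q overlap, then the
#' two are concatenated, sorted in q, and coincident q points averaged with
#' propagated uncertainties. The scale factor is recorded in provenance.
#'
#' @param long_distance low-q [profile1d()] (longer sample-to-detector
#'   distance).
#' @param short_distance high-q [profile1d()].
#' @return merged [profile1d()] spanning min(q_long) to max(q_short).
#' @export
merge_profiles <- function(long_distance, short_distance) {
  la <- attr(long_distance, "label"); sa <- attr(short_distance, "label")
  if (!identical(la, sa))
    stop("merge_profiles: profiles have different sector labels")
  lo <- max(min(long_distance$q), min(short_distance$q))
  hi <- min(max(long_distance$q), max(short_distance$q))
  if (lo >= hi) stop("merge_profiles: q-ranges do not overlap")
  ov <- short_distance$q >= lo & short_distance$q <= hi
  Il <- stats::approx(long_distance$q, long_distance$I,
                      xout = short_distance$q[ov])$y
  scale <- stats::median(Il / short_distance$I[ov])
  q <- c(long_distance$q, short_distance$q)
  I <- c(long_distance$I, short_distance$I * scale)
  s <- c(long_distance$sigma, short_distance$sigma * scale)
  o <- order(q)
  q <- q[o]; I <- I[o]; s <- s[o]
  grp <- cumsum(!duplicated(q))
  qm <- tapply(q, grp, `[`, 1)
  Im <- tapply(I, grp, mean)
  sm <- sqrt(tapply(s^2, grp, sum)) / tapply(s, grp, length)
  profile1d(q = as.numeric(qm), I = as.numeric(Im), sigma = as.numeric(sm),
            label = la, sample_id = attr(long_distance, "sample_id"),
            provenance = c(list(merge_scale = scale),
                           list(overlap = c(lo, hi))))
}
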
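#' Composite empirical SANS model parameters
#'
#' Container for the parameters of the empirical scattering model used
#' throughout the package: a low-q power law \eqn{C_1 q^{-P_1}}, a mid-q
#' unified (Beaucage) level joining a Guinier regime of size \eqn{R_g} to a
#' power-law regime with exponent \eqn{P_2}, a Gaussian diffraction peak at
#' \eqn{q_0} whose position encodes the elementary-fibril spacing
#' \eqn{d = 2\pi/q_0}, and a flat background. Intensities are in one shared
#' arbitrary unit; q and all q-like quantities are in reciprocal Angstrom.
#'
#' @param pl_prefactor power-law prefactor \eqn{C_1} (intensity * A^-P1), >= 0.
#' @param pl_exponent power-law exponent \eqn{P_1}, in (1, 4.5].
#' @param level_G Guinier prefactor G of the unified level (intensity), >= 0.
#' @param level_Rg radius of gyration of the unified level, Angstrom, > 0
#'   (required whenever `level_G` or `level_B` is positive).
#' @param level_B high-q prefactor B of the unified level, >= 0.
#' @param level_P2 unified-level power-law exponent \eqn{P_2}, in (0, 4].
#' @param peak_amp Gaussian peak amplitude A (intensity), >= 0.
#' @param peak_center peak position \eqn{q_0}, 1/Angstrom, > 0.
#' @param peak_width Gaussian standard deviation w, 1/Angstrom, > 0.
#' @param background flat background (intensity), >= 0.
#' @return an object of class `sans_params` (named list).
#' @export
#' @examples
#' p <- model_params(pl_prefactor = 1e-6, pl_exponent = 3.7,
#'                   peak_amp = 0.5, peak_center = 0.123, peak_width = 0.015,
#'                   background = 0.05)
#' model_intensity(0.1, p, terms = c("power_law", "peak"))
model_params <- function(pl_prefactor = 0, pl_exponent = 4,
                         level_G = 0, level_Rg = 100, level_B = 0,
                         level_P2 = 2,
                         peak_amp = 0, peak_center = 0.1, peak_width = 0.01,
                         background = 0) {
  p <- list(pl_prefactor = pl_prefactor, pl_exponent = pl_exponent,
            level_G = level_G, level_Rg = level_Rg, level_B = level_B,
            level_P2 = level_P2, peak_amp = peak_amp,
            peak_center = peak_center, peak_width = peak_width,
            background = background)
  validate_model_params(p)
  structure(p, class = "sans_params")
}

validate_model_params <- function(p) {
  stopifnot(is.numeric(unlist(p)), !anyNA(unlist(p)))
  if (p$pl_prefactor < 0 || p$level_G < 0 || p$level_B < 0 ||
      p$peak_amp < 0 || p$background < 0)
    stop("all prefactors, amplitudes and background must be >= 0")
  if (p$pl_exponent <= 1 || p$pl_exponent > 4.5)
    stop("pl_exponent P1 must lie in (1, 4.5]")
  if (p$level_P2 <= 0 || p$level_P2 > 4)
    stop("level_P2 must lie in (0, 4]")
  if (p$level_Rg <= 0) stop("level_Rg must be > 0")
  if (p$peak_center <= 0) stop("peak_center q0 must be > 0")
  if (p$peak_width <= 0) stop("peak_width must be > 0")
  invisible(p)
}

#' @export
print.sans_params <- function(x, ...) {
  cat("<sans_params>\n")
  cat(sprintf("  power law : C1 = %.4g, P1 = %.3g\n",
              x$pl_prefactor, x$pl_exponent))
  cat(sprintf("  unified   : G = %.4g, Rg = %.4g A, B = %.4g, P2 = %.3g\n",
              x$level_G, x$level_Rg, x$level_B, x$level_P2))
  cat(sprintf("  peak      : A = %.4g, q0 = %.4g 1/A (d = %.3g nm), w = %.4g\n",
              x$peak_amp, x$peak_center,
              if (x$peak_center > 0) 2 * pi / x$peak_center / 10 else NA,
              x$peak_width))
  cat(sprintf("  background: %.4g\n", x$background))
  invisible(x)
}

#' Low-q power-law scattering term
#'
#' \eqn{I(q) = C q^{-P}}. Describes the steep low-q upturn from surfaces and
#' large-scale (> 100 nm) cell-wall structure; exponents near 4 indicate
#' smooth interfaces (Porod), 2-3 mass fractals.
#'
#' @param q scattering vector, 1/Angstrom, > 0.
#' @param prefactor scale C >= 0.
#' @param exponent power-law exponent P.
#' @return intensity, same length as `q`.
#' @export
power_law_term <- function(q, prefactor, exponent) {
  if (any(q <= 0)) stop("power_law_term: q must be > 0")
  prefactor * q^(-exponent)
}

#' Unified (Beaucage) level
#'
#' Empirical form smoothly joining a Guinier regime of size Rg to a power-law
#' regime with exponent P:
#' \deqn{I(q) = G e^{-q^2 R_g^2/3} + B (q^*)^{-P}, \quad
#'       q^* = q / [\mathrm{erf}(q R_g/\sqrt{6})]^3.}
#' Tends to G as q -> 0 and to B q^-P when q Rg >> 1.
#'
#' @param q scattering vector, 1/Angstrom.
#' @param G Guinier prefactor, >= 0.
#' @param Rg radius of gyration, Angstrom, > 0.
#' @param B power-law prefactor, >= 0.
#' @param P power-law exponent.
#' @param k empirical sharpening factor applied inside the erf argument;
#'   the canonical published form has k = 1 (the default).
#' @return intensity, same length as `q`.
#' @export
unified_level_term <- function(q, G, Rg, B, P, k = 1) {
  if (Rg <= 0) stop("unified_level_term: Rg must be > 0")
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  guinier <- G * exp(-q^2 * Rg^2 / 3)
  qs <- q / pmax(erf(k * q * Rg / sqrt(6)), .Machine$double.xmin)^3
  guinier + B * qs^(-P)
}

#' Gaussian diffraction peak
#'
#' \eqn{I(q) = A \exp(-(q-q_0)^2 / 2w^2)}. In wood cell walls the regular
#' packing of cellulose elementary fibrils produces this peak; its position
#' q0 gives the fibril spacing d = 2*pi/q0.
#'
#' @param q scattering vector, 1/Angstrom.
#' @param amp amplitude A, >= 0.
#' @param center peak position q0, 1/Angstrom, > 0.
#' @param width Gaussian standard deviation w, 1/Angstrom, > 0.
#' @return intensity, same length as `q`.
#' @export
gaussian_peak_term <- function(q, amp, center, width) {
  if (width <= 0) stop("gaussian_peak_term: width must be > 0")
  if (center <= 0) stop("gaussian_peak_term: center must be > 0")
  amp * exp(-(q - center)^2 / (2 * width^2))
}

#' Evaluate the composite empirical model
#'
#' Sum of the enabled terms plus (optionally) the flat background. The
#' two-level configuration used for subtracted curves is
#' `terms = c("power_law", "peak")`; the three-level configuration used for
#' amorphous/isotropic curves is `terms = c("power_law", "unified")` or all
#' three.
#'
#' @param q scattering vector, 1/Angstrom, > 0.
#' @param params a [model_params()] object.
#' @param terms character subset of `c("power_law", "unified", "peak")`.
#' @param background logical; include the flat background term.
#' @return intensity, same length as `q`.
#' @export
model_intensity <- function(q, params,
                            terms = c("power_law", "unified", "peak"),
                            background = TRUE) {
  terms <- match.arg(terms, c("power_law", "unified", "peak"),
                     several.ok = TRUE)
  if (length(terms) == 0 && !background)
    stop("model_intensity: empty term set")
  I <- numeric(length(q))
  if ("power_law" %in% terms)
    I <- I + power_law_term(q, params$pl_prefactor, params$pl_exponent)
  if ("unified" %in% terms)
    I <- I + unified_level_term(q, params$level_G, params$level_Rg,
                                params$level_B, params$level_P2)
  if ("peak" %in% terms)
    I <- I + gaussian_peak_term(q, params$peak_amp, params$peak_center,
                                params$peak_width)
  if (background) I <- I + params$background
  I
}

#' Resolution smearing by the instrument wavelength spread
#'
#' Convolves a model curve with a Gaussian in q whose width is proportional
#' to q: sigma_q = frac * q. A fractional FWHM wavelength spread
#' dlambda/lambda maps to frac = (dlambda/lambda) / (2 sqrt(2 ln 2)); the
#' beamline value 13% gives frac ~ 0.055. Kernel weights are renormalized on
#' the finite grid so a flat curve stays flat and the integral is preserved
#' away from the grid edges.
#'
#' @param q strictly increasing q grid, 1/Angstrom.
#' @param I model intensity on `q`.
#' @param frac fractional resolution sigma_q / q, >= 0. 0 returns `I`
#'   unchanged.
#' @return smeared intensity on the same grid.
#' @export
smear_profile <- function(q, I, frac) {
  if (is.unsorted(q, strictly = TRUE)) stop("smear_profile: q must be strictly increasing")
  if (frac < 0) stop("smear_profile: frac must be >= 0")
  if (frac == 0) return(I)
  as.vector(smear_matrix(q, frac) %*% I)
}

#' Precomputed row-stochastic smearing kernel for a fixed grid
#'
#' Returns the n x n matrix S such that `S %*% I` equals
#' [smear_profile]`(q, I, frac)`; useful when many curves (or optimizer
#' iterations) share one grid.
#'
#' @inheritParams smear_profile
#' @return numeric matrix with rows summing to 1.
#' @export
smear_matrix <- function(q, frac) {
  if (is.unsorted(q, strictly = TRUE))
    stop("smear_matrix: q must be strictly increasing")
  if (frac <= 0) stop("smear_matrix: frac must be > 0")
  # trapezoid-style quadrature weights on a possibly non-uniform grid
  n <- length(q)
  dq <- diff(q)
  wq <- c(dq[1] / 2, (dq[-(n - 1)] + dq[-1]) / 2, dq[n - 1] / 2)
  s <- frac * q
  K <- exp(-outer(q, q, `-`)^2 / (2 * s^2)) *
    rep(wq, each = n)  # K[i, j] = exp(-(q_j - q_i)^2 / 2 s_i^2) w_j
  K / rowSums(K)
}

#' Convert fractional FWHM wavelength spread to a sigma-type q resolution
#'
#' @param wavelength_spread FWHM fractional spread (e.g. 0.13).
#' @return sigma_q / q.
#' @export
wavelength_spread_to_sigma <- function(wavelength_spread) {
  wavelength_spread / (2 * sqrt(2 * log(2)))
}
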
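#' Fit configuration
#'
#' Controls which model terms are enabled, which parameters are held fixed
#' (as the staged protocol does for weak-featured samples, e.g. P1 = 3.6 or
#' a fixed fibril spacing), the fit q-window, the chi-square ratio used for
#' profile uncertainties, and optional initialization overrides.
#'
#' @param terms character subset of c("power_law", "unified", "peak").
#' @param fixed named list of parameters to hold fixed at the given values.
#' @param q_window c(lo, hi) fit window in q, 1/Angstrom.
#' @param chi2_ratio uncertainty rule multiplier (> 1); intervals are the
#'   range where chi2 < chi2_ratio * chi2_min. Default 1.06.
#' @param max_iterations optimizer iteration cap.
#' @param init named list of initial-value overrides.
#' @param smear_frac opt-in fractional resolution (sigma_q/q) convolved into
#'   the model during fitting; default 0 (resolution ignored, the common
#'   beamline practice).
#' @return a `fit_config` object.
#' @export
fit_config <- function(terms = c("power_law", "unified"),
                       fixed = list(), q_window = c(0.003, 0.27),
                       chi2_ratio = 1.06, max_iterations = 300,
                       init = list(), smear_frac = 0) {
  terms <- match.arg(terms, c("power_law", "unified", "peak"),
                     several.ok = TRUE)
  stopifnot(chi2_ratio > 1, q_window[1] < q_window[2])
  structure(list(terms = terms, fixed = fixed, q_window = q_window,
                 chi2_ratio = chi2_ratio, max_iterations = max_iterations,
                 init = init, smear_frac = smear_frac),
            class = "fit_config")
}

#' Subtract the amorphous profile from the aligned profile
#'
#' Enhances the elementary-fibril diffraction peak by removing the mid-q
#' scattering contribution common to both sectors. The amorphous curve is
#' linearly interpolated onto the aligned q grid within its range;
#' uncertainties add in quadrature; negative intensities are retained.
#'
#' @param aligned aligned-sector [profile1d()].
#' @param amorphous amorphous-sector [profile1d()].
#' @return a [profile1d()] labelled "subtracted".
#' @export
subtract_amorphous <- function(aligned, amorphous) {
  lo <- max(min(aligned$q), min(amorphous$q))
  hi <- min(max(aligned$q), max(amorphous$q))
  if (lo > hi) stop("subtract_amorphous: disjoint q-ranges")
  keep <- aligned$q >= lo & aligned$q <= hi
  qa <- aligned$q[keep]
  Ib <- stats::approx(amorphous$q, amorphous$I, xout = qa)$y
  sb <- stats::approx(amorphous$q, amorphous$sigma, xout = qa)$y
  profile1d(q = qa, I = aligned$I[keep] - Ib,
            sigma = sqrt(aligned$sigma[keep]^2 + sb^2),
            label = "subtracted", sample_id = attr(aligned, "sample_id"),
            provenance = list(operation = "aligned - amorphous"))
}

# --- internal fit engine --------------------------------------------------

# Parameter metadata: which model parameters each term activates, box
# bounds, and whether the optimizer works in log10 space (intensity scales
# span many decades).
.par_info <- function(q_window) {
  data.frame(
    name  = c("pl_prefactor", "pl_exponent", "level_G", "level_Rg",
              "level_B", "level_P2", "peak_amp", "peak_center",
              "peak_width", "background"),
    term  = c("power_law", "power_law", "unified", "unified", "unified",
              "unified", "peak", "peak", "peak", "background"),
    log   = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
              TRUE),
    lower = c(1e-20, 1.001, 1e-20, 5, 1e-20, 0.05, 1e-20,
              max(q_window[1], 0.01), 1e-3, 1e-12),
    upper = c(1e6, 4.5, 1e6, 2000, 1e6, 4, 1e6, q_window[2], 0.1, 1e6),
    stringsAsFactors = FALSE)
}

.fit_weights <- function(profile) {
  s <- profile$sigma
  if (all(s == 0)) {
    warning("all-zero sigma column: falling back to unit weights")
    return(rep(1, length(s)))
  }
  s[s == 0] <- min(s[s > 0])
  1 / s^2
}

# Build the chi-square objective over the free parameters (in transformed
# coordinates) for a window-restricted profile.
.make_objective <- function(q, I, w, terms, info, fixed_values,
                            smear_frac = 0) {
  free <- info$name[!(info$name %in% names(fixed_values)) &
                    (info$term %in% terms | info$term == "background")]
  model_terms <- intersect(terms, c("power_law", "unified", "peak"))
  base <- as.list(model_params())  # defaults for inactive params
  for (nm in names(fixed_values)) base[[nm]] <- fixed_values[[nm]]
  S <- if (smear_frac > 0) smear_matrix(q, smear_frac) else NULL
  is_log <- info$log[match(free, info$name)]
  eval_params <- function(theta) {
    p <- base
    for (j in seq_along(free))
      p[[free[j]]] <- if (is_log[j]) 10^theta[j] else theta[j]
    p
  }
  has_pl <- "power_law" %in% model_terms
  has_un <- "unified" %in% model_terms
  has_pk <- "peak" %in% model_terms
  q2 <- q^2
  chi2 <- function(theta) {
    p <- eval_params(theta)
    # inlined model evaluation (hot path: called thousands of times)
    M <- rep(p$background, length(q))
    if (has_pl) M <- M + p$pl_prefactor * q^(-p$pl_exponent)
    if (has_un) {
      e <- 2 * stats::pnorm(q * (p$level_Rg * sqrt(2 / 6))) - 1
      M <- M + p$level_G * exp(-q2 * (p$level_Rg^2 / 3)) +
        p$level_B * (q / pmax(e, 1e-300)^3)^(-p$level_P2)
    }
    if (has_pk)
      M <- M + p$peak_amp *
        exp(-(q - p$peak_center)^2 / (2 * p$peak_width^2))
    if (!is.null(S)) M <- as.vector(S %*% M)
    sum(w * (I - M)^2)
  }
  list(chi2 = chi2, free = free, eval_params = eval_params)
}

.transform <- function(v, is_log) ifelse(is_log, log10(pmax(v, 1e-20)), v)

# Run the bounded optimizer from one or more deterministic starts (a fixed
# start list, not random restarts, so results are reproducible without
# seeds); the best final chi-square wins.
.run_fit <- function(q, I, w, terms, info, fixed_values, starts,
                     max_iterations, smear_frac = 0) {
  obj <- .make_objective(q, I, w, terms, info, fixed_values, smear_frac)
  free <- obj$free
  ii <- match(free, info$name)
  lo <- .transform(info$lower[ii], info$log[ii])
  hi <- .transform(info$upper[ii], info$log[ii])
  ctl <- list(maxit = max_iterations, factr = 1e2,
              ndeps = rep(1e-7, length(free)))
  if (!is.null(names(starts))) starts <- list(starts)
  # explore on the cheap unsmeared objective, then polish each basin on
  # the full (smeared) objective; the unsmeared optimum is always close
  explore <- if (smear_frac > 0)
    .make_objective(q, I, w, terms, info, fixed_values, 0)$chi2
  else obj$chi2
  run_one <- function(fn, th0, rounds) {
    opt <- stats::optim(th0, fn, method = "L-BFGS-B",
                        lower = lo, upper = hi, control = ctl)
    # restarting L-BFGS-B from its own optimum escapes the flat-gradient
    # stalls of the log-scale parametrization
    improvement <- Inf
    for (rep in seq_len(rounds)) {
      opt2 <- stats::optim(opt$par, fn, method = "L-BFGS-B",
                           lower = lo, upper = hi, control = ctl)
      improvement <- opt$value - opt2$value
      opt <- opt2
      if (improvement <= 1e-10 * (1 + abs(opt$value))) break
    }
    opt$improvement <- improvement
    opt
  }
  best <- NULL
  for (start in starts) {
    th0 <- .transform(pmin(pmax(unlist(start[free]), info$lower[ii]),
                           info$upper[ii]), info$log[ii])
    opt <- run_one(explore, th0, rounds = 4)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish the winning basin on the full (smeared) objective
  if (smear_frac > 0) best <- run_one(obj$chi2, best$par, rounds = 2)
  # a line-search abort after the value has stabilized is convergence
  best$stable <- best$convergence == 0 ||
    best$improvement <= 1e-6 * (1 + abs(best$value))
  list(opt = best, obj = obj, free = free)
}

# Deterministic initialization heuristics (documented in the methods
# vignette): q0 from the subtracted-intensity argmax over 0.05-0.3 1/A,
# w = 0.2 q0, P1 from the low-q log-log slope, Rg from a mid-q Guinier
# line, prefactors from evaluating the data at window edges.
.default_init <- function(q, I, terms, q_window) {
  init <- list()
  pos <- I > 0
  # low-q power-law slope over q <= 0.01 (falling back to the lowest
  # quartile of points if the curve starts above 0.01)
  sel <- q <= 0.01 & pos
  if (sum(sel) < 3) sel <- q <= stats::quantile(q, 0.25) & pos
  if (sum(sel) >= 3) {
    co <- stats::coef(stats::lm(log(I[sel]) ~ log(q[sel])))
    P1 <- min(max(-co[2], 1.05), 4.5)
    init$pl_exponent <- P1
    init$pl_prefactor <- exp(co[1])
  } else {
    init$pl_exponent <- 3.5
    init$pl_prefactor <- max(I[1], 1e-8) * q[1]^3.5
  }
  bkg <- stats::quantile(I[q >= stats::quantile(q, 0.9)], 0.5)
  init$background <- max(bkg * 0.5, 1e-10)
  if ("peak" %in% terms) {
    wsel <- q >= max(0.05, q_window[1]) & q <= min(0.3, q_window[2])
    if (!any(wsel)) wsel <- q >= stats::median(q)
    q0 <- q[wsel][which.max(I[wsel])]
    init$peak_center <- q0
    init$peak_width <- 0.2 * q0
    init$peak_amp <- max(max(I[wsel]) - init$background, 1e-8)
  }
  if ("unified" %in% terms) {
    pl <- init$pl_prefactor * q^(-init$pl_exponent)
    resid <- I - pl - init$background
    gsel <- q >= 0.015 & q <= 0.06 & resid > 0
    Rg <- 60
    if (sum(gsel) >= 4) {
      co <- stats::coef(stats::lm(log(resid[gsel]) ~ I(q[gsel]^2)))
      if (is.finite(co[2]) && co[2] < 0) {
        Rg <- min(max(sqrt(-3 * co[2]), 10), 500)
      }
      init$level_G <- min(max(exp(co[1]), 1e-6), 1e5)
    } else {
      init$level_G <- max(stats::median(resid[resid > 0]), 1e-6)
    }
    init$level_Rg <- Rg
    init$level_P2 <- 2
    qh <- q[length(q)]
    rh <- max(I[length(I)] - init$background * 0.5, 1e-8)
    init$level_B <- rh * qh^2
  }
  init
}

.assemble_fit <- function(run, q, I, w, terms, fixed_values, q_window,
                          profile, smear_frac) {
  opt <- run$opt
  theta <- opt$par
  params <- do.call(model_params, run$obj$eval_params(theta))
  n <- length(q); k <- length(run$free)
  structure(list(params = params, free = run$free,
                 fixed = fixed_values,
                 terms = terms,
                 chi2 = opt$value,
                 red_chi2 = opt$value / max(n - k, 1),
                 n = n, n_free = k,
                 converged = isTRUE(opt$stable),
                 q_window = q_window,
                 smear_frac = smear_frac,
                 label = attr(profile, "label"),
                 sample_id = attr(profile, "sample_id"),
                 intervals = list()),
            class = "sans_fit")
}

#' @export
print.sans_fit <- function(x, ...) {
  cat(sprintf("<sans_fit> %s / %s: terms {%s}, chi2 = %.4g (reduced %.3g), %s\n",
              x$sample_id, x$label, paste(x$terms, collapse = ", "),
              x$chi2, x$red_chi2,
              if (x$converged) "converged" else "NOT converged"))
  p <- x$params
  show <- c("pl_prefactor", "pl_exponent",
            if ("unified" %in% x$terms)
              c("level_G", "level_Rg", "level_B", "level_P2"),
            if ("peak" %in% x$terms)
              c("peak_amp", "peak_center", "peak_width"),
            "background")
  for (nm in show) {
    tag <- if (nm %in% names(x$fixed)) " (fixed)" else ""
    iv <- x$intervals[[nm]]
    ivs <- if (!is.null(iv)) sprintf("  [%.4g, %.4g]", iv[1], iv[2]) else ""
    cat(sprintf("  %-13s %.5g%s%s\n", nm, p[[nm]], tag, ivs))
  }
  invisible(x)
}

.window_profile <- function(profile, q_window) {
  keep <- profile$q >= q_window[1] & profile$q <= q_window[2]
  list(q = profile$q[keep], I = profile$I[keep],
       sigma = profile$sigma[keep], keep = keep)
}

.fit_profile <- function(profile, config, terms) {
  wp <- .window_profile(profile, config$q_window)
  info <- .par_info(config$q_window)
  sub <- profile1d(wp$q, wp$I, pmax(wp$sigma, 0),
                   label = attr(profile, "label"),
                   sample_id = attr(profile, "sample_id"))
  w <- .fit_weights(sub)
  n_free_max <- sum(info$term %in% c(terms, "background") &
                    !(info$name %in% names(config$fixed)))
  if (length(wp$q) < n_free_max)
    stop("fewer data points than free parameters")
  start <- .default_init(wp$q, wp$I, terms, config$q_window)
  start <- utils::modifyList(start, config$init)
  for (nm in names(config$fixed)) start[[nm]] <- config$fixed[[nm]]
  # make sure every active parameter has a start value
  defaults <- as.list(model_params())
  for (nm in info$name[info$term %in% c(terms, "background")])
    if (is.null(start[[nm]])) start[[nm]] <- max(defaults[[nm]], 1e-8)
  starts <- list(start)
  # when a unified level competes with the power law at low q, the slope
  # heuristic under-estimates P1; add fixed alternative starts that
  # attribute the lowest-q point wholly to the power law (deterministic
  # multi-start, best final chi-square wins)
  if ("unified" %in% terms && length(config$init) == 0) {
    P1vs <- if ("pl_exponent" %in% names(config$fixed))
      config$fixed$pl_exponent else c(3.0, 3.9)
    for (P1v in P1vs) {
      s <- start
      s$pl_exponent <- P1v
      s$pl_prefactor <- max(wp$I[1], 1e-10) * wp$q[1]^P1v
      starts <- c(starts, list(s))
    }
  }
  run <- .run_fit(wp$q, wp$I, w, terms, info, config$fixed, starts,
                  config$max_iterations, config$smear_frac)
  .assemble_fit(run, wp$q, wp$I, w, terms, config$fixed, config$q_window,
                profile, config$smear_frac)
}

#' Two-level fit of a subtracted curve: low-q power law + diffraction peak
#'
#' Fits `power_law + peak + background` to an aligned-minus-amorphous
#' subtracted profile by weighted least squares (weights 1/sigma^2, linear
#' intensity space), yielding the low-q exponent P1 and the peak position
#' q0 from which the elementary-fibril spacing d = 2 pi / q0 follows.
#'
#' @param subtracted a [profile1d()] (normally labelled "subtracted").
#' @param config a [fit_config()]; the terms are forced to
#'   power_law + peak.
#' @return a `sans_fit` object.
#' @export
fit_two_level <- function(subtracted, config = fit_config()) {
  config$terms <- c("power_law", "peak")
  .fit_profile(subtracted, config, config$terms)
}

#' Three-level fit of an amorphous or isotropic curve
#'
#' Fits `power_law + unified + background` (optionally plus a weak peak via
#' `include_peak`) to extract the mid-q radius of gyration Rg and power-law
#' exponent P2. For weak-featured samples P1 can be supplied in
#' `config$fixed` (e.g. `fixed = list(pl_exponent = 3.6)`), reproducing the
#' fixed-parameter protocol.
#'
#' @param profile an amorphous or isotropic [profile1d()].
#' @param config a [fit_config()].
#' @param include_peak also fit a (weak) Gaussian peak term.
#' @return a `sans_fit` object; `$params$level_Rg` is in Angstrom
#'   (divide by 10 for nm).
#' @export
fit_three_level <- function(profile, config = fit_config(),
                            include_peak = FALSE) {
  config$terms <- c("power_law", "unified", if (include_peak) "peak")
  .fit_profile(profile, config, config$terms)
}

#' Chi-square profile uncertainty interval for one parameter
#'
#' Scans the named parameter away from its best-fit value, re-optimizing
#' all other free parameters at each scan point, and returns the largest
#' interval around the best fit on which the profiled chi-square stays
#' below `chi2_ratio * chi2_min` (the fractional chi-square band rule,
#' default ratio 1.06). Endpoints are bracketed by bisection to 1% of the
#' parameter value; an endpoint that runs into the parameter's box bound is
#' flagged open-ended.
#'
#' @param result a converged `sans_fit`.
#' @param data the fitted [profile1d()].
#' @param parameter parameter name (must be free in the fit).
#' @param chi2_ratio band multiplier; defaults to the value stored in the
#'   fit configuration (1.06).
#' @return numeric c(lo, hi) with attributes `open_lo` / `open_hi`.
#' @export
profile_uncertainty <- function(result, data, parameter,
                                chi2_ratio = 1.06) {
  stopifnot(inherits(result, "sans_fit"))
  if (!result$converged) stop("profile_uncertainty: fit did not converge")
  if (parameter %in% names(result$fixed) || !(parameter %in% result$free))
    stop(sprintf("profile_uncertainty: parameter '%s' is not free",
                 parameter))
  if (chi2_ratio <= 1) stop("chi2_ratio must be > 1")
  wp <- .window_profile(data, result$q_window)
  info <- .par_info(result$q_window)
  sub <- profile1d(wp$q, wp$I, wp$sigma, label = result$label)
  w <- suppressWarnings(.fit_weights(sub))
  best <- result$params[[parameter]]
  target <- chi2_ratio * max(result$chi2, .Machine$double.eps)
  start_all <- as.list(result$params)
  prow <- match(parameter, info$name)
  # profiled chi2 with `parameter` clamped at v
  prof_chi2 <- function(v) {
    fixed <- result$fixed
    fixed[[parameter]] <- v
    others <- setdiff(result$free, parameter)
    if (length(others) == 0) {
      obj <- .make_objective(wp$q, wp$I, w, result$terms, info, fixed,
                             result$smear_frac)
      return(obj$chi2(numeric(0)))
    }
    run <- .run_fit(wp$q, wp$I, w, result$terms, info, fixed, start_all,
                    500, result$smear_frac)
    run$opt$value
  }
  step0 <- max(abs(best) * 0.01, 1e-12)
  find_edge <- function(dir) {
    bound <- if (dir > 0) info$upper[prow] else info$lower[prow]
    step <- step0
    a <- best
    repeat {
      b <- best + dir * step
      hit_bound <- (dir > 0 && b >= bound) || (dir < 0 && b <= bound)
      if (hit_bound) b <- bound
      if (prof_chi2(b) > target) break
      a <- b
      if (hit_bound) return(list(v = bound, open = TRUE))
      step <- step * 2
    }
    # bisect in [a, b] to 1% of parameter value
    tol <- max(abs(best) * 0.01, 1e-12)
    while (abs(b - a) > tol) {
      m <- (a + b) / 2
      if (prof_chi2(m) > target) b <- m else a <- m
    }
    list(v = (a + b) / 2, open = FALSE)
  }
  up <- find_edge(+1)
  dn <- find_edge(-1)
  structure(c(dn$v, up$v), open_lo = dn$open, open_hi = up$open)
}

# --- fit-result serialization --------------------------------------------

#' Write a fit result as a flat key-value report file
#'
#' One line per item: `key<TAB>value`. Parameters appear as
#' `param.<name>`, fixed flags as `fixed.<name>`, intervals as
#' `interval.<name>.lo/.hi`; chi-square statistics and labels round-trip
#' via [read_fit_result()].
#'
#' @param fit a `sans_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  ln <- c(sprintf("sample_id\t%s", fit$sample_id),
          sprintf("label\t%s", fit$label),
          sprintf("terms\t%s", paste(fit$terms, collapse = ",")),
          sprintf("chi2\t%.17g", fit$chi2),
          sprintf("red_chi2\t%.17g", fit$red_chi2),
          sprintf("n\t%d", fit$n),
          sprintf("converged\t%s", fit$converged),
          sprintf("q_window\t%.17g %.17g", fit$q_window[1],
                  fit$q_window[2]))
  for (nm in names(fit$params))
    ln <- c(ln, sprintf("param.%s\t%.17g", nm, fit$params[[nm]]))
  for (nm in names(fit$fixed))
    ln <- c(ln, sprintf("fixed.%s\tTRUE", nm))
  for (nm in names(fit$intervals)) {
    iv <- fit$intervals[[nm]]
    ln <- c(ln, sprintf("interval.%s.lo\t%.17g", nm, iv[1]),
            sprintf("interval.%s.hi\t%.17g", nm, iv[2]))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a fit-result report file written by [write_fit_result()]
#'
#' @param path input path.
#' @return a `sans_fit` (without the data-dependent internals).
#' @export
read_fit_result <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  pn <- kv$key[startsWith(kv$key, "param.")]
  params <- stats::setNames(as.numeric(kv$value[match(pn, kv$key)]),
                            sub("^param\\.", "", pn))
  fx <- sub("^fixed\\.", "", kv$key[startsWith(kv$key, "fixed.")])
  ivn <- kv$key[startsWith(kv$key, "interval.")]
  intervals <- list()
  for (nm in unique(sub("^interval\\.(.*)\\.(lo|hi)$", "\\1", ivn))) {
    intervals[[nm]] <- c(as.numeric(get(sprintf("interval.%s.lo", nm))),
                         as.numeric(get(sprintf("interval.%s.hi", nm))))
  }
  terms <- strsplit(get("terms"), ",")[[1]]
  free <- setdiff(.par_info(c(0.003, 0.3))$name, fx)
  structure(list(params = do.call(model_params, as.list(params)),
                 free = free,
                 fixed = stats::setNames(as.list(params[fx]), fx),
                 terms = terms,
                 chi2 = as.numeric(get("chi2")),
                 red_chi2 = as.numeric(get("red_chi2")),
                 n = as.integer(get("n")),
                 converged = as.logical(get("converged")),
                 q_window = as.numeric(strsplit(get("q_window"),
                                                " ")[[1]]),
                 smear_frac = 0,
                 label = get("label"), sample_id = get("sample_id"),
                 intervals = intervals),
            class = "sans_fit")
}
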
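#' Elementary-fibril spacing from the diffraction peak position
#'
#' The center-to-center spacing of regularly packed cellulose elementary
#' fibrils follows from the diffraction peak position as d = 2 pi / q0,
#' converted from Angstrom to nanometres. An uncertainty interval on q0 is
#' mapped through the same (monotone decreasing) transform, so the interval
#' endpoints swap.
#'
#' @param q0 peak position, 1/Angstrom, > 0; may be a vector.
#' @param interval optional c(lo, hi) interval on q0.
#' @return spacing in nm; if `interval` is given, attribute `interval`
#'   carries the transformed c(lo, hi).
#' @export
ef_spacing_nm <- function(q0, interval = NULL) {
  if (any(q0 <= 0)) stop("ef_spacing_nm: q0 must be > 0")
  d <- (2 * pi / q0) / 10
  if (!is.null(interval)) {
    if (any(interval <= 0)) stop("ef_spacing_nm: interval must be > 0")
    attr(d, "interval") <- sort((2 * pi / interval) / 10)
  }
  d
}

#' Percent change of a treated value relative to a reference
#'
#' 100 * (treated - reference) / reference; used to express, e.g., the
#' relative increase in elementary-fibril spacing across treatment levels.
#'
#' @param reference reference value, > 0.
#' @param treated treated value.
#' @return percent change.
#' @export
relative_change_pct <- function(reference, treated) {
  if (any(reference <= 0)) stop("relative_change_pct: reference must be > 0")
  100 * (treated - reference) / reference
}

#' Classify a scattering vector into the conventional q regions
#'
#' Low-q spans 0.001-0.01, mid-q 0.01-0.1 and high-q 0.1-0.3 (1/Angstrom);
#' bins are half-open [lo, hi) except high-q which is closed at 0.3.
#' Anything outside is "out_of_range".
#'
#' @param q scattering vector(s), 1/Angstrom, >= 0.
#' @return character vector in {"low", "mid", "high", "out_of_range"}.
#' @export
classify_q_region <- function(q) {
  if (any(q < 0)) stop("classify_q_region: q must be >= 0")
  out <- rep("out_of_range", length(q))
  out[q >= 0.001 & q < 0.01] <- "low"
  out[q >= 0.01 & q < 0.1] <- "mid"
  out[q >= 0.1 & q <= 0.3] <- "high"
  out
}

.fmt_val <- function(value, interval, fixed, digits = 2) {
  if (is.null(value) || is.na(value)) return("-")
  v <- formatC(round(value, digits), format = "f", digits = digits)
  if (fixed) return(paste0(v, "**"))
  if (!is.null(interval) && !anyNA(interval)) {
    hw <- (interval[2] - interval[1]) / 2
    return(sprintf("%s ± %s", v,
                   formatC(round(hw, digits), format = "f",
                           digits = digits)))
  }
  v
}

#' Assemble a study-level nanostructure report
#'
#' One row per sample: P1 and the elementary-fibril spacing d come from the
#' two-level fit of the subtracted curve; Rg (nm) and P2 from the
#' three-level fit of the amorphous/isotropic curve. Fixed values are
#' flagged and carry no interval. Missing fits yield explicit NA markers.
#'
#' @param fits named list (by sample_id); each element is a list with
#'   optional components `two_level` and `three_level` (`sans_fit`
#'   objects).
#' @param metadata data.frame with column `sample_id` and optional
#'   treatment-label columns (delignification, cmf_pulses, decay_days,
#'   enzyme); row order defines report order.
#' @return data.frame of class `sans_report` with numeric columns
#'   P1, Rg_nm, P2, d_nm, their interval columns, and fixed flags.
#' @export
compile_report <- function(fits, metadata) {
  if (nrow(metadata) == 0) {
    out <- data.frame(sample_id = character(0))
    class(out) <- c("sans_report", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    sid <- metadata$sample_id[i]
    f <- fits[[sid]]
    row <- metadata[i, , drop = FALSE]
    row$P1 <- row$P1_lo <- row$P1_hi <- NA_real_
    row$P1_fixed <- FALSE
    row$Rg_nm <- row$Rg_lo <- row$Rg_hi <- NA_real_
    row$P2 <- row$P2_lo <- row$P2_hi <- NA_real_
    row$d_nm <- row$d_lo <- row$d_hi <- NA_real_
    row$d_fixed <- FALSE
    tl <- f$two_level
    if (!is.null(tl)) {
      row$P1 <- tl$params$pl_exponent
      row$P1_fixed <- "pl_exponent" %in% names(tl$fixed)
      iv <- tl$intervals$pl_exponent
      if (!is.null(iv)) { row$P1_lo <- iv[1]; row$P1_hi <- iv[2] }
      row$d_nm <- ef_spacing_nm(tl$params$peak_center)
      row$d_fixed <- "peak_center" %in% names(tl$fixed)
      iv <- tl$intervals$peak_center
      if (!is.null(iv)) {
        dv <- sort((2 * pi / iv) / 10)
        row$d_lo <- dv[1]; row$d_hi <- dv[2]
      }
    }
    th <- f$three_level
    if (!is.null(th)) {
      if (is.null(tl)) {  # shavings protocol: P1 reported from this fit
        row$P1 <- th$params$pl_exponent
        row$P1_fixed <- "pl_exponent" %in% names(th$fixed)
        iv <- th$intervals$pl_exponent
        if (!is.null(iv)) { row$P1_lo <- iv[1]; row$P1_hi <- iv[2] }
      }
      row$Rg_nm <- th$params$level_Rg / 10
      iv <- th$intervals$level_Rg
      if (!is.null(iv)) { row$Rg_lo <- iv[1] / 10; row$Rg_hi <- iv[2] / 10 }
      row$P2 <- th$params$level_P2
      iv <- th$intervals$level_P2
      if (!is.null(iv)) { row$P2_lo <- iv[1]; row$P2_hi <- iv[2] }
    }
    if (is.null(tl) && is.null(th))
      message(sprintf("compile_report: no fits for sample '%s'", sid))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sans_report", "data.frame")
  out
}

#' @export
print.sans_report <- function(x, digits = 2, ...) {
  if (nrow(x) == 0) { cat("<sans_report> empty\n"); return(invisible(x)) }
  cat(sprintf("%-22s %-14s %-12s %-12s %-14s\n",
              "Sample", "P1 (low-q)", "Rg nm (mid)", "P2 (mid)",
              "EF spacing nm"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-22s %-14s %-12s %-12s %-14s\n",
                x$sample_id[i],
                .fmt_val(x$P1[i], c(x$P1_lo[i], x$P1_hi[i]),
                         x$P1_fixed[i], digits),
                .fmt_val(x$Rg_nm[i], c(x$Rg_lo[i], x$Rg_hi[i]), FALSE,
                         digits),
                .fmt_val(x$P2[i], c(x$P2_lo[i], x$P2_hi[i]), FALSE,
                         digits),
                .fmt_val(x$d_nm[i], c(x$d_lo[i], x$d_hi[i]),
                         x$d_fixed[i], digits)))
  }
  invisible(x)
}

#' Write a report both as CSV and as aligned human-readable text
#'
#' @param report a `sans_report` from [compile_report()].
#' @param csv_path,txt_path output paths (either may be NULL to skip).
#' @param digits rounding for the text report (default 2, matching the
#'   two-decimal convention of published deconstruction tables).
#' @return invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL,
                         digits = 2) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    sink(txt_path); print(report, digits = digits); sink()
  }
  invisible(report)
}
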
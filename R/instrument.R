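#' Instrument configuration for one detector distance
#'
#' Geometry and beam metadata needed to map detector pixels to scattering
#' vectors. The reference geometry is a 6 Angstrom beam with 13% FWHM wavelength
#' spread measured at two sample-to-detector distances, 1.7 m (high q) and
#' 14.5 m (low q), jointly covering q = 0.003-0.27 1/Angstrom.
#'
#' @param wavelength neutron wavelength lambda, Angstrom.
#' @param wavelength_spread FWHM fractional spread dlambda/lambda in [0, 1).
#' @param sdd sample-to-detector distance L, metres.
#' @param beam_center c(x, y) beam-center in pixel coordinates (0-based,
#'   pixel centers at integers; may be fractional).
#' @param pixel_pitch pixel pitch, millimetres.
#' @param detector_shape c(nx, ny) detector size in pixels.
#' @param q_range c(q_min, q_max) usable q range, 1/Angstrom.
#' @return an `instrument_config` object.
#' @export
instrument_config <- function(wavelength = 6, wavelength_spread = 0.13,
                              sdd = 1.7,
                              beam_center = c(63.5, 63.5),
                              pixel_pitch = 8,
                              detector_shape = c(128L, 128L),
                              q_range = c(0.012, 0.27)) {
  stopifnot(wavelength > 0, sdd > 0,
            wavelength_spread >= 0, wavelength_spread < 1,
            length(beam_center) == 2, length(detector_shape) == 2,
            pixel_pitch > 0, length(q_range) == 2, q_range[1] < q_range[2])
  structure(list(wavelength = wavelength,
                 wavelength_spread = wavelength_spread,
                 sdd = sdd, beam_center = as.numeric(beam_center),
                 pixel_pitch = pixel_pitch,
                 detector_shape = as.integer(detector_shape),
                 q_range = as.numeric(q_range)),
            class = "instrument_config")
}

#' Default two-configuration instrument setup
#'
#' The long (14.5 m) configuration acquires the lowest q values and the
#' short (1.7 m) configuration the higher q data; merged they cover
#' 0.003-0.27 1/Angstrom.
#'
#' @return named list with elements `long` and `short`.
#' @export
default_configs <- function() {
  list(long  = instrument_config(sdd = 14.5, q_range = c(0.003, 0.036)),
       short = instrument_config(sdd = 1.7,  q_range = c(0.012, 0.27)))
}

#' Raw detector frame with correction inputs
#'
#' Holds one 2D counts grid plus the normalization inputs named by the
#' reduction protocol: incident-beam monitor counts, dark-current frame,
#' pixel sensitivity map and background frame. Absent optional inputs are
#' treated as zero (dark, background) or one (sensitivity).
#'
#' @param counts non-negative integer matrix, dim = detector_shape (nx rows,
#'   ny columns; row index = detector x).
#' @param config an [instrument_config()].
#' @param monitor incident-beam monitor counts, > 0.
#' @param dark optional dark-current counts grid (same shape).
#' @param sensitivity optional positive per-pixel sensitivity map.
#' @param background optional background intensity grid subtracted after
#'   normalization (already in normalized intensity units).
#' @param sample_id sample label.
#' @return a `detector_frame` object.
#' @export
detector_frame <- function(counts, config, monitor = 1,
                           dark = NULL, sensitivity = NULL,
                           background = NULL, sample_id = "") {
  stopifnot(inherits(config, "instrument_config"))
  counts <- as.matrix(counts)
  if (!all(dim(counts) == config$detector_shape))
    stop("detector_frame: counts shape does not match detector_shape")
  if (any(counts < 0)) stop("detector_frame: negative counts")
  if (monitor <= 0) stop("detector_frame: monitor must be > 0")
  chk <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dim(counts)))
      stop(sprintf("detector_frame: %s shape mismatch", nm))
    m
  }
  sensitivity <- chk(sensitivity, "sensitivity")
  if (!is.null(sensitivity) && any(sensitivity <= 0))
    stop("detector_frame: sensitivity entries must be > 0")
  structure(list(counts = counts, config = config, monitor = monitor,
                 dark = chk(dark, "dark"), sensitivity = sensitivity,
                 background = chk(background, "background"),
                 sample_id = sample_id),
            class = "detector_frame")
}

#' Reduced 1D scattering profile
#'
#' Columns q (strictly increasing, 1/Angstrom), I (arbitrary intensity
#' units) and sigma (1-sigma uncertainty), with a sector label
#' (aligned / amorphous / isotropic / subtracted), sample identity and
#' free-form provenance.
#'
#' @param q,I,sigma equal-length numeric vectors; `sigma` >= 0.
#' @param label one of "aligned", "amorphous", "isotropic", "subtracted".
#' @param sample_id sample label.
#' @param sigma_q optional resolution column.
#' @param provenance named list of reduction/fit metadata.
#' @return a `profile1d` object (data.frame with attributes).
#' @export
profile1d <- function(q, I, sigma, label = "isotropic", sample_id = "",
                      sigma_q = NULL, provenance = list()) {
  stopifnot(length(q) == length(I), length(I) == length(sigma))
  if (is.unsorted(q, strictly = TRUE))
    stop("profile1d: q must be strictly increasing")
  if (any(sigma < 0)) stop("profile1d: sigma must be >= 0")
  label <- match.arg(label, c("aligned", "amorphous", "isotropic",
                              "subtracted"))
  df <- data.frame(q = q, I = I, sigma = sigma)
  if (!is.null(sigma_q)) df$sigma_q <- sigma_q
  structure(df, class = c("profile1d", "data.frame"),
            label = label, sample_id = sample_id, provenance = provenance)
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %s / %s: %d points, q in [%.4g, %.4g] 1/A\n",
              attr(x, "sample_id"), attr(x, "label"), nrow(x),
              min(x$q), max(x$q)))
  invisible(x)
}

#' Azimuthal sector definition
#'
#' A wedge of the detector image. Azimuth is measured in degrees
#' counterclockwise from the detector +x axis; with `twofold = TRUE`
#' (default) the sector and its 180-degree mirror are pooled, matching the
#' two-fold symmetry of fibre scattering.
#'
#' @param center center azimuth phi0, degrees in [0, 360).
#' @param half_width sector half width, degrees in (0, 90].
#' @param twofold pool the mirror sector at phi0 + 180.
#' @return a `sector` object.
#' @export
sector_def <- function(center = 0, half_width = 25, twofold = TRUE) {
  center <- center %% 360
  if (half_width <= 0 || half_width > 90)
    stop("sector_def: half_width must be in (0, 90]")
  structure(list(center = center, half_width = half_width,
                 twofold = isTRUE(twofold)),
            class = "sector")
}

# --- plain-text frame container ------------------------------------------
# Sectioned ASCII stand-in for the NXcanSAS-style HDF5 layout: '#'-prefixed
# "key: value" attribute lines, then one "# dataset: <name>" line per grid
# followed by integer/numeric rows. Counts are bit-exact integers.

#' Write a detector frame to a sectioned ASCII file
#'
#' @param frame a [detector_frame()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  cfg <- frame$config
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# wavelength_A: %.17g", cfg$wavelength),
           sprintf("# wavelength_spread: %.17g", cfg$wavelength_spread),
           sprintf("# sdd_m: %.17g", cfg$sdd),
           sprintf("# beam_center_px: %.17g %.17g",
                   cfg$beam_center[1], cfg$beam_center[2]),
           sprintf("# pixel_pitch_mm: %.17g", cfg$pixel_pitch),
           sprintf("# detector_shape: %d %d",
                   cfg$detector_shape[1], cfg$detector_shape[2]),
           sprintf("# q_range: %.17g %.17g", cfg$q_range[1], cfg$q_range[2]),
           sprintf("# monitor: %.17g", frame$monitor),
           sprintf("# sample_id: %s", frame$sample_id))
  writeLines(hdr, con)
  wgrid <- function(name, m) {
    if (is.null(m)) return(invisible())
    writeLines(sprintf("# dataset: %s", name), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  }
  wgrid("counts", frame$counts)
  wgrid("dark", frame$dark)
  wgrid("sensitivity", frame$sensitivity)
  wgrid("background", frame$background)
  invisible(path)
}

#' Read a detector frame written by [write_frame()]
#'
#' @param path input file path.
#' @return a [detector_frame()].
#' @export
read_frame <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- sub("^# *", "", lines[is_hdr])
  key <- sub(":.*$", "", kv)
  val <- trimws(sub("^[^:]*: *", "", kv))
  get <- function(k) val[match(k, key)]
  nums <- function(k) as.numeric(strsplit(get(k), "[[:space:]]+")[[1]])
  cfg <- instrument_config(wavelength = nums("wavelength_A"),
                           wavelength_spread = nums("wavelength_spread"),
                           sdd = nums("sdd_m"),
                           beam_center = nums("beam_center_px"),
                           pixel_pitch = nums("pixel_pitch_mm"),
                           detector_shape = nums("detector_shape"),
                           q_range = nums("q_range"))
  nx <- cfg$detector_shape[1]
  hdr_idx <- which(is_hdr)
  ds <- which(key == "dataset")
  ds_lines <- hdr_idx[ds]
  ds_names <- val[ds]
  grids <- list()
  for (j in seq_along(ds_lines)) {
    from <- ds_lines[j] + 1
    to <- if (j < length(ds_lines)) ds_lines[j + 1] - 1 else length(lines)
    block <- lines[from:to]
    block <- block[!startsWith(block, "#") & nzchar(block)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "[[:space:]]+"),
                               as.numeric))
    stopifnot(nrow(m) == nx)
    grids[[ds_names[j]]] <- m
  }
  if (!is.null(grids$counts) && all(grids$counts == round(grids$counts)) &&
      max(grids$counts) <= .Machine$integer.max)
    storage.mode(grids$counts) <- "integer"
  detector_frame(grids$counts, cfg, monitor = nums("monitor"),
                 dark = grids$dark, sensitivity = grids$sensitivity,
                 background = grids$background, sample_id = get("sample_id"))
}

# --- ASCII 1D profile I/O -------------------------------------------------

#' Write a 1D profile as ASCII columns
#'
#' '#'-prefixed header lines carry sample_id, label and provenance, followed
#' by whitespace-separated columns q (1/Angstrom), I, sigma and optionally
#' sigma_q.
#'
#' @param profile a [profile1d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id: %s", attr(profile, "sample_id")), con)
  writeLines(sprintf("# label: %s", attr(profile, "label")), con)
  prov <- attr(profile, "provenance")
  for (nm in names(prov))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(prov[[nm]], digits = 17),
                             collapse = " ")), con)
  writeLines(paste("#", paste(names(profile), collapse = " ")), con)
  utils::write.table(format(profile, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII 1D profile written by [write_profile()]
#'
#' @param path input file path.
#' @return a [profile1d()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- sub("^# *", "", hdr)
  has_colon <- grepl(":", kv, fixed = TRUE)
  key <- sub(":.*$", "", kv[has_colon])
  val <- trimws(sub("^[^:]*: *", "", kv[has_colon]))
  cols <- strsplit(trimws(kv[!has_colon][length(kv[!has_colon])]),
                   "[[:space:]]+")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  colnames(m) <- cols
  prov_keys <- setdiff(key, c("sample_id", "label"))
  prov <- stats::setNames(as.list(val[match(prov_keys, key)]), prov_keys)
  profile1d(q = m[, "q"], I = m[, "I"], sigma = m[, "sigma"],
            sigma_q = if ("sigma_q" %in% cols) m[, "sigma_q"] else NULL,
            label = val[match("label", key)],
            sample_id = val[match("sample_id", key)],
            provenance = prov)
}
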
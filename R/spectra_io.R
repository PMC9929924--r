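#' Construct a mass spectrum
#'
#' A `mass_spectrum` holds one acquired or simulated spectrum: an m/z axis,
#' the corresponding intensities, and the instrument settings that matter for
#' dissociation analysis (trap acceleration voltage and quadrupole low-mass
#' cutoff).
#'
#' @param mz Numeric vector of mass-to-charge values (Thomson), strictly
#'   increasing.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param accel_voltage Trap acceleration voltage in volt, or `NA` if not
#'   applicable.
#' @param quad_cutoff_mz Low-mass cutoff of the quadrupole filter (Thomson),
#'   or `NA`.
#' @param label Free-text label.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, accel_voltage = NA_real_,
                          quad_cutoff_mz = NA_real_, label = "") {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz values must be strictly increasing")
  if (any(intensity < 0))
    stop("intensities must be non-negative (first offending index: ",
         which(intensity < 0)[1], ")")
  structure(
    list(mz = mz, intensity = intensity,
         accel_voltage = as.numeric(accel_voltage)[1],
         quad_cutoff_mz = as.numeric(quad_cutoff_mz)[1],
         label = as.character(label)[1]),
    class = "mass_spectrum"
  )
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum>", length(x$mz), "points")
  if (length(x$mz)) cat(sprintf(", m/z %.6g-%.6g", min(x$mz), max(x$mz)))
  if (!is.na(x$accel_voltage)) cat(sprintf(", accel %g V", x$accel_voltage))
  if (nzchar(x$label)) cat(", '", x$label, "'", sep = "")
  cat("\n")
  invisible(x)
}

#' Construct a collision-voltage ramp experiment
#'
#' Bundles the spectra of one dissociation ramp (one replicate): a series of
#' native MS acquisitions of the same sample at increasing trap acceleration
#' voltage, together with the mass of the monitored 1:1 complex and the set
#' of charge states used for quantification.
#'
#' @param spectra List of [mass_spectrum()] objects, each with
#'   `accel_voltage` set; sorted by voltage internally.
#' @param replicate_id Integer replicate identifier.
#' @param complex_mass Mass of the monitored complex (Da).
#' @param charge_subset Integer charge states quantified (e.g. `23:26`).
#' @return An object of class `ramp_experiment`.
#' @export
ramp_experiment <- function(spectra, replicate_id = 1L, complex_mass,
                            charge_subset = 23:26) {
  if (!length(spectra)) stop("at least one spectrum is required")
  if (!all(vapply(spectra, inherits, logical(1), "mass_spectrum")))
    stop("spectra must be a list of mass_spectrum objects")
  v <- vapply(spectra, function(s) s$accel_voltage, numeric(1))
  if (anyNA(v)) stop("every spectrum in a ramp must have accel_voltage set")
  spectra <- spectra[order(v)]
  v <- sort(v)
  if (length(v) > 1 && any(diff(v) <= 0))
    stop("acceleration voltages must be distinct")
  if (!length(charge_subset)) stop("charge_subset must be non-empty")
  if (complex_mass <= 0) stop("complex_mass must be positive")
  structure(
    list(spectra = spectra, voltages = v,
         replicate_id = as.integer(replicate_id),
         complex_mass = as.numeric(complex_mass),
         charge_subset = as.integer(sort(charge_subset))),
    class = "ramp_experiment"
  )
}

#' Construct a fluorescence-anisotropy titration
#'
#' Receptor concentrations against replicate anisotropy readings for a fixed
#' concentration of fluorescently labelled peptide probe.
#'
#' @param concentrations Receptor concentrations (molar), strictly positive;
#'   sorted increasing internally.
#' @param anisotropy Numeric matrix, one row per concentration, one column
#'   per replicate; or a vector for a single replicate.
#' @param probe_conc Labelled-peptide concentration (molar).
#' @param label Identifier for the peptide/receptor pair.
#' @return An object of class `anisotropy_titration`.
#' @export
anisotropy_titration <- function(concentrations, anisotropy,
                                 probe_conc = 10e-9, label = "") {
  concentrations <- as.numeric(concentrations)
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive")
  if (is.null(dim(anisotropy)))
    anisotropy <- matrix(as.numeric(anisotropy), ncol = 1)
  anisotropy <- as.matrix(anisotropy)
  if (nrow(anisotropy) != length(concentrations))
    stop("anisotropy must have one row per concentration")
  o <- order(concentrations)
  concentrations <- concentrations[o]
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be distinct")
  anisotropy <- anisotropy[o, , drop = FALSE]
  structure(
    list(concentrations = concentrations, anisotropy = anisotropy,
         probe_conc = as.numeric(probe_conc)[1],
         label = as.character(label)[1]),
    class = "anisotropy_titration"
  )
}

#' @export
print.anisotropy_titration <- function(x, ...) {
  cat("<anisotropy_titration>", length(x$concentrations), "concentrations x",
      ncol(x$anisotropy), "replicates,",
      sprintf("%.3g-%.3g M", min(x$concentrations), max(x$concentrations)))
  if (nzchar(x$label)) cat(", '", x$label, "'", sep = "")
  cat("\n")
  invisible(x)
}

# -- TSV dialect ------------------------------------------------------------
# Tab-separated, '.' decimal separator, optional '#'-prefixed comment lines
# carrying metadata as key=value; numeric values written at 6 significant
# digits, which exceeds instrument precision and keeps read/write round trips
# exact at that precision.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

.read_tsv_with_meta <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  meta <- list()
  for (cl in sub("^#\\s*", "", lines[is_comment])) {
    eq <- regexpr("=", cl, fixed = TRUE)
    if (eq > 0) {
      meta[[trimws(substr(cl, 1, eq - 1))]] <- trimws(substr(cl, eq + 1, nchar(cl)))
    }
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  list(meta = meta, body = body)
}

#' Read a spectrum from a tab-separated file
#'
#' Expects a two-column (m/z, intensity) table with an optional header row
#' and optional `#`-prefixed `key=value` comment lines (recognised keys:
#' `accel_voltage`, `quad_cutoff_mz`, `label`). Rows are sorted by m/z.
#'
#' @param path Path to the file.
#' @param metadata Optional named list; entries override metadata found in
#'   the file.
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, metadata = list()) {
  parsed <- .read_tsv_with_meta(path)
  body <- parsed$body
  if (length(body) && grepl("^[a-zA-Z]", body[1])) body <- body[-1]
  n <- length(body)
  mz <- numeric(n); intensity <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], "[\t,]")[[1]]
    fields <- fields[nzchar(trimws(fields))]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2 || anyNA(vals))
      stop("malformed spectrum row ", i, ": '", body[i], "'")
    if (vals[2] < 0)
      stop("negative intensity in spectrum row ", i, ": '", body[i], "'")
    mz[i] <- vals[1]; intensity[i] <- vals[2]
  }
  if (anyDuplicated(mz))
    stop("duplicate m/z value in spectrum row ",
         anyDuplicated(mz), ": ", mz[anyDuplicated(mz)])
  o <- order(mz)
  meta <- parsed$meta
  meta[names(metadata)] <- metadata
  num_meta <- function(key) {
    if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  }
  mass_spectrum(mz[o], intensity[o],
                accel_voltage = num_meta("accel_voltage"),
                quad_cutoff_mz = num_meta("quad_cutoff_mz"),
                label = if (is.null(meta$label)) "" else meta$label)
}

#' Write a spectrum to a tab-separated file
#'
#' Inverse of [read_spectrum()]: metadata as `#` comments, a header row, and
#' one `mz<TAB>intensity` row per point at 6 significant digits.
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  lines <- character(0)
  if (!is.na(spectrum$accel_voltage))
    lines <- c(lines, paste0("# accel_voltage=", .fmt_num(spectrum$accel_voltage)))
  if (!is.na(spectrum$quad_cutoff_mz))
    lines <- c(lines, paste0("# quad_cutoff_mz=", .fmt_num(spectrum$quad_cutoff_mz)))
  if (nzchar(spectrum$label))
    lines <- c(lines, paste0("# label=", spectrum$label))
  lines <- c(lines, "mz\tintensity")
  if (length(spectrum$mz))
    lines <- c(lines, paste(.fmt_num(spectrum$mz), .fmt_num(spectrum$intensity),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an anisotropy titration from a tab-separated file
#'
#' Expects one concentration column followed by one or more replicate
#' anisotropy columns; optional `#` comments with `probe_conc` and `label`.
#'
#' @param path Path to the file.
#' @return An [anisotropy_titration()].
#' @export
read_titration <- function(path) {
  parsed <- .read_tsv_with_meta(path)
  body <- parsed$body
  if (length(body) && grepl("^[a-zA-Z]", body[1])) body <- body[-1]
  if (!length(body)) stop("titration file contains no data rows")
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(body[i], "[\t,]")[[1]]
    fields <- fields[nzchar(trimws(fields))]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals))
      stop("malformed titration row ", i, ": '", body[i], "'")
    vals
  })
  ncol <- unique(vapply(rows, length, integer(1)))
  if (length(ncol) != 1)
    stop("ragged replicate columns in titration file")
  m <- do.call(rbind, rows)
  conc <- m[, 1]
  if (any(conc <= 0))
    stop("non-positive concentration in titration row ", which(conc <= 0)[1])
  meta <- parsed$meta
  anisotropy_titration(
    conc, m[, -1, drop = FALSE],
    probe_conc = if (is.null(meta$probe_conc)) 10e-9 else as.numeric(meta$probe_conc),
    label = if (is.null(meta$label)) "" else meta$label
  )
}

#' Write an anisotropy titration to a tab-separated file
#'
#' @param titration An [anisotropy_titration()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_titration <- function(titration, path) {
  stopifnot(inherits(titration, "anisotropy_titration"))
  nrep <- ncol(titration$anisotropy)
  lines <- c(paste0("# probe_conc=", .fmt_num(titration$probe_conc)))
  if (nzchar(titration$label))
    lines <- c(lines, paste0("# label=", titration$label))
  lines <- c(lines, paste(c("concentration", paste0("rep", seq_len(nrep))),
                          collapse = "\t"))
  for (i in seq_along(titration$concentrations)) {
    lines <- c(lines, paste(c(.fmt_num(titration$concentrations[i]),
                              .fmt_num(titration$anisotropy[i, ])),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a fit-result record as flat JSON
#'
#' Serialises any fit object of this package (LFER fits, Boltzmann fits,
#' binding fits, K_D summaries) as a flat JSON object, dropping bulky data
#' members, so results are machine-readable across languages.
#'
#' @param fit A fit object (a named list).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$data <- NULL
  x$model <- NULL
  x$curve <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
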
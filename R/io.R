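# Plain-text serialization. Spectra and phantoms travel as small CSV
# files; tomograms as CSV matrices with the depth axis in the first
# column; configs as YAML. All values SI with unit-suffixed column names.

#' Write / read a source spectrum as CSV
#'
#' Columns `frequency_Hz`, `power_W`, `line_index` (NA for continuous
#' spectra, where rows are grid samples and `power_W` is the per-sample
#' integrated power). Comb metadata (FSR, envelope, centre) is stored in
#' `# key=value` header comments so the round trip is lossless.
#'
#' @param spectrum A `comb_spectrum`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "comb_spectrum"))
  hdr <- c(
    sprintf("# center_frequency_hz=%.17g", spectrum$center_frequency),
    sprintf("# fsr_hz=%.17g", spectrum$fsr),
    sprintf("# envelope_kind=%s", spectrum$envelope_kind),
    sprintf("# line_linewidth_hz=%.17g", spectrum$line_linewidth))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(
    data.frame(frequency_Hz = spectrum$line_frequencies,
               power_W = spectrum$line_powers,
               line_index = spectrum$line_index),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  new_comb_spectrum(
    center_frequency = as.numeric(meta[["center_frequency_hz"]]),
    mu = df$line_index, nu = df$frequency_Hz, p = df$power_W,
    linewidth = as.numeric(meta[["line_linewidth_hz"]]),
    kind = meta[["envelope_kind"]], fsr = as.numeric(meta[["fsr_hz"]]))
}

#' Write / read a reflector phantom as CSV
#'
#' Columns `z_m`, `reflectivity`, `phase_rad`.
#'
#' @param phantom A `reflector_phantom`.
#' @param path File path.
#' @return `path` (writer) or a `reflector_phantom` (reader).
#' @export
write_phantom_csv <- function(phantom, path) {
  stopifnot(inherits(phantom, "reflector_phantom"))
  utils::write.csv(
    data.frame(z_m = phantom$reflectors$z,
               reflectivity = phantom$reflectors$reflectivity,
               phase_rad = phantom$reflectors$phase),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phantom_csv
#' @export
read_phantom_csv <- function(path) {
  df <- utils::read.csv(path)
  reflector_phantom(df$z_m, df$reflectivity, phase = df$phase_rad)
}

#' Write per-line detector traces as CSV
#'
#' One column per line (named `line_<id>`), sampling rate and duration in
#' header comments.
#'
#' @param traces A `line_traces`.
#' @param path File path.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "line_traces"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_sa_s=%.17g", traces$sampling_rate),
               sprintf("# duration_s=%.17g", traces$duration),
               sprintf("# line_ids=%s",
                       paste(traces$line_ids, collapse = ","))), con)
  df <- as.data.frame(traces$traces)
  names(df) <- paste0("trace", seq_along(traces$line_ids))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  tr <- unname(as.matrix(df))
  structure(
    list(traces = tr,
         sampling_rate = as.numeric(meta[["sampling_rate_sa_s"]]),
         duration = as.numeric(meta[["duration_s"]]),
         line_ids = as.integer(strsplit(meta[["line_ids"]], ",")[[1]]),
         mean_powers = colMeans(tr)),
    class = "line_traces")
}

# Tomogram as CSV: first column depth_m, remaining columns A-scan
# amplitudes. Used by run_pipeline().
write_tomogram_csv <- function(tomo, path) {
  df <- data.frame(depth_m = tomo$depth_axis)
  df <- cbind(df, as.data.frame(tomo$amplitude))
  names(df)[-1] <- paste0("ascan_", seq_len(ncol(tomo$amplitude)))
  utils::write.csv(df, path, row.names = FALSE)
  path
}
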
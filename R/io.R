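# CSV dialect: UTF-8, comma separator, dot decimal point, optional leading
# '#'-prefixed metadata lines of the form "# key=value".

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (!nzchar(body) || !grepl("=", body, fixed = TRUE)) next
    kv <- strsplit(body, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

meta_header_lines <- function(meta) {
  if (!length(meta)) return(character(0))
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s=%s", k, if (is.numeric(v)) fmt_num(v) else as.character(v))
  }, character(1))
}

read_csv_with_meta <- function(path, required_cols) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stopf("%s: no data lines", path)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  missing <- setdiff(required_cols, trimws(header))
  if (length(missing))
    stopf("%s: missing column(s) %s (header: %s)", path,
          paste(missing, collapse = ", "), body[1L])
  line_no <- which(!is_meta)[-1L]  # file line numbers of the data rows
  df <- read.csv(text = paste(body, collapse = "\n"), header = TRUE,
                 colClasses = NA, check.names = TRUE)
  for (cl in required_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stopf("%s: non-numeric value in column '%s' at line %d", path, cl,
            line_no[bad])
    }
    if (anyNA(v))
      stopf("%s: missing value in column '%s' at line %d", path, cl,
            line_no[which(is.na(v))[1L]])
  }
  list(data = df, meta = meta, line_no = line_no)
}

#' Read an oscillating-drop trace CSV
#'
#' Expects the canonical trace dialect: optional `# key=value` metadata
#' lines (`# concentration_mM=...`, `# salt_mM=...`, `# frequency_hz=...`),
#' then a header `time_s,area_mm2,tension_mN_m` and numeric rows. The
#' nominal oscillation frequency is taken from the `frequency_hz` metadata
#' unless overridden.
#'
#' @param path file path.
#' @param nominal_frequency override for the frequency (Hz); required if
#'   the file has no `frequency_hz` metadata.
#' @return an [oscillation_trace()] whose `meta` holds the metadata lines.
#' @export
read_trace_csv <- function(path, nominal_frequency = NULL) {
  parsed <- read_csv_with_meta(path, c("time_s", "area_mm2", "tension_mN_m"))
  df <- parsed$data
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stopf("%s: time_s not strictly increasing at line %d", path,
          parsed$line_no[which(dt <= 0)[1L] + 1L])
  nu <- nominal_frequency %||% parsed$meta$frequency_hz
  if (is.null(nu))
    stopf("%s: no '# frequency_hz=' metadata; pass nominal_frequency", path)
  oscillation_trace(df$time_s, df$area_mm2, df$tension_mN_m,
                    nominal_frequency = nu, meta = parsed$meta)
}

#' Write an oscillating-drop trace CSV
#'
#' Inverse of [read_trace_csv()]; numeric values are written with 15
#' significant digits so write/read round trips are stable to at least 12
#' digits.
#'
#' @param trace an [oscillation_trace()].
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_trace_csv <- function(trace, path) {
  if (!inherits(trace, "oscillation_trace")) stopf("trace must be an oscillation_trace")
  meta <- trace$meta
  meta$frequency_hz <- trace$nominal_frequency
  rows <- paste(fmt_num(trace$t), fmt_num(trace$area),
                fmt_num(trace$tension), sep = ",")
  writeLines(c(meta_header_lines(meta), "time_s,area_mm2,tension_mN_m",
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a surface tension isotherm CSV
#'
#' Dialect: optional `# salt_mM=...` metadata, header
#' `conc_mol_per_L,tension_mN_m`, numeric rows.
#'
#' @param path file path.
#' @return an [isotherm_dataset()].
#' @export
read_isotherm_csv <- function(path) {
  parsed <- read_csv_with_meta(path, c("conc_mol_per_L", "tension_mN_m"))
  isotherm_dataset(parsed$data$conc_mol_per_L, parsed$data$tension_mN_m,
                   salt_mM = parsed$meta$salt_mM %||% 0, meta = parsed$meta)
}

#' Write a surface tension isotherm CSV
#'
#' @param data an [isotherm_dataset()] or data.frame with `conc`, `tension`.
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_isotherm_csv <- function(data, path) {
  df <- as.data.frame(data)
  meta <- attr(data, "meta") %||% list()
  meta$salt_mM <- attr(data, "salt_mM") %||% meta$salt_mM %||% 0
  rows <- paste(fmt_num(df$conc), fmt_num(df$tension), sep = ",")
  writeLines(c(meta_header_lines(meta), "conc_mol_per_L,tension_mN_m",
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' Write a modulus table CSV
#'
#' Writes the output of [analyze_traces()] in the canonical modulus table
#' dialect.
#'
#' @param table data.frame from [analyze_traces()].
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_modulus_csv <- function(table, path) {
  cols <- c("concentration_mM", "frequency_hz", "eps_real_mN_m",
            "eps_imag_mN_m", "harmonic_ratio", "quality_flag")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stopf("modulus table lacks column(s): %s", paste(missing, collapse = ", "))
  num <- cols[cols != "quality_flag"]
  num_mat <- vapply(num, function(cl) fmt_num(as.numeric(table[[cl]])),
                    character(nrow(table)))
  if (is.null(dim(num_mat))) num_mat <- matrix(num_mat, nrow = 1L)
  rows <- apply(cbind(num_mat, as.character(table$quality_flag)), 1L,
                paste, collapse = ",")
  writeLines(c(paste(cols, collapse = ","), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a modulus table CSV
#'
#' @param path file path written by [write_modulus_csv()].
#' @return data.frame.
#' @export
read_modulus_csv <- function(path) {
  parsed <- read_csv_with_meta(
    path, c("frequency_hz", "eps_real_mN_m", "eps_imag_mN_m"))
  parsed$data
}
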
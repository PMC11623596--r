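#' Read and write rate tables
#'
#' The rate CSV schema has columns `variant`, `condition`, `temp_C`,
#' `replicate`, `kcat_per_s`.
#'
#' @param path File path.
#' @return `read_rate_csv()` returns a tibble in the rate schema.
#' @export
read_rate_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    variant = readr::col_character(),
    condition = readr::col_character(),
    temp_C = readr::col_double(),
    replicate = readr::col_integer(),
    kcat_per_s = readr::col_double()
  ))
  req <- c("variant", "condition", "temp_C", "replicate", "kcat_per_s")
  if (!all(req %in% names(out))) {
    abort(sprintf("Rate CSV must contain columns: %s",
                  paste(req, collapse = ", ")),
          class = "litdark_bad_schema")
  }
  out
}

#' @rdname read_rate_csv
#' @param rates A tibble in the rate schema.
#' @export
write_rate_csv <- function(rates, path) {
  req <- c("variant", "condition", "temp_C", "replicate", "kcat_per_s")
  if (!all(req %in% names(rates))) {
    abort(sprintf("Rate table must contain columns: %s",
                  paste(req, collapse = ", ")),
          class = "litdark_bad_schema")
  }
  readr::write_csv(rates[, req], path)
  invisible(path)
}

#' Read and write melt tables
#'
#' The melt CSV schema has columns `variant`, `condition`, `temp_C`,
#' `wavelength_nm`, `cd_mdeg`, `ht_v`.
#'
#' @param path File path.
#' @return `read_melt_csv()` returns a `melt_curve` tibble.
#' @export
read_melt_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    variant = readr::col_character(),
    condition = readr::col_character(),
    temp_C = readr::col_double(),
    wavelength_nm = readr::col_double(),
    cd_mdeg = readr::col_double(),
    ht_v = readr::col_double()
  ))
  req <- c("variant", "condition", "temp_C", "wavelength_nm", "cd_mdeg",
           "ht_v")
  if (!all(req %in% names(out))) {
    abort(sprintf("Melt CSV must contain columns: %s",
                  paste(req, collapse = ", ")),
          class = "litdark_bad_schema")
  }
  class(out) <- c("melt_curve", class(out))
  out
}

#' @rdname read_melt_csv
#' @param curve A `melt_curve` tibble.
#' @export
write_melt_csv <- function(curve, path) {
  req <- c("variant", "condition", "temp_C", "wavelength_nm", "cd_mdeg",
           "ht_v")
  if (!all(req %in% names(curve))) {
    abort(sprintf("Melt table must contain columns: %s",
                  paste(req, collapse = ", ")),
          class = "litdark_bad_schema")
  }
  readr::write_csv(tibble::as_tibble(curve)[, req], path)
  invisible(path)
}

#' Read and write kinetic traces
#'
#' Trace files are CSVs with columns `time_s`, `absorbance`, preceded by a
#' `# key=value` header block carrying the instrument metadata (`temp_C`,
#' `condition`, `enzyme_conc_M`, `epsilon_mM_cm`, `pathlength_cm`,
#' `wavelength_nm`).
#'
#' @param path File path.
#' @return `read_trace_csv()` returns a `kinetic_trace` tibble with the
#'   metadata restored as attributes.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  df <- readr::read_csv(I(paste(lines[-hdr], collapse = "\n")),
                        col_types = readr::cols(
                          time_s = readr::col_double(),
                          absorbance = readr::col_double()
                        ))
  new_kinetic_trace(df,
                    temp_C = num(meta$temp_C),
                    condition = meta$condition %||% NA_character_,
                    enzyme_conc_M = num(meta$enzyme_conc_M),
                    epsilon_mM_cm = num(meta$epsilon_mM_cm),
                    pathlength_cm = num(meta$pathlength_cm),
                    wavelength_nm = num(meta$wavelength_nm))
}

#' @rdname read_trace_csv
#' @param trace A `kinetic_trace` tibble.
#' @export
write_trace_csv <- function(trace, path) {
  meta <- trace_meta(trace)
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s=%s", k, format(meta[[k]], scientific = TRUE))
  }, character(1))
  body <- readr::format_csv(tibble::as_tibble(trace)[, c("time_s",
                                                         "absorbance")])
  writeLines(c(hdr, sub("\n$", "", body)), path)
  invisible(path)
}
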
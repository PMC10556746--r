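# CSV readers/writers for the two interchange formats:
#   spectra:   header "id,<wn1>,<wn2>,...", one row per sample
#   reference: columns id,value[,analyte,units]
# Comma separator, "." decimal, UTF-8, mandatory header.

#' Read a spectra CSV file
#'
#' Expects a header row `id,<wn1>,<wn2>,...` with wavenumbers in cm^-1 and
#' one numeric row per sample. Columns are sorted by ascending wavenumber
#' if the file stores them out of order (a message notes the reordering).
#'
#' @param path path to a CSV file.
#' @return A [spectra_set()].
#' @seealso [write_spectra_csv()]
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop_nircal("spectra CSV needs an id column and at least one wavelength")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop_nircal("duplicate sample id '", ids[duplicated(ids)][1L],
                "' in ", path)
  }
  wn <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (any(is.na(wn))) {
    stop_nircal("non-numeric wavenumber header '",
                names(df)[-1L][which(is.na(wn))[1L]], "' in ", path)
  }
  if (anyDuplicated(wn)) {
    stop_nircal("duplicated wavenumber ", wn[duplicated(wn)][1L], " in ", path)
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (any(is.na(num) & !is.na(body))) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1L, ]
    stop_nircal("non-numeric value '", body[bad[1L], bad[2L]], "' at row ",
                bad[1L], " (id '", ids[bad[1L]], "'), wavelength column ",
                bad[2L], " in ", path)
  }
  if (is.unsorted(wn, strictly = TRUE)) {
    ord <- order(wn)
    wn <- wn[ord]
    num <- num[, ord, drop = FALSE]
    message("read_spectra_csv: columns reordered to ascending wavenumber")
  }
  spectra_set(wn, num, ids)
}

#' Write a spectra CSV file
#'
#' Deterministic, bit-stable output: numbers are formatted with `%.17g`
#' (shortest exact round-trip for doubles), so writing the same object
#' twice yields byte-identical files and a write/read round trip restores
#' the values exactly.
#'
#' @param s a [spectra_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  fmt <- function(x) sub("^(-?)0[.]", "\\1.", sprintf("%.17g", x))
  header <- paste(c("id", sprintf("%.17g", s$wavenumbers)), collapse = ",")
  rows <- vapply(seq_len(nrow(s$absorbance)), function(i) {
    paste(c(s$sample_ids[i], sprintf("%.17g", s$absorbance[i, ])),
          collapse = ",")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a reference-concentration CSV file
#'
#' Columns `id,value` with optional `analyte` and `units` columns (the
#' first non-empty entry of each is used for the whole table).
#'
#' @param path path to a CSV file.
#' @return A [concentration_table()].
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("id", "value") %in% names(df))) {
    stop_nircal("reference CSV must have 'id' and 'value' columns")
  }
  values <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(values))) {
    stop_nircal("non-numeric value for sample '",
                df$id[which(is.na(values))[1L]], "' in ", path)
  }
  analyte <- if ("analyte" %in% names(df)) as.character(df$analyte[1L]) else "unknown"
  units <- if ("units" %in% names(df)) as.character(df$units[1L]) else "mg/kg"
  concentration_table(as.character(df$id), values, analyte = analyte,
                      units = units)
}

#' Write a reference-concentration CSV file
#'
#' @param y a [concentration_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(y, path) {
  stopifnot(inherits(y, "concentration_table"))
  lines <- c("id,value,analyte,units",
             sprintf("%s,%.17g,%s,%s", y$sample_ids, unname(y$values),
                     y$analyte, y$units))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
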
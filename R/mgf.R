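# Minimal Mascot Generic Format (MGF) reader/writer: TITLE, PEPMASS,
# CHARGE and peak pairs are the only fields the search consumes.

#' Read an MGF peak-list file
#'
#' @param path MGF file.
#' @return A list of spectra; each is a list with `id` (TITLE),
#'   `precursor_mz`, `charge` (NA when absent) and a two-column `peaks`
#'   matrix (`mz`, `intensity`) sorted by m/z.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unmatched BEGIN/END IONS")
  mapply(function(b, e) {
    block <- lines[(b + 1L):(e - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    pk <- block[!kv & nzchar(block)]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(pk, "[ \t]+"), function(x)
        as.numeric(x[1:2])))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, "mz"]), , drop = FALSE]
    } else {
      matrix(numeric(), 0, 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    charge <- if ("CHARGE" %in% keys)
      as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1L])) else NA_integer_
    list(
      id = if ("TITLE" %in% keys) vals[keys == "TITLE"][1L] else NA_character_,
      precursor_mz = as.numeric(
        strsplit(vals[keys == "PEPMASS"][1L], "[ \t]+")[[1L]][1L]),
      charge = charge,
      peaks = peaks
    )
  }, begins, ends, SIMPLIFY = FALSE)
}

#' Write spectra to an MGF file
#'
#' @param spectra List of spectra as returned by [read_mgf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  out <- unlist(lapply(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", s$id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (!is.na(s$charge)) sprintf("CHARGE=%d+", s$charge),
      sprintf("%.6f %.2f", s$peaks[, "mz"], s$peaks[, "intensity"]),
      "END IONS", "")
  }))
  writeLines(out, path)
  invisible(path)
}
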
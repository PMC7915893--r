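# In-silico tryptic digestion and peptide/fragment mass arithmetic.

#' Tryptic digestion of a protein sequence
#'
#' Cleaves after K or R except when the next residue is P, generating all
#' peptides with 0 to `max_missed` internal (missed) cleavage sites.
#' Coordinates are 1-based inclusive positions in the protein.
#'
#' @param sequence Protein sequence (uppercase one-letter amino acids).
#' @param max_missed Maximum missed cleavages (default 2).
#' @return Data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest("AKRPCK")$sequence # RP bond is not cleaved
#' @export
digest <- function(sequence, max_missed = 2L) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(sequence, "")[[1L]]
  bad <- which(!aa %in% names(AA_RESIDUE_MASS))
  if (length(bad))
    stop("invalid residue '", aa[bad[1L]], "' at position ", bad[1L])
  n <- length(aa)
  # cut points: after position i when aa[i] in {K,R} and aa[i+1] != P
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts == n | aa[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, if (!n %in% cuts) n)  # segment end positions
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nseg <- length(starts)
  out <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed)) {
      out[[length(out) + 1L]] <- c(starts[i], ends[j], j - i)
    }
  }
  m <- do.call(rbind, out)
  data.frame(
    sequence = substring(sequence, m[, 1L], m[, 2L]),
    start = m[, 1L], end = m[, 2L], missed_cleavages = m[, 3L],
    stringsAsFactors = FALSE
  )
}

# placements: data frame with columns `position` (1-based in peptide) and
# `mod` (name in MOD_DELTAS). Empty data frame = unmodified.
empty_placements <- function() {
  data.frame(position = integer(), mod = character(),
             stringsAsFactors = FALSE)
}

validate_placements <- function(sequence, placements) {
  if (nrow(placements) == 0L) return(invisible(placements))
  aa <- strsplit(sequence, "")[[1L]]
  targets <- list(carbamidomethyl = "C", oxidation = "M", stn = c("S", "T"))
  for (k in seq_len(nrow(placements))) {
    mod <- placements$mod[k]
    pos <- placements$position[k]
    if (!mod %in% names(MOD_DELTAS)) stop("unknown modification: ", mod)
    if (pos < 1L || pos > length(aa))
      stop("modification position ", pos, " outside peptide")
    if (!aa[pos] %in% targets[[mod]])
      stop(mod, " cannot be placed on residue ", aa[pos], " at position ", pos)
  }
  invisible(placements)
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus water plus all modification deltas.
#'
#' @param sequence Peptide sequence.
#' @param placements Data frame of modification placements with columns
#'   `position` (1-based in the peptide) and `mod`
#'   (`"carbamidomethyl"`, `"oxidation"` or `"stn"`).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, placements = empty_placements()) {
  aa <- strsplit(sequence, "")[[1L]]
  bad <- which(!aa %in% names(AA_RESIDUE_MASS))
  if (length(bad))
    stop("invalid residue '", aa[bad[1L]], "' at position ", bad[1L])
  validate_placements(sequence, placements)
  sum(AA_RESIDUE_MASS[aa]) + MASS_CONSTANTS[["water"]] +
    sum(MOD_DELTAS[placements$mod])
}

# Singly-charged b/y fragment m/z for a modified peptide. STn-carrying
# fragments are returned both with the intact glycan and with full glycan
# loss (HCD commonly strips O-glycans from the backbone).
fragment_ions <- function(sequence, placements = empty_placements()) {
  aa <- strsplit(sequence, "")[[1L]]
  n <- length(aa)
  if (n < 2L) return(numeric())
  deltas <- numeric(n)
  stn_flag <- logical(n)
  if (nrow(placements)) {
    for (k in seq_len(nrow(placements))) {
      deltas[placements$position[k]] <-
        deltas[placements$position[k]] + MOD_DELTAS[[placements$mod[k]]]
      if (placements$mod[k] == "stn") stn_flag[placements$position[k]] <- TRUE
    }
  }
  res <- AA_RESIDUE_MASS[aa] + deltas
  res_naked <- res - stn_flag * MOD_DELTAS[["stn"]]
  proton <- MASS_CONSTANTS[["proton"]]
  water <- MASS_CONSTANTS[["water"]]
  b <- cumsum(res)[-n] + proton
  y <- rev(cumsum(rev(res))[-n]) + water + proton
  ions <- c(b, y)
  if (any(stn_flag)) {
    b0 <- cumsum(res_naked)[-n] + proton
    y0 <- rev(cumsum(rev(res_naked))[-n]) + water + proton
    ions <- c(ions, b0, y0)
  }
  sort(unique(ions))
}
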
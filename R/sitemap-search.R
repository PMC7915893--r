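# Oxonium-gated glycopeptide search with b/y-ion glycosite localization.
#
# Spectra are prefiltered on the diagnostic low-mass oxonium ions of STn
# (HexNAc 204.0867 and NeuAc 292.1027 / water loss 274.0921): an STn
# interpretation is only ever reported for a spectrum carrying both a
# GalNAc-type and a NeuAc-type oxonium ion. Candidates within the precursor
# tolerance are scored by the number of matched singly-charged b/y ions,
# counting STn-carrying fragments as matched with either the intact glycan
# or full glycan loss.

#' Test a spectrum for STn-diagnostic oxonium ions
#'
#' Returns `TRUE` iff some peak matches the HexNAc oxonium ion (204.0866)
#' AND some peak matches a NeuAc oxonium ion (292.1027 or its water loss
#' 274.0921), each within `fragment_tol` Da.
#'
#' @param spectrum A spectrum as returned by [read_mgf()].
#' @param fragment_tol Fragment match tolerance in Da (default 0.01).
#' @return Logical scalar; an empty spectrum returns `FALSE`.
#' @export
oxonium_filter <- function(spectrum, fragment_tol = 0.01) {
  mz <- spectrum$peaks[, "mz"]
  if (length(mz) == 0L) {
    message("oxonium_filter: empty spectrum ", spectrum$id)
    return(FALSE)
  }
  has <- function(target) any(abs(mz - target) <= fragment_tol)
  has(OXONIUM_MZ[["HexNAc"]]) &&
    (has(OXONIUM_MZ[["NeuAc"]]) || has(OXONIUM_MZ[["NeuAc_h2o"]]))
}

# utils::combn(x, m) treats a scalar x as seq_len(x); guard against it
combn_sets <- function(x, m) {
  if (m == 0L) return(list(integer()))
  if (length(x) < m) return(list())
  if (length(x) == 1L) return(list(x))
  utils::combn(x, m, simplify = FALSE)
}

count_matched <- function(theoretical, observed, tol) {
  if (length(theoretical) == 0L || length(observed) == 0L) return(0L)
  idx <- findInterval(theoretical, observed)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(observed))
  sum(pmin(abs(theoretical - observed[lo]),
           abs(theoretical - observed[hi])) <= tol)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of protein sequences.
#' @return Named character vector (accession = first word of the header).
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  out
}

# Enumerate modification placements for one peptide: fixed carbamidomethyl
# on every C, 0..max_ox oxidations on M, n_stn STn on S/T (all site
# combinations). Returns a list of placement data frames.
enumerate_placements <- function(sequence, n_stn, max_ox = 2L,
                                 max_stn = 3L) {
  aa <- strsplit(sequence, "")[[1L]]
  fixed <- if (any(aa == "C"))
    data.frame(position = which(aa == "C"), mod = "carbamidomethyl",
               stringsAsFactors = FALSE) else empty_placements()
  st <- which(aa %in% c("S", "T"))
  if (n_stn > max_stn || n_stn > length(st)) return(list())
  stn_sets <- combn_sets(st, n_stn)
  mpos <- which(aa == "M")
  ox_sets <- list(integer())
  for (k in seq_len(min(max_ox, length(mpos))))
    ox_sets <- c(ox_sets, combn_sets(mpos, k))
  out <- list()
  for (ss in stn_sets) for (os in ox_sets) {
    pl <- rbind(
      fixed,
      if (length(ss)) data.frame(position = ss, mod = "stn",
                                 stringsAsFactors = FALSE),
      if (length(os)) data.frame(position = os, mod = "oxidation",
                                 stringsAsFactors = FALSE)
    )
    out[[length(out) + 1L]] <- pl
  }
  out
}

format_placements <- function(placements) {
  if (nrow(placements) == 0L) return("")
  pl <- placements[order(placements$position), , drop = FALSE]
  paste(sprintf("%s@%d", pl$mod, pl$position), collapse = ";")
}

#' Search MS/MS spectra for STn glycopeptides
#'
#' For each spectrum, tryptic peptide candidates from the FASTA (with fixed
#' carbamidomethyl-C, up to 2 oxidation-M and up to `max_stn` STn on S/T)
#' are matched against the precursor within `precursor_tol_ppm`; candidates
#' are scored by matched singly-charged b/y ions within `fragment_tol` and
#' the best interpretation is reported with glycosite localization. STn
#' interpretations require a passing [oxonium_filter()]. Spectra without a
#' charge are tried at 2+ and 3+.
#'
#' @param spectra List of spectra from [read_mgf()].
#' @param proteins Named character vector of protein sequences (see
#'   [read_protein_fasta()]), or a FASTA path.
#' @param precursor_tol_ppm Precursor tolerance, ppm (default 10).
#' @param fragment_tol Fragment tolerance, Da (default 0.01).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param max_stn Maximum STn per peptide (default 3).
#' @return Data frame with one row per matched spectrum: `spectrum_id`,
#'   `accession`, `peptide`, `start`, `end`, `mods`, `charge`, `ppm_error`,
#'   `n_matched_ions`, `glycosites` (protein positions, `;`-separated),
#'   `localized`.
#' @export
search_glycopeptides <- function(spectra, proteins, precursor_tol_ppm = 10,
                                 fragment_tol = 0.01, max_missed = 2L,
                                 max_stn = 3L) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- read_protein_fasta(proteins)
  if (length(proteins) == 0L) stop("no protein sequences supplied")
  peptides <- do.call(rbind, lapply(names(proteins), function(acc) {
    d <- digest(proteins[[acc]], max_missed)
    d$accession <- acc
    d
  }))
  peptides <- peptides[nchar(peptides$sequence) >= 5L, , drop = FALSE]
  # base mass = residues + water + fixed carbamidomethyl on C
  ncys <- vapply(strsplit(peptides$sequence, ""), function(a)
    sum(a == "C"), 0L)
  base_mass <- vapply(peptides$sequence, function(s)
    sum(AA_RESIDUE_MASS[strsplit(s, "")[[1L]]]), 0) +
    MASS_CONSTANTS[["water"]] + ncys * MOD_DELTAS[["carbamidomethyl"]]
  proton <- MASS_CONSTANTS[["proton"]]

  rows <- lapply(spectra, function(sp) {
    if (!is.na(sp$charge) && sp$charge < 1L) {
      warning("spectrum ", sp$id, " has charge < 1; skipped")
      return(NULL)
    }
    charges <- if (is.na(sp$charge)) c(2L, 3L) else sp$charge
    stn_ok <- oxonium_filter(sp, fragment_tol)
    obs <- sp$peaks[, "mz"]
    best <- NULL
    for (z in charges) {
      target <- z * (sp$precursor_mz - proton)
      tol_da <- precursor_tol_ppm * 1e-6 * target
      # neutral mass combinations: base + n_stn*STn + n_ox*Ox
      for (n_stn in 0:max_stn) {
        if (n_stn > 0L && !stn_ok) next
        for (n_ox in 0:2) {
          need <- target - n_stn * MOD_DELTAS[["stn"]] -
            n_ox * MOD_DELTAS[["oxidation"]]
          hit <- which(abs(base_mass - need) <= tol_da)
          for (h in hit) {
            pep <- peptides[h, ]
            pls <- enumerate_placements(pep$sequence, n_stn,
                                        max_ox = 2L, max_stn = max_stn)
            pls <- Filter(function(p) sum(p$mod == "oxidation") == n_ox, pls)
            for (pl in pls) {
              theo <- fragment_ions(pep$sequence, pl)
              sc <- count_matched(theo, obs, fragment_tol)
              mass <- peptide_mass(pep$sequence, pl)
              ppm <- (mass - target) / target * 1e6
              cand <- list(pep = pep, pl = pl, score = sc, ppm = ppm,
                           z = z, nmod = nrow(pl))
              if (is.null(best) || sc > best$score ||
                  (sc == best$score && (cand$nmod < best$nmod ||
                    (cand$nmod == best$nmod &&
                     pep$sequence < best$pep$sequence))))
                best <- cand
            }
          }
        }
      }
    }
    if (is.null(best) || best$score == 0L) return(NULL)
    stn_pos <- best$pl$position[best$pl$mod == "stn"]
    loc <- if (length(stn_pos) > 0L)
      localize(best$pep$sequence, sp, n_stn = length(stn_pos),
               fixed_other = best$pl[best$pl$mod != "stn", , drop = FALSE],
               fragment_tol = fragment_tol)
    else list(sites = integer(), localized = NA)
    glyco_prot <- if (length(stn_pos))
      best$pep$start + loc$sites - 1L else integer()
    data.frame(
      spectrum_id = sp$id, accession = best$pep$accession,
      peptide = best$pep$sequence, start = best$pep$start,
      end = best$pep$end, mods = format_placements(best$pl),
      charge = best$z, ppm_error = best$ppm,
      n_matched_ions = best$score,
      glycosites = paste(glyco_prot, collapse = ";"),
      localized = loc$localized, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(spectrum_id = character(), accession = character(),
                      peptide = character(), start = integer(),
                      end = integer(), mods = character(),
                      charge = integer(), ppm_error = numeric(),
                      n_matched_ions = integer(), glycosites = character(),
                      localized = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Localize STn sites on a matched peptide
#'
#' Scores every placement of `n_stn` STn over the peptide's S/T positions by
#' its count of matched site-determining b/y ions (ions whose m/z differs
#' between placements). A unique argmax gives `localized = TRUE`; ties
#' return the union of the tied placements' sites with `localized = FALSE`.
#'
#' @param sequence Peptide sequence.
#' @param spectrum Spectrum (as from [read_mgf()]).
#' @param n_stn Number of STn modifications to place (default 1).
#' @param fixed_other Placement data frame of non-STn modifications already
#'   assigned (fixed + oxidation).
#' @param fragment_tol Fragment tolerance, Da.
#' @return List with `sites` (1-based peptide positions) and `localized`.
#' @export
localize <- function(sequence, spectrum, n_stn = 1L,
                     fixed_other = empty_placements(),
                     fragment_tol = 0.01) {
  aa <- strsplit(sequence, "")[[1L]]
  st <- which(aa %in% c("S", "T"))
  if (length(st) < n_stn) stop("fewer S/T positions than STn to place")
  combos <- combn_sets(st, n_stn)
  if (length(combos) == 1L)
    return(list(sites = combos[[1L]], localized = TRUE))
  ion_sets <- lapply(combos, function(ss) {
    pl <- rbind(fixed_other,
                data.frame(position = ss, mod = "stn",
                           stringsAsFactors = FALSE))
    fragment_ions(sequence, pl)
  })
  # site-determining ions: not shared by every placement
  all_ions <- sort(unique(unlist(ion_sets)))
  shared <- all_ions
  for (s in ion_sets) shared <- shared[shared %in% s]
  obs <- spectrum$peaks[, "mz"]
  scores <- vapply(ion_sets, function(s)
    count_matched(setdiff(s, shared), obs, fragment_tol), 0L)
  top <- which(scores == max(scores))
  if (length(top) == 1L && max(scores) > 0L)
    list(sites = combos[[top]], localized = TRUE)
  else
    list(sites = sort(unique(unlist(combos[top]))), localized = FALSE)
}

#' Summarize glycosites per protein
#'
#' Collapses a match table to one row per protein listing its distinct
#' localized glycosites.
#'
#' @param matches Data frame from [search_glycopeptides()].
#' @return Data frame `accession`, `n_glycosites`, `glycosites`.
#' @export
glycosite_summary <- function(matches) {
  m <- matches[matches$glycosites != "", , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(accession = character(), n_glycosites = integer(),
                      glycosites = character(), stringsAsFactors = FALSE))
  by_acc <- split(m$glycosites, m$accession)
  out <- do.call(rbind, lapply(names(by_acc), function(acc) {
    sites <- sort(unique(as.integer(unlist(strsplit(by_acc[[acc]], ";")))))
    data.frame(accession = acc, n_glycosites = length(sites),
               glycosites = paste(sites, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
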
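# Tryptic digestion, peptide mass, oxonium gating, glycopeptide search and
# glycosite localization.

test_that("digestion follows the no-cut-before-proline rule", {
  d <- digest("AKRPCK")
  expect_setequal(d$sequence, c("AK", "AKRPCK", "RPCK"))
  expect_equal(d$start[d$sequence == "RPCK"], 3L)
  expect_equal(d$end[d$sequence == "RPCK"], 6L)
  expect_equal(digest("ACDEFG")$sequence, "ACDEFG")  # no K/R
  d3 <- digest("KKK", max_missed = 2)
  expect_equal(sort(d3$sequence), c("K", "K", "K", "KK", "KK", "KKK"))
  expect_error(digest("AKZ"), "invalid residue 'Z' at position 3")
  expect_error(digest(""), "empty")
})

test_that("digestion equals the brute-force cut-point oracle", {
  proteins <- read_protein_fasta(toy_fasta())
  for (s in c(substr(proteins[[1]], 1, 80), "MKTRSPKKRAY", "RRRPR")) {
    for (mm in 0:2) {
      expect_equal(sort(digest(s, mm)$sequence), oracle_digest(s, mm))
    }
  }
  # prefix closure: every k-missed peptide concatenates adjacent 0-missed ones
  d <- digest(proteins[[2]], 2)
  zero <- d[d$missed_cleavages == 0, ]
  for (i in which(d$missed_cleavages > 0)) {
    parts <- zero[zero$start >= d$start[i] & zero$end <= d$end[i], ]
    parts <- parts[order(parts$start), ]
    expect_equal(paste(parts$sequence, collapse = ""), d$sequence[i])
  }
})

test_that("peptide masses match frozen elemental-oracle values", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(peptide_mass("PEPTIDE"), 799.35996, tolerance = 1e-5)
  stn <- data.frame(position = 3, mod = "stn", stringsAsFactors = FALSE)
  expect_equal(peptide_mass("AKSIR", stn) - peptide_mass("AKSIR"),
               494.1748, tolerance = 1e-4)
  expect_error(peptide_mass("AKAIR", stn), "cannot be placed")
  expect_error(
    peptide_mass("AK", data.frame(position = 1, mod = "phospho")),
    "unknown modification")
})

test_that("oxonium gate requires both GalNAc- and NeuAc-type ions", {
  mk <- function(mz) list(id = "s", precursor_mz = 500, charge = 2,
                          peaks = cbind(mz = sort(mz),
                                        intensity = rep(1, length(mz))))
  expect_true(oxonium_filter(mk(c(204.087, 292.103))))
  expect_true(oxonium_filter(mk(c(204.087, 274.092))))
  expect_false(oxonium_filter(mk(c(204.087))))          # AND semantics
  expect_false(oxonium_filter(mk(c(292.103))))
  expect_false(oxonium_filter(mk(c(204.137, 292.153)))) # +0.05 Da off
  expect_false(suppressMessages(oxonium_filter(mk(numeric()))))
})

test_that("noiseless synthetic spectra are fully recovered with sites", {
  fx <- make_glyco_spectra(n_spectra = 25L, seed = 77L)
  matches <- search_glycopeptides(fx$spectra, read_protein_fasta(toy_fasta()))
  expect_equal(nrow(matches), 25L)
  m <- matches[match(fx$truth$spectrum_id, matches$spectrum_id), ]
  expect_equal(m$peptide, fx$truth$peptide)
  expect_equal(m$glycosites, as.character(fx$truth$site_protein))
  expect_true(all(m$localized))
  # contract assertions on every reported match
  expect_true(all(abs(m$ppm_error) <= 10))
  expect_true(all(m$n_matched_ions > 0))
})

test_that("search is gated by oxonium ions and precursor tolerance", {
  fx <- make_glyco_spectra(n_spectra = 8L, include_oxonium = FALSE,
                           seed = 12L)
  matches <- search_glycopeptides(fx$spectra,
                                  read_protein_fasta(toy_fasta()))
  expect_false(any(grepl("stn", matches$mods)))  # zero false STn reports
  # precursor shifted by 50 ppm: no match at 10 ppm
  fx2 <- make_glyco_spectra(n_spectra = 5L, seed = 13L)
  shifted <- lapply(fx2$spectra, function(s) {
    s$precursor_mz <- s$precursor_mz * (1 + 50e-6); s
  })
  expect_equal(nrow(search_glycopeptides(
    shifted, read_protein_fasta(toy_fasta()))), 0L)
})

test_that("search degrades gracefully under peak dropout", {
  fx <- make_glyco_spectra(n_spectra = 12L, dropout = 0.3,
                           n_decoy_peaks = 15L, seed = 19L)
  matches <- search_glycopeptides(fx$spectra,
                                  read_protein_fasta(toy_fasta()))
  # may miss spectra, but never reports a site outside the peptide's S/T set
  for (i in seq_len(nrow(matches))) {
    sites <- as.integer(strsplit(matches$glycosites[i], ";")[[1]])
    if (length(sites) == 0) next
    aa <- strsplit(matches$peptide[i], "")[[1]]
    pep_pos <- sites - matches$start[i] + 1L
    expect_true(all(aa[pep_pos] %in% c("S", "T")))
  }
})

test_that("localization needs site-determining ions", {
  # forced placement: single S/T
  sp <- list(id = "x", precursor_mz = 0, charge = 2,
             peaks = cbind(mz = 1, intensity = 1))
  loc <- localize("AKSIR", sp, n_stn = 1)
  expect_true(loc$localized)
  expect_equal(loc$sites, 3L)
  # two candidate sites (S2, T5), planted ions for T5 only
  pep <- "ASKATR"
  pl2 <- data.frame(position = 5, mod = "stn", stringsAsFactors = FALSE)
  ions2 <- fragment_ions(pep, pl2)
  sp2 <- list(id = "y", precursor_mz = 0, charge = 2,
              peaks = cbind(mz = ions2, intensity = rep(1, length(ions2))))
  loc2 <- localize(pep, sp2, n_stn = 1)
  expect_true(loc2$localized)
  expect_equal(loc2$sites, 5L)
  # no site-determining ions at all: ambiguous, both sites returned
  sp3 <- list(id = "z", precursor_mz = 0, charge = 2,
              peaks = cbind(mz = 5000, intensity = 1))
  loc3 <- localize(pep, sp3, n_stn = 1)
  expect_false(loc3$localized)
  expect_equal(loc3$sites, c(2L, 5L))
})

test_that("MGF writing and reading round-trip", {
  fx <- make_glyco_spectra(n_spectra = 3L, seed = 4L)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(fx$spectra, path)
  back <- read_mgf(path)
  expect_equal(length(back), 3L)
  expect_equal(back[[1]]$id, fx$spectra[[1]]$id)
  expect_equal(back[[1]]$charge, fx$spectra[[1]]$charge)
  expect_equal(back[[1]]$precursor_mz, fx$spectra[[1]]$precursor_mz,
               tolerance = 1e-6)
  expect_equal(back[[2]]$peaks[, "mz"], fx$spectra[[2]]$peaks[, "mz"],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("glycosite summary collapses matches per protein", {
  m <- data.frame(
    spectrum_id = c("a", "b", "c"), accession = c("P1", "P1", "P2"),
    glycosites = c("10;12", "12", "5"), stringsAsFactors = FALSE)
  s <- glycosite_summary(m)
  expect_equal(s$n_glycosites, c(2L, 1L))
  expect_equal(s$glycosites, c("10;12", "5"))
})
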
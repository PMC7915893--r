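# Seeded generators for every input the pipeline consumes: identification
# tables with a membrane registry, tissue-expression annotation tables, STn
# glycopeptide MGF spectra with ground truth, and survival cohorts. Each
# generator is a pure function of its arguments (seed included): the same
# call writes byte-identical files.

with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a protein identification fixture
#'
#' Emulates two fractionation-method exports (RPS and SCX): PEP scores are
#' drawn from Beta(1, 20) (a right-skewed distribution concentrating mass at
#' confident, near-zero PEP); a planted subset of accessions receives, by
#' construction, the `planted_overlap` smallest PEPs within each method, so
#' it survives any top-N cut with N >= `planted_overlap`; a configurable
#' fraction of accessions is marked plasma-membrane in the registry (always
#' including the planted set).
#'
#' @param n_proteins Proteins per method (>= 2).
#' @param membrane_fraction Fraction of accessions in the membrane registry.
#' @param planted_overlap Number of accessions planted into both methods
#'   at the most confident PEP ranks.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed); when `NULL` (default)
#'   nothing is written.
#' @return List with `ids` (data frame), `registry` (character vector),
#'   `planted` (accessions), and file `paths` when `dir` is given.
#' @export
make_identifications <- function(n_proteins = 1000L, membrane_fraction = 0.4,
                                 planted_overlap = 100L, seed = 1L,
                                 dir = NULL) {
  if (n_proteins < 2L) stop("n_proteins must be >= 2")
  if (membrane_fraction < 0 || membrane_fraction > 1)
    stop("membrane_fraction must lie in [0, 1]")
  if (planted_overlap > n_proteins)
    stop("planted overlap cannot exceed n_proteins")
  with_fixture_seed(seed, {
    acc_pool <- sprintf("P%05d", seq_len(2L * n_proteins))
    planted <- acc_pool[seq_len(planted_overlap)]
    rest <- setdiff(acc_pool, planted)
    one_method <- function(method, own) {
      acc <- c(planted, own)
      pep <- sort(stats::rbeta(length(acc), 1, 20))
      # planted accessions take the smallest PEPs (in random order among
      # themselves); the rest are shuffled over the remaining values
      pep <- c(sample(pep[seq_along(planted)]),
               sample(pep[-seq_along(planted)]))
      data.frame(accession = acc,
                 gene = paste0("G", sub("^P0*", "", acc)),
                 pep = round(pep, 6),
                 method = method,
                 n_psms = stats::rpois(length(acc), 5) + 1L,
                 stringsAsFactors = FALSE)
    }
    n_own <- n_proteins - planted_overlap
    own_a <- sample(rest, n_own)
    own_b <- sample(setdiff(rest, own_a), n_own)
    ids <- rbind(one_method("RPS", own_a), one_method("SCX", own_b))
    n_mem <- round(membrane_fraction * length(acc_pool))
    registry <- sort(c(planted,
                       sample(setdiff(acc_pool, planted),
                              max(0L, n_mem - length(planted)))))
    if (membrane_fraction == 0) registry <- character()
    out <- list(ids = ids, registry = registry, planted = planted)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(ids = file.path(dir, "identifications.tsv"),
                 registry = file.path(dir, "membrane_registry.txt"))
      write_tsv(ids, paths[["ids"]])
      writeLines(registry, paths[["registry"]])
      out$paths <- paths
    }
    out
  })
}

#' Generate a tissue-expression annotation fixture
#'
#' Emulates a tissue-atlas-style annotation table: random expression levels
#' over `n_tissues` healthy tissues (drawn from the bundled tissue-system
#' map, always covering the reproductive, immune and nervous systems), with
#' random membrane/tumor/prognosis flags. When `planted_target` is set, one
#' protein (`TARGET01`) gets the profile of an ideal marker — plasma
#' membrane, tumor-high, unfavorable prognosis, expression in only one
#' non-penalized healthy tissue at low level — while decoys are broadly
#' expressed.
#'
#' @param n_proteins Number of proteins.
#' @param n_tissues Number of healthy tissue columns (>= 3).
#' @param planted_target Plant the ideal marker profile (default `TRUE`).
#' @param seed Integer seed.
#' @param dir Output directory, as in [make_identifications()].
#' @return List with `annotations` (data frame), `planted` (accession or
#'   `NA`), and `paths` when written.
#' @export
make_annotations <- function(n_proteins = 100L, n_tissues = 12L,
                             planted_target = TRUE, seed = 1L, dir = NULL) {
  if (n_tissues < 3L) stop("n_tissues must be >= 3")
  map <- tissue_system_map()
  with_fixture_seed(seed, {
    # one tissue per penalized system, rest sampled
    must <- vapply(PENALIZED_SYSTEMS, function(s)
      map$tissue[map$system == s][1L], "")
    pool <- setdiff(map$tissue, must)
    tissues <- c(must, sample(pool, min(n_tissues - 3L, length(pool))))
    acc <- sprintf("DEC%05d", seq_len(n_proteins))
    levels_chr <- names(EXPRESSION_LEVELS)
    ann <- data.frame(
      accession = acc,
      plasma_membrane = sample(c(TRUE, FALSE), n_proteins, TRUE),
      tumor_level = sample(levels_chr, n_proteins, TRUE),
      prognosis_unfavorable = sample(c(TRUE, FALSE), n_proteins, TRUE),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (t in tissues)
      ann[[t]] <- sample(levels_chr, n_proteins, TRUE,
                         prob = c(0.2, 0.3, 0.3, 0.2))
    planted <- NA_character_
    if (planted_target) {
      planted <- "TARGET01"
      ann$accession[1L] <- planted
      ann$plasma_membrane[1L] <- TRUE
      ann$tumor_level[1L] <- "high"
      ann$prognosis_unfavorable[1L] <- TRUE
      other <- tissues[!tissues %in% must]
      for (t in tissues) ann[[t]][1L] <- "nd"
      ann[[other[1L]]][1L] <- "low"
    }
    out <- list(annotations = ann, planted = planted)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(annotations = file.path(dir, "annotations.tsv"))
      write_tsv(ann, paths[["annotations"]])
      out$paths <- paths
    }
    out
  })
}

#' Bundled toy protein FASTA
#'
#' Three invented membrane-protein-like sequences (synthetic, S/T rich);
#' shipped so the glycopeptide search is testable without any download.
#'
#' @return Path to the FASTA file.
#' @export
toy_fasta <- function() {
  system.file("extdata", "toy_proteins_synthetic.fasta",
              package = "glycotarget", mustWork = TRUE)
}

#' Generate STn glycopeptide MS/MS spectra with ground truth
#'
#' Samples tryptic peptides (>= 5 aa, with at least one S/T) from the given
#' proteins, places one STn on a random S/T site, and emits for each the
#' complete singly-charged b/y ion series (both glycan-intact and
#' glycan-stripped forms for STn fragments), the three STn-diagnostic
#' oxonium ions, and the exact precursor m/z at charge 2. Peak dropout and
#' uniform decoy peaks are applied per configuration. A ground-truth table
#' describing every spectrum is returned (and written) alongside.
#'
#' @param n_spectra Number of spectra.
#' @param proteins Named character vector of sequences or FASTA path
#'   (default the bundled [toy_fasta()]).
#' @param dropout Fraction of fragment peaks randomly removed (in `[0, 1)`;
#'   oxonium ions are never dropped).
#' @param n_decoy_peaks Uniform random decoy peaks added per spectrum.
#' @param include_oxonium Emit the oxonium ions (default `TRUE`; set
#'   `FALSE` to test the filter gate).
#' @param seed Integer seed.
#' @param dir Output directory, as in [make_identifications()].
#' @return List with `spectra` (list as from [read_mgf()]), `truth` (data
#'   frame: `spectrum_id`, `accession`, `peptide`, `start`, `end`,
#'   `site_peptide`, `site_protein`), and `paths` when written.
#' @export
make_glyco_spectra <- function(n_spectra = 50L, proteins = toy_fasta(),
                               dropout = 0, n_decoy_peaks = 0L,
                               include_oxonium = TRUE, seed = 1L,
                               dir = NULL) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- read_protein_fasta(proteins)
  peptides <- do.call(rbind, lapply(names(proteins), function(acc) {
    d <- digest(proteins[[acc]], max_missed = 2L)
    d$accession <- acc
    d
  }))
  has_st <- vapply(strsplit(peptides$sequence, ""), function(a)
    any(a %in% c("S", "T")), TRUE)
  peptides <- peptides[has_st & nchar(peptides$sequence) >= 5L &
                         nchar(peptides$sequence) <= 30L, , drop = FALSE]
  proton <- MASS_CONSTANTS[["proton"]]
  with_fixture_seed(seed, {
    picks <- sample(nrow(peptides), n_spectra, replace = TRUE)
    spectra <- vector("list", n_spectra)
    truth <- vector("list", n_spectra)
    for (i in seq_len(n_spectra)) {
      pep <- peptides[picks[i], ]
      aa <- strsplit(pep$sequence, "")[[1L]]
      st <- which(aa %in% c("S", "T"))
      site <- if (length(st) == 1L) st else sample(st, 1L)
      pl <- rbind(
        if (any(aa == "C"))
          data.frame(position = which(aa == "C"), mod = "carbamidomethyl",
                     stringsAsFactors = FALSE),
        data.frame(position = site, mod = "stn", stringsAsFactors = FALSE)
      )
      frag <- fragment_ions(pep$sequence, pl)
      if (dropout > 0) frag <- frag[stats::runif(length(frag)) >= dropout]
      mz <- c(frag, if (include_oxonium) unname(OXONIUM_MZ),
              if (n_decoy_peaks > 0L)
                stats::runif(n_decoy_peaks, 150, 1800))
      peaks <- cbind(mz = mz, intensity = rep(100, length(mz)))
      peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
      z <- 2L
      spectra[[i]] <- list(
        id = sprintf("synthetic_scan_%04d", i),
        precursor_mz = (peptide_mass(pep$sequence, pl) + z * proton) / z,
        charge = z, peaks = peaks
      )
      truth[[i]] <- data.frame(
        spectrum_id = spectra[[i]]$id, accession = pep$accession,
        peptide = pep$sequence, start = pep$start, end = pep$end,
        site_peptide = site, site_protein = pep$start + site - 1L,
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth)
    out <- list(spectra = spectra, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(mgf = file.path(dir, "spectra.mgf"),
                 truth = file.path(dir, "spectra_truth.tsv"))
      write_mgf(spectra, paths[["mgf"]])
      write_tsv(truth, paths[["truth"]])
      out$paths <- paths
    }
    out
  })
}

#' Generate a two-group survival cohort
#'
#' Event times are exponential with the group hazard ratio applied to group
#' B; censoring times are independent exponentials scaled so that roughly
#' `censoring` of subjects are censored.
#'
#' @param n_per_group Vector of two group sizes (default `c(100, 100)`).
#' @param hazard_ratio Hazard ratio of group B vs A (> 0, default 1).
#' @param censoring Approximate fraction censored (in `[0, 1)`, default 0.2).
#' @param baseline_hazard Events per month in group A (default 0.05).
#' @param seed Integer seed.
#' @param dir Output directory, as in [make_identifications()].
#' @return List with `cohort` (data frame: `subject`, `group`, `time`,
#'   `event`) and `paths` when written.
#' @export
make_cohort <- function(n_per_group = c(100L, 100L), hazard_ratio = 1,
                        censoring = 0.2, baseline_hazard = 0.05, seed = 1L,
                        dir = NULL) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (any(n_per_group < 1L)) stop("group sizes must be >= 1")
  if (censoring < 0 || censoring >= 1) stop("censoring must lie in [0, 1)")
  with_fixture_seed(seed, {
    hazards <- c(A = baseline_hazard, B = baseline_hazard * hazard_ratio)
    rows <- lapply(c("A", "B"), function(g) {
      n <- n_per_group[match(g, c("A", "B"))]
      t_event <- stats::rexp(n, hazards[[g]])
      if (censoring > 0) {
        # censoring hazard c*h makes P(censored) = c/(1+c); solve for c
        crate <- censoring / (1 - censoring) * hazards[[g]]
        t_cens <- stats::rexp(n, crate)
      } else t_cens <- rep(Inf, n)
      data.frame(subject = paste0(g, sprintf("%04d", seq_len(n))),
                 group = g,
                 time = round(pmin(t_event, t_cens), 4),
                 event = as.integer(t_event <= t_cens),
                 stringsAsFactors = FALSE)
    })
    cohort <- do.call(rbind, rows)
    out <- list(cohort = cohort)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(cohort = file.path(dir, "cohort.tsv"))
      write_tsv(cohort, paths[["cohort"]])
      out$paths <- paths
    }
    out
  })
}
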
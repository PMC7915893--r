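# O-glycome m/z arithmetic for permethylated benzyl glycosides.
#
# The cellular O-glycome reporter strategy feeds cells benzyl-GalNAc; the
# secreted benzyl glycosides are permethylated and measured by LC-ESI-MS/MS.
# Every free hydroxyl/amide hydrogen is methylated and sialic acid carboxyls
# are methyl-esterified, so each methylation site adds CH2. Forming a
# glycosidic bond removes one hydroxyl, i.e. one methylation site, hence
# n_sites = sum(base sites) - (R - 1) for R residues, independent of branch
# topology.

#' Construct a glycan composition
#'
#' @param hex,hexnac,dhex,neuac Non-negative integer counts of each
#'   monosaccharide class.
#' @param label Optional free-text label (e.g. `"T antigen"`).
#' @return An object of class `glycan_composition`: a named integer vector of
#'   counts with a `label` attribute.
#' @examples
#' glycan_composition(hex = 1, hexnac = 1, label = "T antigen")
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0,
                               label = NULL) {
  counts <- c(Hex = hex, HexNAc = hexnac, dHex = dhex, NeuAc = neuac)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("monosaccharide counts must be non-negative integers")
  counts <- as.integer(round(counts))
  names(counts) <- c("Hex", "HexNAc", "dHex", "NeuAc")
  if (sum(counts) < 1L)
    stop("a glycan composition needs at least one residue")
  structure(counts, label = label, class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), unclass(nz), collapse = " ")
}

#' @export
print.glycan_composition <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<glycan composition> ", format(x),
      if (!is.null(lab)) paste0(" (", lab, ")"), "\n", sep = "")
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), MONOSACCHARIDES$class)
    if (length(bad))
      stop("unknown monosaccharide class: ", paste(bad, collapse = ", "))
    full <- stats::setNames(rep(0, 4), MONOSACCHARIDES$class)
    full[names(x)] <- x
    return(glycan_composition(full[["Hex"]], full[["HexNAc"]],
                              full[["dHex"]], full[["NeuAc"]]))
  }
  stop("cannot interpret object as a glycan composition")
}

#' Neutral monoisotopic mass of a permethylated benzyl glycoside
#'
#' Sums the residue masses, adds water and the benzyl substituent (C7H6,
#' replacing the anomeric hydroxyl hydrogen), and one CH2 per methylation
#' site, where the site count is the per-class total minus one per glycosidic
#' bond. Set `benzyl = FALSE` for a free reducing end (permethylated but not
#' benzylated); the standard reporter readout keeps the default.
#'
#' @param comp A [glycan_composition()] (or named count vector).
#' @param benzyl Include the benzyl aglycone (default `TRUE`).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' permethylated_benzyl_mass(glycan_composition(hex = 1, hexnac = 1)) # 571.2993
#' @export
permethylated_benzyl_mass <- function(comp, benzyl = TRUE) {
  comp <- as_composition(comp)
  counts <- unclass(comp)[MONOSACCHARIDES$class]
  r <- sum(counts)
  n_sites <- sum(counts * MONOSACCHARIDES$base_methyl_sites) - (r - 1L)
  mass <- sum(counts * MONOSACCHARIDES$residue_mass) +
    MASS_CONSTANTS[["water"]] +
    n_sites * MASS_CONSTANTS[["methylene"]]
  if (benzyl) {
    mass <- mass + MASS_CONSTANTS[["benzyl_substituent"]]
  } else {
    # the anomeric hydroxyl keeps its methyl instead of the benzyl
    mass <- mass + MASS_CONSTANTS[["methylene"]]
  }
  unname(mass)
}

#' Protonated m/z of a permethylated benzyl glycoside
#'
#' @inheritParams permethylated_benzyl_mass
#' @param charge Positive integer charge state; peaks are treated as
#'   protonated `[M + zH]z+`, singly charged by default.
#' @return m/z in Da.
#' @examples
#' glycan_mz(glycan_composition(hexnac = 1, neuac = 1)) # 729.38, STn
#' @export
glycan_mz <- function(comp, charge = 1L, benzyl = TRUE) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  (permethylated_benzyl_mass(comp, benzyl = benzyl) +
     charge * MASS_CONSTANTS[["proton"]]) / charge
}

#' Assign glycan compositions to an observed m/z
#'
#' Exhaustively enumerates compositions within per-class count bounds and
#' returns those whose computed `[M+H]+` lies within `tolerance` of the
#' observed value, ordered by absolute mass error, ties broken by fewer
#' residues then by class-count lexicographic order (Hex, HexNAc, dHex,
#' NeuAc).
#'
#' @param observed_mz Observed peak m/z (Da).
#' @param max_per_class Upper bound on the count of each monosaccharide class
#'   (scalar, or named vector per class). Default 6.
#' @param tolerance Match tolerance in Da (default 0.05).
#' @inheritParams permethylated_benzyl_mass
#' @return A data frame with columns `Hex`, `HexNAc`, `dHex`, `NeuAc`,
#'   `theoretical_mz` and `error_da`; zero rows when nothing matches.
#' @export
assign_composition <- function(observed_mz, max_per_class = 6L,
                               tolerance = 0.05, benzyl = TRUE) {
  stopifnot(length(observed_mz) == 1L, is.finite(observed_mz))
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0")
  classes <- MONOSACCHARIDES$class
  if (length(max_per_class) == 1L)
    max_per_class <- stats::setNames(rep(max_per_class, 4), classes)
  if (any(!is.finite(max_per_class)))
    stop("per-class bounds must be finite")
  max_per_class <- max_per_class[classes]
  grid <- expand.grid(
    Hex = 0:max_per_class[["Hex"]], HexNAc = 0:max_per_class[["HexNAc"]],
    dHex = 0:max_per_class[["dHex"]], NeuAc = 0:max_per_class[["NeuAc"]]
  )
  grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
  counts <- as.matrix(grid)
  r <- rowSums(counts)
  n_sites <- counts %*% MONOSACCHARIDES$base_methyl_sites - (r - 1L)
  mass <- counts %*% MONOSACCHARIDES$residue_mass +
    MASS_CONSTANTS[["water"]] + n_sites * MASS_CONSTANTS[["methylene"]]
  mass <- mass + if (benzyl) MASS_CONSTANTS[["benzyl_substituent"]] else
    MASS_CONSTANTS[["methylene"]]
  theo <- as.numeric(mass) + MASS_CONSTANTS[["proton"]]
  err <- theo - observed_mz
  keep <- abs(err) <= tolerance
  out <- cbind(grid[keep, , drop = FALSE],
               theoretical_mz = theo[keep], error_da = err[keep])
  ord <- order(abs(out$error_da), rowSums(out[, 1:4, drop = FALSE]),
               out$Hex, out$HexNAc, out$dHex, out$NeuAc)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize glycome intensities to relative abundances
#'
#' Each entry's relative abundance is its intensity divided by the summed
#' intensity of all entries, i.e. its contribution relative to the whole
#' detected glycome. Input order is preserved.
#'
#' @param entries A data frame with at least an `intensity` column
#'   (non-negative, not all zero).
#' @return The input with a `relative_abundance` column appended; class
#'   `glycome_profile`.
#' @export
normalize_glycome <- function(entries) {
  if (!is.data.frame(entries) || !"intensity" %in% names(entries))
    stop("entries must be a data frame with an 'intensity' column")
  ints <- entries$intensity
  if (any(!is.finite(ints)) || any(ints < 0))
    stop("intensities must be finite and >= 0")
  total <- sum(ints)
  if (total <= 0)
    stop("cannot normalize: all intensities are zero")
  entries$relative_abundance <- ints / total
  class(entries) <- c("glycome_profile", class(entries))
  entries
}

#' Annotate a peak table with glycan compositions and relative abundances
#'
#' For each peak, keeps the top-ranked composition assignment (if any) and
#' normalizes intensities over the annotated peaks.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @inheritParams assign_composition
#' @param library Optional composition library data frame with columns
#'   `label`, `Hex`, `HexNAc`, `dHex`, `NeuAc`; matched assignments inherit
#'   its labels.
#' @return A `glycome_profile` data frame with columns `observed_mz`,
#'   `intensity`, `label`, `composition`, `Hex`..`NeuAc`, `theoretical_mz`,
#'   `error_da`, `relative_abundance` (annotated peaks only).
#' @export
annotate_glycome <- function(peaks, max_per_class = 6L, tolerance = 0.05,
                             library = NULL) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    hits <- assign_composition(peaks$mz[i], max_per_class, tolerance)
    if (nrow(hits) == 0L) return(NULL)
    top <- hits[1L, ]
    comp <- glycan_composition(top$Hex, top$HexNAc, top$dHex, top$NeuAc)
    lab <- NA_character_
    if (!is.null(library)) {
      m <- which(library$Hex == top$Hex & library$HexNAc == top$HexNAc &
                   library$dHex == top$dHex & library$NeuAc == top$NeuAc)
      if (length(m)) lab <- library$label[m[1L]]
    }
    data.frame(observed_mz = peaks$mz[i], intensity = peaks$intensity[i],
               label = lab, composition = format(comp),
               top[, c("Hex", "HexNAc", "dHex", "NeuAc",
                       "theoretical_mz", "error_da")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no peak could be assigned a composition within tolerance")
  normalize_glycome(out)
}
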
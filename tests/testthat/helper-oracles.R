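# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Element-level mass oracle: monoisotopic atomic masses and per-residue
# elemental formulas. The package computes with residue-level constants;
# this recomputes from atoms.
ATOM <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)

GLYCAN_ELEMENTS <- list(
  Hex    = c(C = 6,  H = 10, N = 0, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  dHex   = c(C = 6,  H = 10, N = 0, O = 4),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8)
)

# neutral permethylated benzyl glycoside mass from elemental formulas
oracle_glycan_mass <- function(counts) {
  sites <- c(Hex = 4, HexNAc = 4, dHex = 3, NeuAc = 6)
  el <- c(C = 0, H = 0, N = 0, O = 0)
  for (cl in names(counts))
    el <- el + counts[[cl]] * GLYCAN_ELEMENTS[[cl]]
  r <- sum(unlist(counts))
  n_sites <- sum(sites[names(counts)] * unlist(counts)) - (r - 1)
  el <- el + c(C = 0, H = 2, N = 0, O = 1)            # water
  el <- el + c(C = 7, H = 6, N = 0, O = 0)            # benzyl substituent
  el <- el + n_sites * c(C = 1, H = 2, N = 0, O = 0)  # CH2 per site
  sum(el * ATOM[names(el)])
}

# brute-force tryptic digest: enumerate all (i, j) whose ends are valid
# cleavage boundaries and whose internal boundary count is <= max_missed
oracle_digest <- function(sequence, max_missed = 2L) {
  aa <- strsplit(sequence, "")[[1L]]
  n <- length(aa)
  is_cut <- vapply(seq_len(n), function(i)
    aa[i] %in% c("K", "R") && (i == n || aa[i + 1L] != "P"), TRUE)
  bounds <- c(0L, which(is_cut), if (!is_cut[n]) n)
  bounds <- sort(unique(bounds))
  peps <- character()
  for (i in seq_along(bounds)) for (j in seq_along(bounds)) {
    if (bounds[j] <= bounds[i]) next
    internal <- sum(bounds > bounds[i] & bounds < bounds[j])
    if (internal <= max_missed)
      peps <- c(peps, substring(sequence, bounds[i] + 1L, bounds[j]))
  }
  sort(peps)
}

# classical closed-form 2x2 Pearson statistic
oracle_chi2_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- sum(m)
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# hand-rolled product-limit estimator for one group
oracle_km <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out <- numeric(length(times))
  for (k in seq_along(times)) {
    at_risk <- sum(time >= times[k])
    deaths <- sum(time == times[k] & event == 1)
    s <- s * (1 - deaths / at_risk)
    out[k] <- s
  }
  data.frame(time = times, survival = out)
}

# scoring oracle: direct transliteration of the Target Score definition
oracle_target_score <- function(membrane, tumor, prognosis, healthy_levels,
                                healthy_systems, w) {
  mult <- ifelse(healthy_systems %in% c("reproductive", "immune", "nervous"),
                 w$system_penalty_multiplier, 1)
  pen_terms <- w$w_healthy_per_level * mult * healthy_levels
  pen <- if (length(pen_terms) == 0) 0 else
    if (w$healthy_aggregation == "mean") mean(pen_terms) else sum(pen_terms)
  w$w_membrane * membrane + w$w_tumor_per_level * tumor +
    w$w_prognosis * prognosis - pen
}
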
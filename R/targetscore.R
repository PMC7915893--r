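# Target Score: a linear prioritization heuristic for cell-surface
# biomarkers. It rewards plasma-membrane location, tumor expression level
# and poor-prognosis association, and penalizes expression in healthy
# tissues, with an extra multiplier for reproductive, immune and nervous
# system tissues where off-target effects would be most damaging.

EXPRESSION_LEVELS <- c(nd = 0L, low = 1L, medium = 2L, high = 3L)

PENALIZED_SYSTEMS <- c("reproductive", "immune", "nervous")

#' Scoring weights for the Target Score
#'
#' All weights are non-negative and configurable so an alternative published
#' weighting can be dropped in without code changes.
#'
#' @param w_membrane Reward for plasma-membrane location (default 3).
#' @param w_tumor_per_level Reward per ordinal tumor expression level 0-3
#'   (default 1).
#' @param w_prognosis Reward for an unfavorable-prognosis association
#'   (default 2).
#' @param w_healthy_per_level Penalty weight per healthy-tissue expression
#'   level (default 1).
#' @param system_penalty_multiplier Extra multiplier (>= 1) applied to
#'   reproductive, immune and nervous system tissues (default 2).
#' @param healthy_aggregation How per-tissue penalties combine: `"mean"`
#'   (default; insensitive to the number of profiled tissues) or `"sum"`.
#' @return A list of class `score_weights`.
#' @export
score_weights <- function(w_membrane = 3, w_tumor_per_level = 1,
                          w_prognosis = 2, w_healthy_per_level = 1,
                          system_penalty_multiplier = 2,
                          healthy_aggregation = c("mean", "sum")) {
  healthy_aggregation <- match.arg(healthy_aggregation)
  w <- list(w_membrane = w_membrane, w_tumor_per_level = w_tumor_per_level,
            w_prognosis = w_prognosis,
            w_healthy_per_level = w_healthy_per_level,
            system_penalty_multiplier = system_penalty_multiplier,
            healthy_aggregation = healthy_aggregation)
  num <- unlist(w[1:5])
  if (any(!is.finite(num)) || any(num[1:4] < 0))
    stop("score weights must be finite and non-negative")
  if (w$system_penalty_multiplier < 1)
    stop("system_penalty_multiplier must be >= 1")
  structure(w, class = "score_weights")
}

#' Read score weights from a YAML config
#'
#' Reads the `targetscore:` block of a YAML file; fields mirror the
#' arguments of [score_weights()]. Absent fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `score_weights` object.
#' @export
read_score_weights <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$targetscore)) cfg <- cfg$targetscore
  do.call(score_weights, cfg)
}

as_level <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 0 | x > 3, na.rm = TRUE))
      stop("expression levels must lie in 0..3")
    out <- as.integer(x)
  } else {
    out <- EXPRESSION_LEVELS[match(tolower(as.character(x)),
                                   names(EXPRESSION_LEVELS))]
  }
  # missing annotations are treated as not detected (no penalty)
  out[is.na(out)] <- 0L
  unname(out)
}

#' Bundled tissue-to-system map
#'
#' Maps healthy tissue names (Human Protein Atlas vocabulary) to the body
#' system used for penalty multipliers: reproductive, immune, nervous, or
#' other.
#'
#' @return Data frame with columns `tissue` and `system`.
#' @export
tissue_system_map <- function() {
  path <- system.file("extdata", "tissue_systems.tsv",
                      package = "glycotarget", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

system_of <- function(tissues, map = tissue_system_map()) {
  sys <- map$system[match(tolower(tissues), tolower(map$tissue))]
  sys[is.na(sys)] <- "other"
  sys
}

#' Compute the Target Score of one protein annotation
#'
#' score = w_membrane * membrane + w_tumor_per_level * tumor_level +
#' w_prognosis * unfavorable_prognosis - penalty, where the penalty
#' aggregates `w_healthy_per_level * multiplier(system) * level` over the
#' healthy-tissue profile (mean or sum per the weights), and the multiplier
#' is `system_penalty_multiplier` for reproductive/immune/nervous tissues,
#' 1 otherwise.
#'
#' @param plasma_membrane Logical: annotated at the plasma membrane.
#' @param tumor_level Tumor expression level, 0-3 or
#'   `"nd"/"low"/"medium"/"high"`.
#' @param unfavorable_prognosis Logical: associated with poor prognosis.
#' @param healthy_levels Named vector of healthy-tissue expression levels
#'   (names are tissue names; values 0-3 or level strings). May be empty.
#' @param weights A [score_weights()] object.
#' @param system_map Tissue-to-system map (default bundled).
#' @return Numeric score.
#' @export
target_score <- function(plasma_membrane, tumor_level,
                         unfavorable_prognosis, healthy_levels = numeric(),
                         weights = score_weights(),
                         system_map = tissue_system_map()) {
  stopifnot(inherits(weights, "score_weights"))
  reward <- weights$w_membrane * as.numeric(isTRUE(as.logical(plasma_membrane))) +
    weights$w_tumor_per_level * as_level(tumor_level) +
    weights$w_prognosis * as.numeric(isTRUE(as.logical(unfavorable_prognosis)))
  if (length(healthy_levels)) {
    lev <- as_level(healthy_levels)
    mult <- ifelse(system_of(names(healthy_levels), system_map) %in%
                     PENALIZED_SYSTEMS,
                   weights$system_penalty_multiplier, 1)
    terms <- weights$w_healthy_per_level * mult * lev
    penalty <- switch(weights$healthy_aggregation,
                      mean = mean(terms), sum = sum(terms))
  } else {
    penalty <- 0
  }
  reward - penalty
}

#' Read a protein annotation table
#'
#' Expected columns: `accession`, `plasma_membrane` (logical/0-1),
#' `tumor_level`, `prognosis_unfavorable`, then one column per healthy
#' tissue holding levels `nd/low/medium/high` (or 0-3). `tumor_column`
#' renames an alternative tumor-expression column (e.g. a related tumor
#' type used as proxy when the tumor of interest is not profiled) into
#' `tumor_level`.
#'
#' @param path Annotation TSV.
#' @param tumor_column Column to use as `tumor_level` (default
#'   `"tumor_level"`).
#' @return Data frame; non-tissue columns first, tissue columns after.
#' @export
read_annotations <- function(path, tumor_column = "tumor_level") {
  ann <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!tumor_column %in% names(ann))
    stop("annotation table lacks tumor column '", tumor_column, "'")
  names(ann)[names(ann) == tumor_column] <- "tumor_level"
  required <- c("accession", "plasma_membrane", "tumor_level",
                "prognosis_unfavorable")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation table lacks column(s): ",
         paste(missing, collapse = ", "))
  ann
}

tissue_columns <- function(ann) {
  setdiff(names(ann), c("accession", "gene", "plasma_membrane",
                        "tumor_level", "prognosis_unfavorable"))
}

#' Rank proteins by Target Score
#'
#' @param ann Annotation data frame (see [read_annotations()]).
#' @param weights A [score_weights()] object.
#' @param system_map Tissue-to-system map (default bundled).
#' @return Data frame `accession`, `score`, `rank` (dense, ties by
#'   accession), plus component columns `reward_membrane`, `reward_tumor`,
#'   `reward_prognosis`, `penalty_healthy`.
#' @export
rank_proteins <- function(ann, weights = score_weights(),
                          system_map = tissue_system_map()) {
  if (!is.data.frame(ann) || nrow(ann) == 0L)
    stop("at least one annotation is required")
  tcols <- tissue_columns(ann)
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    healthy <- if (length(tcols))
      stats::setNames(unlist(ann[i, tcols]), tcols) else numeric()
    s <- target_score(ann$plasma_membrane[i], ann$tumor_level[i],
                      ann$prognosis_unfavorable[i], healthy,
                      weights, system_map)
    base <- target_score(ann$plasma_membrane[i], ann$tumor_level[i],
                         ann$prognosis_unfavorable[i], numeric(), weights)
    data.frame(
      accession = ann$accession[i], score = s,
      reward_membrane = weights$w_membrane *
        as.numeric(isTRUE(as.logical(ann$plasma_membrane[i]))),
      reward_tumor = weights$w_tumor_per_level * as_level(ann$tumor_level[i]),
      reward_prognosis = weights$w_prognosis *
        as.numeric(isTRUE(as.logical(ann$prognosis_unfavorable[i]))),
      penalty_healthy = base - s,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$accession), , drop = FALSE]
  out$rank <- cumsum(!duplicated(round(-out$score, 12)))
  rownames(out) <- NULL
  out[, c("accession", "score", "rank", "reward_membrane", "reward_tumor",
          "reward_prognosis", "penalty_healthy")]
}
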
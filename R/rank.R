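#' Truncate a source ranking to a cutoff
#'
#' Keeps the entries with rank <= cutoff (the study truncates every
#' signature-reversal source to its top 50 drugs, the cap imposed by the
#' smallest source's export limit); ranks are unchanged.
#'
#' @param r a `source_ranking`.
#' @param cutoff maximum rank kept.
#' @return A `source_ranking` with at most `cutoff` entries.
#' @export
truncate_ranking <- function(r, cutoff = 50) {
  keep <- r$rank <= cutoff
  source_ranking(r$source, r$drug[keep], r$rank[keep])
}

#' Consensus prior score across ranked drug lists
#'
#' Aggregates K source rankings into one prior per drug, weighting the
#' average rank and the number of occurrences:
#' \deqn{prior = (k/K) \cdot (1 - (\bar{rank} - 1)/cutoff)}
#' where k is the number of sources listing the drug and \eqn{\bar{rank}}
#' its mean rank across those sources. A drug ranked first by every source
#' attains prior 1; appearing in more sources, or at better ranks, never
#' lowers the prior. The output feeds the composite score as its activity
#' component.
#'
#' @param rankings a list of `source_ranking` objects (already truncated).
#' @param cutoff the rank cutoff used for normalization (default 50).
#' @return A data.frame (`drug`, `k`, `mean_rank`, `prior`) sorted by
#'   descending prior, ties broken lexicographically by drug id.
#' @export
consensus_prior <- function(rankings, cutoff = 50) {
  if (length(rankings) == 0) stop("at least one source ranking is required")
  K <- length(rankings)
  df <- do.call(rbind, lapply(rankings, function(r)
    data.frame(drug = r$drug, rank = r$rank, stringsAsFactors = FALSE)))
  if (any(df$rank > cutoff))
    stop("rankings contain ranks beyond the cutoff; truncate first")
  agg <- do.call(rbind, lapply(split(df, df$drug), function(d)
    data.frame(drug = d$drug[1], k = nrow(d), mean_rank = mean(d$rank),
               stringsAsFactors = FALSE)))
  agg$prior <- (agg$k / K) * (1 - (agg$mean_rank - 1) / cutoff)
  agg <- agg[order(-agg$prior, agg$drug), ]
  rownames(agg) <- NULL
  agg
}

#' Functional score: disease-target overlap precision
#'
#' Fraction of a drug's target genes that belong to the disease gene set.
#' Serves as the functional component of the composite score.
#'
#' @param drug_genes character vector of the drug's target genes (non-empty).
#' @param disease a `signed_gene_set`.
#' @return A number in \[0, 1\].
#' @export
functional_score <- function(drug_genes, disease) {
  drug_genes <- unique(as.character(drug_genes))
  if (length(drug_genes) == 0) stop("drug_genes must be non-empty")
  length(intersect(drug_genes, names(disease$direction))) / length(drug_genes)
}

#' Structural score: drug-likeness rule fraction
#'
#' The fraction of four classical drug-likeness rules a structure
#' satisfies: molecular weight <= 500, computed logP <= 5, hydrogen-bond
#' donors <= 5, hydrogen-bond acceptors <= 10. Serves as the structural
#' component of the composite score.
#'
#' @param smiles a single SMILES string.
#' @return A number in \{0, 0.25, 0.5, 0.75, 1\}, with an attribute
#'   `rules` giving the per-rule logical vector.
#' @export
structural_score <- function(smiles) {
  props <- molecular_properties(smiles)
  rules <- c(mw = props$MW <= 500,
             logp = props$logP <= 5,
             hbd = props$HBD <= 5,
             hba = props$HBA <= 10)
  structure(mean(rules), rules = rules)
}

#' Composite (activity/functional/structural) drug score
#'
#' The weighted composite `waS * aS + wFS * FS + wStS * StS` with the
#' study weights (0.45, 0.45, 0.1) by default. All components must lie in
#' \[0, 1\].
#'
#' @param aS activity score(s) in \[0, 1\] (e.g. the consensus prior).
#' @param FS functional score(s) in \[0, 1\].
#' @param StS structural score(s) in \[0, 1\].
#' @param weights numeric length-3 vector (waS, wFS, wStS), summing to 1.
#' @return Numeric vector of composite scores, same length as the inputs.
#' @export
codres_score <- function(aS, FS, StS,
                         weights = c(waS = 0.45, wFS = 0.45, wStS = 0.1)) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be 3 non-negative numbers summing to 1")
  comp <- cbind(aS, FS, StS)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 1))
    stop("all score components must lie in [0, 1]")
  drop(comp %*% as.numeric(weights))
}

#' Score a drug panel end to end
#'
#' Convenience wrapper: aggregates source rankings into the consensus
#' prior, computes functional scores from drug-target sets and structural
#' scores from SMILES, and combines them into the composite score. Drugs
#' without target data get FS = 0; drugs without a structure get StS = 0.
#'
#' @param rankings list of `source_ranking` objects.
#' @param disease a `signed_gene_set` (disease signature).
#' @param drug_targets optional named list: drug id -> character vector of
#'   target genes.
#' @param drug_smiles optional named character vector: drug id -> SMILES.
#' @param config a `pipeline_config`.
#' @return A data.frame (`drug`, `k`, `mean_rank`, `prior`, `aS`, `FS`,
#'   `StS`, `composite`) sorted by descending composite, ties broken by
#'   drug id.
#' @export
score_drugs <- function(rankings, disease, drug_targets = NULL,
                        drug_smiles = NULL, config = pipeline_config()) {
  rankings <- lapply(rankings, truncate_ranking, cutoff = config$rank_cutoff)
  prior <- consensus_prior(rankings, cutoff = config$rank_cutoff)
  prior$aS <- prior$prior
  prior$FS <- vapply(prior$drug, function(d) {
    tg <- drug_targets[[d]]
    if (is.null(tg) || length(tg) == 0) 0 else functional_score(tg, disease)
  }, numeric(1))
  prior$StS <- vapply(prior$drug, function(d) {
    smi <- drug_smiles[d]
    if (is.null(drug_smiles) || is.na(smi)) 0
    else as.numeric(structural_score(smi))
  }, numeric(1))
  prior$composite <- codres_score(prior$aS, prior$FS, prior$StS,
                                  weights = config$codres_weights)
  prior <- prior[order(-prior$composite, prior$drug), ]
  rownames(prior) <- NULL
  prior
}
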
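#' Build the signed bipartite compound-gene network
#'
#' One edge per (compound, gene) pair with the gene shared between the
#' compound's perturbation signature and the reference disease set. The
#' edge is labeled `reverse` when the compound drives the gene opposite to
#' the disease direction (antagonistic, the therapeutic case) and `mimic`
#' when it drives it the same way (synergistic with the disease).
#'
#' @param signatures a named list of compound signatures (named +1/-1
#'   vectors, as from [read_signatures()] or [gen_signatures()]).
#' @param reference a `signed_gene_set` (disease or M2 set).
#' @return A data.frame (`compound`, `relation`, `gene`), one row per edge.
#' @export
build_bipartite <- function(signatures, reference) {
  if (length(reference$direction) == 0)
    stop("reference gene set must be non-empty")
  ref <- reference$direction
  rows <- lapply(sort(names(signatures)), function(cp) {
    sig <- signatures[[cp]]
    shared <- intersect(names(sig), names(ref))
    if (length(shared) == 0) return(NULL)
    shared <- sort(shared)
    data.frame(compound = cp,
               relation = ifelse(sig[shared] == -ref[shared],
                                 "reverse", "mimic"),
               gene = shared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compound = character(0), relation = character(0),
                      gene = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Raw network criticality ratio for one compound
#'
#' `(Degree_reverse - Degree_mimic) / |S_i intersect S_ref|`: +1 for a pure
#' reverser of the reference signature, -1 for a pure mimic. A compound
#' sharing no gene with the reference scores 0 (uninformative), with a
#' warning.
#'
#' @param signature a named +1/-1 vector (compound gene directions).
#' @param reference a `signed_gene_set`.
#' @return A list with `deg_rev`, `deg_mim`, `n_shared`, `raw`.
#' @export
raw_score <- function(signature, reference) {
  ref <- reference$direction
  shared <- intersect(names(signature), names(ref))
  n <- length(shared)
  if (n == 0) {
    warning("signature shares no gene with the reference set; raw score 0")
    return(list(deg_rev = 0L, deg_mim = 0L, n_shared = 0L, raw = 0))
  }
  rev <- sum(signature[shared] == -ref[shared])
  list(deg_rev = as.integer(rev), deg_mim = as.integer(n - rev),
       n_shared = as.integer(n), raw = (2 * rev - n) / n)
}

#' Normalize raw scores by the absolute maximum
#'
#' Divides every raw score by `max(|raw|)` so the scores span the unit
#' interval (-1, 1) with the strongest compound at +/-1. If every raw
#' score is 0, all normalized scores are 0.
#'
#' @param raw numeric vector of raw ratios.
#' @return Numeric vector of normalized scores in \[-1, 1\].
#' @export
normalize_scores <- function(raw) {
  if (length(raw) == 0) stop("at least one compound is required")
  m <- max(abs(raw))
  if (m == 0) return(raw * 0)
  raw / m
}

#' Weighted drug-repurposing (DR) score
#'
#' `DR = omega_bm * score_bm + omega_m2 * score_m2`, combining the
#' compound's normalized criticality against the bone-metastasis signature
#' and against the M2-macrophage (GSEA) signature. The study weights the
#' M2 axis more heavily (0.3 / 0.7).
#'
#' @param score_bm,score_m2 normalized scores in \[-1, 1\].
#' @param omega_bm,omega_m2 non-negative weights summing to 1.
#' @return Numeric vector of DR scores in \[-1, 1\].
#' @export
dr_score <- function(score_bm, score_m2, omega_bm = 0.3, omega_m2 = 0.7) {
  if (omega_bm < 0 || omega_m2 < 0 || abs(omega_bm + omega_m2 - 1) > 1e-9)
    stop("omega_bm and omega_m2 must be non-negative and sum to 1")
  omega_bm * score_bm + omega_m2 * score_m2
}

#' Score compounds against the disease and M2 signatures
#'
#' Full network-scoring stage: per compound, reverse/mimic degrees and raw
#' ratios against both reference sets, max-|raw| normalization of each axis
#' (independently by default), and the weighted DR score.
#'
#' @param signatures a named list of compound signatures.
#' @param bm_set the bone-metastasis `signed_gene_set`.
#' @param m2_set the M2-macrophage (GSEA-derived) `signed_gene_set`.
#' @param config a `pipeline_config` (omega weights).
#' @param normalize_m2_by `"own_max"` (default) normalizes the M2 axis by
#'   its own maximum |raw|; `"bm_max"` by the bone-metastasis maximum.
#' @return A data.frame, one row per compound, sorted by descending `dr`
#'   (ties broken by compound id): `compound`, `deg_rev_bm`, `deg_mim_bm`,
#'   `raw_bm`, `score_bm`, `deg_rev_m2`, `deg_mim_m2`, `raw_m2`,
#'   `score_m2`, `dr`.
#' @export
network_score <- function(signatures, bm_set, m2_set,
                          config = pipeline_config(),
                          normalize_m2_by = c("own_max", "bm_max")) {
  normalize_m2_by <- match.arg(normalize_m2_by)
  compounds <- sort(names(signatures))
  per_set <- function(reference) {
    res <- lapply(compounds, function(cp)
      suppressWarnings(raw_score(signatures[[cp]], reference)))
    data.frame(deg_rev = vapply(res, `[[`, integer(1), "deg_rev"),
               deg_mim = vapply(res, `[[`, integer(1), "deg_mim"),
               raw = vapply(res, `[[`, numeric(1), "raw"))
  }
  bm <- per_set(bm_set)
  m2 <- per_set(m2_set)
  score_bm <- normalize_scores(bm$raw)
  score_m2 <- if (normalize_m2_by == "own_max") normalize_scores(m2$raw)
              else if (max(abs(bm$raw)) == 0) m2$raw * 0
              else m2$raw / max(abs(bm$raw))
  out <- data.frame(compound = compounds,
                    deg_rev_bm = bm$deg_rev, deg_mim_bm = bm$deg_mim,
                    raw_bm = bm$raw, score_bm = score_bm,
                    deg_rev_m2 = m2$deg_rev, deg_mim_m2 = m2$deg_mim,
                    raw_m2 = m2$raw, score_m2 = score_m2,
                    stringsAsFactors = FALSE)
  out$dr <- dr_score(out$score_bm, out$score_m2,
                     omega_bm = config$omega_bm, omega_m2 = config$omega_m2)
  out <- out[order(-out$dr, out$compound), ]
  rownames(out) <- NULL
  out
}
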
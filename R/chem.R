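#' Canonicalize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return The canonical SMILES, or `NA_character_` if the structure does
#'   not parse.
#' @export
canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\tmol\n")),
    error = function(e) "")
  out <- trimws(out)
  if (!nzchar(out)) return(NA_character_)
  strsplit(out, "\t", fixed = TRUE)[[1]][1]
}

#' Physicochemical properties of a structure
#'
#' Molecular weight, computed logP, hydrogen-bond donor and acceptor
#' counts, via Open Babel descriptors.
#'
#' @param smiles a single SMILES string.
#' @return A list with elements `MW`, `logP`, `HBD`, `HBA`.
#' @export
molecular_properties <- function(smiles) {
  mol <- parse_mol(smiles)
  p <- ChemmineOB::prop_OB(mol)
  list(MW = p$MW, logP = p$logP, HBD = p$HBD, HBA = p$HBA2)
}

parse_mol <- function(smiles) {
  if (length(smiles) != 1 || is.na(smiles))
    stop("a single SMILES string is required")
  if (is.na(canonical_smiles(smiles)))
    stop("unparsable SMILES: ", smiles)
  ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tmol"), identity)
}

#' Hashed circular substructure fingerprint
#'
#' Extended-connectivity fingerprint of radius 2 (ECFP4), hashed and folded
#' to `length` bits. Identical structures (after canonicalization) give
#' identical fingerprints.
#'
#' @param smiles a single SMILES string.
#' @param length fingerprint length in bits (default 2048).
#' @return An integer 0/1 vector of `length` bits.
#' @export
fingerprint <- function(smiles, length = 2048) {
  mol <- parse_mol(smiles)
  raw <- ChemmineOB::fingerprint_OB(mol, "ECFP4")
  raw <- as.integer(raw != 0)
  n <- base::length(raw)
  if (n == length) return(raw)
  folded <- integer(length)
  idx <- (seq_len(n) - 1L) %% length + 1L
  folded[unique(idx[raw == 1L])] <- 1L
  folded
}

#' Fingerprint a compound library
#'
#' @param compounds a data.frame with columns `id` and `smiles` (as from
#'   [read_smiles()] or [gen_smiles_library()]).
#' @param length fingerprint length in bits.
#' @return An integer matrix (compounds x bits) with `id` rownames.
#' @export
fingerprint_matrix <- function(compounds, length = 2048) {
  fps <- t(vapply(compounds$smiles, fingerprint, integer(length),
                  length = length))
  rownames(fps) <- compounds$id
  fps
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`; two all-zero vectors are defined as similarity
#' 1 (identical absence of features).
#'
#' @param a,b equal-length 0/1 vectors.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps an integer 0/1 matrix (compounds x bits) with id rownames.
#' @return A symmetric n x n similarity matrix with unit diagonal.
#' @export
similarity_matrix <- function(fps) {
  fps <- as.matrix(fps) * 1
  common <- tcrossprod(fps)
  counts <- diag(common)
  union <- outer(counts, counts, "+") - common
  sim <- ifelse(union == 0, 1, common / pmax(union, 1))
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(fps), rownames(fps))
  sim
}

#' Ward clustering of a similarity matrix
#'
#' Agglomerative clustering with Ward's minimum-variance linkage on the
#' distance d = 1 - similarity, cut at the merge height corresponding to
#' d = 1 - `min_similarity` (default: minimum Tanimoto similarity 80%).
#' Cluster ids are 1-based and ordered by the lexicographically smallest
#' member id, making the assignment invariant to input order.
#'
#' @param sim a symmetric similarity matrix with id dimnames.
#' @param min_similarity minimum within-cluster similarity in (0, 1).
#' @return A `cluster_assignment`: data.frame (`id`, `cluster`) with the
#'   `hclust` tree and cut height as attributes.
#' @export
ward_cluster <- function(sim, min_similarity = 0.80) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n == 0) stop("empty similarity matrix")
  if (min_similarity <= 0 || min_similarity >= 1)
    stop("min_similarity must lie in (0, 1)")
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1) {
    out <- data.frame(id = ids, cluster = 1L, stringsAsFactors = FALSE)
    class(out) <- c("cluster_assignment", "data.frame")
    return(out)
  }
  d <- stats::as.dist(1 - sim)
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, h = 1 - min_similarity)
  out <- data.frame(id = ids, cluster = canonical_cluster_ids(raw, ids),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_assignment", "data.frame")
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- 1 - min_similarity
  out
}

# relabel clusters 1..k ordered by each cluster's smallest member id
canonical_cluster_ids <- function(raw, ids) {
  smallest <- vapply(split(ids, raw), min, character(1))
  relabel <- stats::setNames(rank(smallest, ties.method = "first"),
                             names(smallest))
  as.integer(relabel[as.character(raw)])
}

#' Select one representative compound per cluster
#'
#' The representative is the member with the highest composite score
#' (missing scores count as -Inf); ties are broken by the lexicographically
#' smallest id.
#'
#' @param clusters a `cluster_assignment` from [ward_cluster()].
#' @param scores a named numeric vector: compound id -> composite score.
#' @return The `cluster_assignment` with a logical `representative`
#'   column filled in.
#' @export
select_representatives <- function(clusters, scores) {
  sc <- scores[clusters$id]
  sc[is.na(sc)] <- -Inf
  clusters$score <- unname(sc)
  reps <- vapply(split(seq_len(nrow(clusters)), clusters$cluster),
                 function(rows) {
    best <- rows[clusters$score[rows] == max(clusters$score[rows])]
    best[order(clusters$id[best])][1]
  }, integer(1))
  clusters$representative <- seq_len(nrow(clusters)) %in% reps
  clusters
}

#' Flag candidates by structural overlap with clinical-trial drugs
#'
#' Candidates and trial drugs are clustered jointly; each candidate is then
#' classified: `in_trial` if a trial drug with the identical canonical
#' structure exists, `trial_similar` if its cluster contains at least one
#' trial drug, otherwise `structurally_specific` — the structurally novel
#' candidates the screen is after.
#'
#' @param compounds a data.frame with columns `id`, `smiles` and a logical
#'   `is_trial_drug` column.
#' @param config a `pipeline_config` (fingerprint length and minimum
#'   Tanimoto similarity).
#' @return A data.frame (`id`, `cluster`, `status`) for the non-trial
#'   candidates, plus the full joint `cluster_assignment` as attribute
#'   `clusters`.
#' @export
annotate_trial_overlap <- function(compounds, config = pipeline_config()) {
  if (!"is_trial_drug" %in% names(compounds))
    stop("compounds must carry an is_trial_drug column")
  canon <- vapply(compounds$smiles, canonical_smiles, character(1),
                  USE.NAMES = FALSE)
  if (anyNA(canon))
    stop("unparsable SMILES for id(s): ",
         paste(compounds$id[is.na(canon)], collapse = ", "))
  fps <- fingerprint_matrix(compounds, length = config$fingerprint_length)
  sim <- similarity_matrix(fps)
  clusters <- ward_cluster(sim, min_similarity = config$tanimoto_min_similarity)
  trial_canon <- canon[compounds$is_trial_drug]
  trial_clusters <- clusters$cluster[clusters$id %in%
                                     compounds$id[compounds$is_trial_drug]]
  cand <- !compounds$is_trial_drug
  status <- vapply(which(cand), function(i) {
    if (canon[i] %in% trial_canon) "in_trial"
    else {
      cl <- clusters$cluster[clusters$id == compounds$id[i]]
      if (cl %in% trial_clusters) "trial_similar" else "structurally_specific"
    }
  }, character(1))
  out <- data.frame(id = compounds$id[cand],
                    cluster = clusters$cluster[match(compounds$id[cand],
                                                     clusters$id)],
                    status = status, stringsAsFactors = FALSE)
  attr(out, "clusters") <- clusters
  out
}
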
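#' Construct a signed gene set
#'
#' A signed gene set records, for each gene, the direction of regulation in
#' the phenotype it describes: +1 (up in bone metastases relative to the
#' primary tumour, or up-regulated by a compound) or -1 (down). It is the
#' common currency of the network-scoring stage: the disease set, the
#' M2-macrophage (GSEA-derived) set and every compound signature all take
#' this form.
#'
#' @param genes character vector of gene identifiers (unique).
#' @param directions numeric vector of +1/-1, parallel to `genes`.
#' @param log2fc optional numeric vector of log2 fold-changes.
#' @param label optional set label (e.g. "BM", "GSEA_M2").
#' @return A `signed_gene_set`: list with `direction` (named +1/-1 vector),
#'   optional `log2fc`, and `label`.
#' @export
signed_gene_set <- function(genes, directions, log2fc = NULL, label = NULL) {
  genes <- as.character(genes)
  directions <- as.numeric(directions)
  if (length(genes) != length(directions))
    stop("genes and directions must have equal length")
  if (anyDuplicated(genes))
    stop("duplicate gene(s) in signed gene set: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(directions) > 0 && !all(directions %in% c(-1, 1)))
    stop("directions must be +1 or -1")
  if (!is.null(log2fc)) {
    log2fc <- as.numeric(log2fc)
    if (length(log2fc) != length(genes))
      stop("log2fc must be parallel to genes")
    names(log2fc) <- genes
  }
  structure(list(direction = stats::setNames(directions, genes),
                 log2fc = log2fc, label = label),
            class = "signed_gene_set")
}

#' @export
print.signed_gene_set <- function(x, ...) {
  cat("signed_gene_set", if (!is.null(x$label)) paste0("'", x$label, "'"),
      ":", length(x$direction), "genes (",
      sum(x$direction > 0), "up,", sum(x$direction < 0), "down )\n")
  invisible(x)
}

#' @export
length.signed_gene_set <- function(x) length(x$direction)

#' Filter a DEG table into a signed disease gene set
#'
#' A gene is retained iff `adj_p < p_thr` and `|log2fc| > lfc_thr`, both
#' strict; its direction is the sign of the fold-change. The defaults are
#' the study thresholds (adjusted p < 0.05, |log2FC| > 1).
#'
#' @param table a DEG table (data.frame with `gene`, `log2fc`, `adj_p`).
#' @param p_thr adjusted-p threshold (strict upper bound).
#' @param lfc_thr |log2 fold-change| threshold (strict lower bound).
#' @param label label for the resulting set.
#' @return A `signed_gene_set` with a `counts` attribute: named integer
#'   vector `(total, up, down)`.
#' @export
filter_degs <- function(table, p_thr = 0.05, lfc_thr = 1.0, label = "BM") {
  validate_deg_table(table)
  keep <- table$adj_p < p_thr & abs(table$log2fc) > lfc_thr
  sel <- table[keep, , drop = FALSE]
  set <- signed_gene_set(sel$gene, sign(sel$log2fc), log2fc = sel$log2fc,
                         label = label)
  attr(set, "counts") <- c(total = nrow(sel),
                           up = sum(sel$log2fc > 0),
                           down = sum(sel$log2fc < 0))
  set
}

#' Correlate gene expression with cell-type abundance
#'
#' Pearson correlation between one gene's per-sample expression and a
#' per-sample cell-type abundance estimate (e.g. a macrophage fraction from
#' immune deconvolution), with a two-sided p-value from the t-transform of
#' r on n - 2 degrees of freedom.
#'
#' @param expr numeric vector of per-sample expression values.
#' @param abundance numeric vector of per-sample cell-type fractions.
#' @return A list with elements `r` and `p`.
#' @export
correlate_gene_abundance <- function(expr, abundance) {
  if (length(expr) != length(abundance))
    stop("expr and abundance must be paired (equal length)")
  if (length(expr) < 3)
    stop("at least 3 paired samples are required")
  if (stats::sd(expr) == 0 || stats::sd(abundance) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(expr, abundance, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Select cell-type-associated genes from correlation records
#'
#' Keeps genes whose correlation with the cell-type abundance exceeds
#' `r_thr` (strict) and is significant at `p_thr` (strict). In `"signed"`
#' mode (default) the raw r must exceed the threshold — the screen targets
#' positively macrophage-associated genes; `"absolute"` mode applies the
#' threshold to |r|.
#'
#' @param genes character vector of gene identifiers to screen.
#' @param correlations a named list (one entry per gene) of `list(r=, p=)`
#'   records as returned by [correlate_gene_abundance()].
#' @param r_thr correlation threshold (strict), default 0.3.
#' @param p_thr significance threshold (strict), default 0.05.
#' @param mode `"signed"` or `"absolute"`.
#' @return Character vector of retained genes (input order preserved).
#' @export
select_associated_genes <- function(genes, correlations, r_thr = 0.3,
                                    p_thr = 0.05,
                                    mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  missing <- setdiff(genes, names(correlations))
  if (length(missing) > 0)
    stop("missing correlation record(s) for gene(s): ",
         paste(missing, collapse = ", "))
  keep <- vapply(genes, function(g) {
    rec <- correlations[[g]]
    r <- if (mode == "signed") rec$r else abs(rec$r)
    r > r_thr && rec$p < p_thr
  }, logical(1))
  genes[keep]
}

#' Intersect gene sets by minimum support
#'
#' Returns the genes present in at least `min_support` of the supplied
#' sets; by default a gene must appear in all of them (the consensus used
#' to pin genes confirmed by several deconvolution methods across several
#' datasets).
#'
#' @param sets a list of character vectors (gene sets).
#' @param min_support minimum number of sets a gene must belong to;
#'   defaults to `length(sets)`.
#' @return Sorted character vector of consensus genes.
#' @export
consensus_intersect <- function(sets, min_support = length(sets)) {
  if (length(sets) < 1) stop("at least one gene set is required")
  if (min_support > length(sets))
    stop("min_support cannot exceed the number of sets")
  counts <- table(unlist(lapply(sets, unique)))
  sort(names(counts)[counts >= min_support])
}
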
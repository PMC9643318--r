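#' Read a differential-expression table
#'
#' Expects a TSV with header columns `gene`, `log2fc`, `adj_p` (extra
#' columns are preserved). Genes must be unique and adjusted p-values must
#' lie in \[0, 1\]; rows are kept in file order.
#'
#' @param path path to a TSV file.
#' @return A data.frame with columns `gene` (character), `log2fc`, `adj_p`.
#' @export
read_deg_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "log2fc", "adj_p"))
  df$gene <- as.character(df$gene)
  df$log2fc <- as.numeric(df$log2fc)
  df$adj_p <- as.numeric(df$adj_p)
  validate_deg_table(df)
  df
}

validate_deg_table <- function(df) {
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0)
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  bad <- !is.finite(df$adj_p) | df$adj_p < 0 | df$adj_p > 1
  if (any(bad))
    stop("adj_p outside [0,1] for gene(s): ",
         paste(df$gene[bad], collapse = ", "))
  invisible(df)
}

#' Write a differential-expression table
#'
#' @param df a DEG table as returned by [read_deg_table()].
#' @param path output TSV path.
#' @export
write_deg_table <- function(df, path) {
  validate_deg_table(df)
  write_table(df[c("gene", "log2fc", "adj_p")], path)
}

#' Read ranked drug lists from signature-reversal sources
#'
#' Expects a TSV with columns `source`, `drug`, `rank`. Within every source
#' the ranks must form the exact set 1..n (no gaps, no duplicates).
#'
#' @param path path to a TSV file.
#' @return A named list of `source_ranking` objects (see [source_ranking()]),
#'   ordered by source name.
#' @export
read_rankings <- function(path) {
  df <- read_tsv_checked(path, c("source", "drug", "rank"))
  df$source <- as.character(df$source)
  df$drug <- as.character(df$drug)
  df$rank <- as.integer(df$rank)
  out <- lapply(split(df, df$source), function(d) {
    source_ranking(d$source[1], d$drug[order(d$rank)],
                   ranks = sort(d$rank))
  })
  out[order(names(out))]
}

#' Construct one source's ranked drug list
#'
#' @param source source identifier (e.g. the perturbation database name).
#' @param drugs character vector of drug identifiers, best first.
#' @param ranks optional explicit 1-based ranks matching `drugs`; defaults
#'   to `seq_along(drugs)`. Must form the set 1..n.
#' @return A `source_ranking`: list with elements `source`, `drug`, `rank`
#'   (sorted by rank).
#' @export
source_ranking <- function(source, drugs, ranks = seq_along(drugs)) {
  drugs <- as.character(drugs)
  ranks <- as.integer(ranks)
  if (length(drugs) != length(ranks))
    stop("drugs and ranks must have equal length")
  if (anyDuplicated(drugs))
    stop("duplicate drug(s) in source '", source, "': ",
         paste(unique(drugs[duplicated(drugs)]), collapse = ", "))
  if (!identical(sort(ranks), seq_along(ranks)))
    stop("ranks for source '", source,
         "' must be exactly 1..n with no gaps or duplicates")
  ord <- order(ranks)
  structure(list(source = as.character(source)[1],
                 drug = drugs[ord], rank = ranks[ord]),
            class = "source_ranking")
}

#' @export
print.source_ranking <- function(x, ...) {
  cat("source_ranking '", x$source, "': ", length(x$drug), " drugs\n", sep = "")
  invisible(x)
}

#' Write ranked drug lists
#'
#' @param rankings a list of `source_ranking` objects.
#' @param path output TSV path.
#' @export
write_rankings <- function(rankings, path) {
  df <- do.call(rbind, lapply(rankings, function(r)
    data.frame(source = r$source, drug = r$drug, rank = r$rank,
               stringsAsFactors = FALSE)))
  df <- df[order(df$source, df$rank), ]
  write_table(df, path)
}

#' Read a SMILES library
#'
#' One structure per line, `SMILES<tab>id`. Every structure is canonicalized
#' through Open Babel; in strict mode (the default) an unparsable line is an
#' error naming the line number, in lenient mode it is skipped with a
#' warning.
#'
#' @param path path to a SMILES file.
#' @param strict logical; error (TRUE) or skip-with-warning (FALSE) on
#'   unparsable structures.
#' @return A data.frame with columns `id`, `smiles` (as written) and
#'   `canonical` (canonical SMILES).
#' @export
read_smiles <- function(path, strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_format <- vapply(parts, length, integer(1)) < 2
  if (any(bad_format))
    stop("SMILES file line(s) without a tab-separated id: line ",
         paste(which(bad_format), collapse = ", "))
  smi <- vapply(parts, `[[`, character(1), 1)
  id <- vapply(parts, `[[`, character(1), 2)
  canon <- vapply(smi, canonical_smiles, character(1), USE.NAMES = FALSE)
  invalid <- is.na(canon)
  if (any(invalid)) {
    if (strict)
      stop("unparsable SMILES at line ", paste(which(invalid), collapse = ", "),
           ": ", paste(smi[invalid], collapse = ", "))
    warning("skipping ", sum(invalid), " unparsable SMILES line(s): ",
            paste(which(invalid), collapse = ", "))
  }
  data.frame(id = id[!invalid], smiles = smi[!invalid],
             canonical = canon[!invalid], stringsAsFactors = FALSE)
}

#' Write a SMILES library
#'
#' @param compounds a data.frame with columns `smiles` and `id`.
#' @param path output path; lines are `SMILES<tab>id`.
#' @export
write_smiles <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$id, sep = "\t"), path)
}

#' Read signed compound-gene perturbation signatures
#'
#' Expects a TSV with columns `compound`, `gene`, `direction`; direction
#' tokens may be signed integers (+1/-1) or the strings "up"/"down", and are
#' normalized to +1/-1.
#'
#' @param path path to a TSV file.
#' @return A named list (one element per compound, sorted by compound id) of
#'   named direction vectors (+1/-1 per gene).
#' @export
read_signatures <- function(path) {
  df <- read_tsv_checked(path, c("compound", "gene", "direction"))
  df$compound <- as.character(df$compound)
  df$gene <- as.character(df$gene)
  df$direction <- normalize_direction(df$direction)
  dup <- duplicated(df[c("compound", "gene")])
  if (any(dup))
    stop("duplicate (compound, gene) pair(s) in signature file")
  out <- lapply(split(df, df$compound), function(d) {
    stats::setNames(d$direction, d$gene)
  })
  out[order(names(out))]
}

normalize_direction <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  dir <- rep(NA_real_, length(tok))
  dir[tok %in% c("1", "+1", "up")] <- 1
  dir[tok %in% c("-1", "down")] <- -1
  if (anyNA(dir))
    stop("unknown direction token(s): ",
         paste(unique(tok[is.na(dir)]), collapse = ", "),
         " (expected +1/-1 or up/down)")
  dir
}

#' Write perturbation signatures
#'
#' @param signatures a named list of named direction vectors.
#' @param path output TSV path.
#' @export
write_signatures <- function(signatures, path) {
  df <- do.call(rbind, lapply(sort(names(signatures)), function(cp) {
    sig <- signatures[[cp]]
    data.frame(compound = cp, gene = names(sig),
               direction = as.integer(sig), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$compound, df$gene), ]
  write_table(df, path)
}

#' Read a signed gene set
#'
#' Expects a TSV with columns `gene`, `direction` and optionally `log2fc`.
#'
#' @param path path to a TSV file.
#' @return A `signed_gene_set` (see [signed_gene_set()]).
#' @export
read_gene_set <- function(path) {
  df <- read_tsv_checked(path, c("gene", "direction"))
  lfc <- if ("log2fc" %in% names(df)) as.numeric(df$log2fc) else NULL
  signed_gene_set(as.character(df$gene), normalize_direction(df$direction),
                  log2fc = lfc)
}

#' Write a signed gene set
#'
#' @param set a `signed_gene_set`.
#' @param path output TSV path.
#' @export
write_gene_set <- function(set, path) {
  df <- data.frame(gene = names(set$direction),
                   direction = as.integer(set$direction),
                   stringsAsFactors = FALSE)
  if (!is.null(set$log2fc)) df$log2fc <- unname(set$log2fc)
  write_table(df, path)
}

#' Read a cell-line x drug response (IC50) matrix
#'
#' TSV with cell lines as the first column (`cell_line`) and one column per
#' drug; empty cells or `NA` denote missing values. Observed entries must be
#' strictly positive.
#'
#' @param path path to a TSV file.
#' @return A numeric matrix (rows = cell lines, columns = drugs).
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "cell_line")
    stop("response matrix must have 'cell_line' as its first column")
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("response matrix row/column identifiers must be unique")
  if (any(m[!is.na(m)] <= 0))
    stop("observed IC50 entries must be strictly positive")
  m
}

#' Write a response matrix
#'
#' @param m numeric matrix with dimnames; NA entries written empty.
#' @param path output TSV path.
#' @export
write_response_matrix <- function(m, path) {
  df <- data.frame(cell_line = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a multi-frame XYZ-style trajectory
#'
#' Plain-text format: each frame starts with a line holding the particle
#' count, optionally followed by a comment line, then one `id x y z` line
#' per particle (coordinates in nm). The particle count and identifier order
#' must be constant across frames.
#'
#' @param path path to a trajectory text file.
#' @return A `trajectory`: list with `coords` (frames x particles x 3
#'   array), `ids` (particle identifiers).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L; frames <- list(); ids_ref <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("expected a particle-count header at line ", i)
    i <- i + 1L
    # optional comment line (not parseable as "id x y z")
    peek <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(peek) != 4 || anyNA(suppressWarnings(as.numeric(peek[2:4]))))
      i <- i + 1L
    if (i + n - 1L > length(lines))
      stop("truncated frame: expected ", n, " particle lines")
    block <- strsplit(trimws(lines[i:(i + n - 1L)]), "\\s+")
    ids <- vapply(block, `[[`, character(1), 1)
    xyz <- t(vapply(block, function(b) as.numeric(b[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinate in frame starting at line ", i)
    if (is.null(ids_ref)) ids_ref <- ids
    else if (!identical(ids, ids_ref))
      stop("particle identifiers/order differ between frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + n
  }
  coords <- array(NA_real_, dim = c(length(frames), length(ids_ref), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  structure(list(coords = coords, ids = ids_ref), class = "trajectory")
}

#' Write a trajectory in multi-frame XYZ-style text
#'
#' @param traj a `trajectory` object.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  n <- length(traj$ids)
  out <- character(0)
  for (f in seq_len(dim(traj$coords)[1])) {
    xyz <- traj$coords[f, , , drop = TRUE]
    if (n == 1) xyz <- matrix(xyz, nrow = 1)
    out <- c(out, as.character(n),
             sprintf("%s %.9g %.9g %.9g", traj$ids, xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  writeLines(out, path)
}

#' Write a SIF-style edge list for the bipartite compound-gene network
#'
#' One line per edge: `compound<tab>mimic|reverse<tab>gene`.
#'
#' @param edges a data.frame with columns `compound`, `relation`, `gene`
#'   (as produced by [build_bipartite()]).
#' @param path output path.
#' @export
write_sif <- function(edges, path) {
  edges <- edges[order(edges$compound, edges$gene), ]
  writeLines(paste(edges$compound, edges$relation, edges$gene, sep = "\t"),
             path)
}

#' Write a data.frame as a deterministic TSV
#'
#' Column order is preserved as given; rows are written in their current
#' order; no quoting, no row names. Identical inputs give byte-identical
#' files.
#'
#' @param df a data.frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}
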
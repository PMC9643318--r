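# run expr with an explicit Mersenne-Twister stream, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Specification for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators that emulate the pipeline's
#' inputs: a DEG table with a planted differential fraction, K
#' partially-overlapping ranked drug lists over a latent efficacy ordering,
#' compound perturbation signatures with controlled reversal strength,
#' IC50 matrices with planted sensitive drugs and missing-at-random
#' entries, and particle trajectories with planted correlated /
#' anti-correlated blocks.
#'
#' @param n_genes number of genes in the DEG table.
#' @param frac_de fraction of genes planted as differential.
#' @param lfc_effect minimum |log2FC| of planted differential genes.
#' @param n_sources number of ranked-list sources (K).
#' @param n_drugs size of the drug universe the sources draw from.
#' @param drugs_per_source length of each source's ranked list.
#' @param source_overlap fraction of each list shared across all sources.
#' @param rank_noise_sd sd (in latent-score units, i.e. rank positions) of
#'   the noise each source adds before ranking.
#' @param n_compounds number of perturbation-signature compounds.
#' @param reversal_strength per-compound probability that a shared gene
#'   opposes the disease direction: a scalar, a vector of length
#'   `n_compounds`, or NULL to draw uniformly from \[0.2, 0.95\].
#' @param n_shared_genes disease genes included in each signature.
#' @param n_distractor_genes off-disease genes included as distractors.
#' @param n_cell_lines,n_response_drugs response-matrix dimensions.
#' @param n_sensitive number of planted sensitive drugs.
#' @param na_fraction fraction of response entries missing at random.
#' @param n_overmissing number of drugs planted with > 20% missingness.
#' @param n_frames,n_particles trajectory dimensions.
#' @param block_spec list of `list(particles=, direction=)` blocks
#'   (direction +1/-1); NULL = two equal anti-phase blocks.
#' @param traj_amplitude amplitude (nm) of the collective motion.
#' @param noise_sd isotropic coordinate noise sd (nm).
#' @param seed integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 2000, frac_de = 0.1, lfc_effect = 2,
                            n_sources = 3, n_drugs = 150,
                            drugs_per_source = 50, source_overlap = 0.6,
                            rank_noise_sd = 2,
                            n_compounds = 20, reversal_strength = NULL,
                            n_shared_genes = 50, n_distractor_genes = 20,
                            n_cell_lines = 100, n_response_drugs = 30,
                            n_sensitive = 5, na_fraction = 0.05,
                            n_overmissing = 0,
                            n_frames = 100, n_particles = 20,
                            block_spec = NULL, traj_amplitude = 0.5,
                            noise_sd = 0.05, seed = 1) {
  spec <- as.list(environment())
  for (f in c("frac_de", "source_overlap", "na_fraction")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("spec field '", f, "' must lie in [0, 1]")
  }
  for (f in c("n_genes", "n_sources", "n_drugs", "drugs_per_source",
              "n_compounds", "n_shared_genes", "n_cell_lines",
              "n_response_drugs", "n_frames", "n_particles")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 1) stop("spec field '", f, "' must be >= 1")
    spec[[f]] <- as.integer(v)
  }
  if (spec$drugs_per_source > spec$n_drugs)
    stop("drugs_per_source cannot exceed n_drugs")
  if (spec$n_sensitive > spec$n_response_drugs)
    stop("n_sensitive cannot exceed n_response_drugs")
  if (!is.null(reversal_strength)) {
    rs <- reversal_strength
    if (!length(rs) %in% c(1L, spec$n_compounds))
      stop("reversal_strength must be scalar or length n_compounds")
    if (any(rs < 0 | rs > 1)) stop("reversal_strength must lie in [0, 1]")
  }
  spec$seed <- as.integer(seed)
  structure(spec, class = "simulation_spec")
}

pad_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate a DEG table with a planted differential fraction
#'
#' Planted genes draw |log2FC| at or above `lfc_effect` and an adjusted p
#' well below 0.05; non-planted genes draw adjusted p uniformly on
#' \[0.05, 1\] (and small fold-changes), so the study filter recovers the
#' planted truth set exactly.
#'
#' @param spec a `simulation_spec`.
#' @return A list: `table` (DEG data.frame) and `truth` (sorted planted
#'   gene ids).
#' @export
gen_deg_table <- function(spec) {
  n <- spec$n_genes
  n_de <- round(spec$frac_de * n)
  genes <- pad_ids("g", n)
  with_seed(spec$seed + 101L, {
    planted <- sort(sample(genes, n_de))
    lfc <- stats::rnorm(n, 0, 0.3)
    adj_p <- stats::runif(n, 0.05, 1)
    if (n_de > 0) {
      idx <- match(planted, genes)
      lfc[idx] <- (spec$lfc_effect + stats::rexp(n_de, rate = 2)) *
        sample(c(-1, 1), n_de, replace = TRUE)
      adj_p[idx] <- 0.05 * stats::runif(n_de) * stats::runif(n_de)
    }
    list(table = data.frame(gene = genes, log2fc = lfc, adj_p = adj_p,
                            stringsAsFactors = FALSE),
         truth = planted)
  })
}

#' Generate partially-overlapping ranked drug lists
#'
#' A latent "true efficacy" ordering over the drug universe is drawn; each
#' source ranks a subsample (a core shared by all sources plus its own
#' extras) by the latent score plus Gaussian noise.
#'
#' @param spec a `simulation_spec`.
#' @return A list: `rankings` (list of `source_ranking`) and `truth` (the
#'   latent drug ordering, best first).
#' @export
gen_rankings <- function(spec) {
  drugs <- pad_ids("d", spec$n_drugs)
  m <- spec$drugs_per_source
  with_seed(spec$seed + 202L, {
    truth <- sample(drugs)                       # best first
    latent <- stats::setNames(rev(seq_along(truth)), truth)
    core_size <- round(spec$source_overlap * m)
    core <- truth[seq_len(core_size)]            # overlap on the head of the
                                                 # latent order, as real
                                                 # reversal screens agree most
                                                 # on their top hits
    rankings <- lapply(seq_len(spec$n_sources), function(s) {
      pool <- setdiff(drugs, core)
      extras <- sample(pool, m - core_size)
      members <- c(core, extras)
      noisy <- latent[members] + stats::rnorm(m, 0, spec$rank_noise_sd)
      ordered <- members[order(-noisy, members)]
      source_ranking(sprintf("source%02d", s), ordered)
    })
    names(rankings) <- vapply(rankings, `[[`, character(1), "source")
    list(rankings = rankings, truth = truth)
  })
}

#' Generate compound perturbation signatures with planted reversers
#'
#' Each compound regulates a shared subset of the disease genes, opposing
#' the disease direction independently per gene with its recorded
#' reversal strength, plus off-disease distractor genes with random
#' directions.
#'
#' @param spec a `simulation_spec`.
#' @param disease a `signed_gene_set` (the disease signature).
#' @return A list: `signatures` (named list of +1/-1 vectors) and `truth`
#'   (named per-compound reversal strengths).
#' @export
gen_signatures <- function(spec, disease) {
  if (length(disease$direction) == 0) stop("disease set must be non-empty")
  compounds <- pad_ids("c", spec$n_compounds)
  n_shared <- min(spec$n_shared_genes, length(disease$direction))
  with_seed(spec$seed + 303L, {
    rho <- spec$reversal_strength
    if (is.null(rho)) rho <- stats::runif(spec$n_compounds, 0.2, 0.95)
    rho <- stats::setNames(rep_len(rho, spec$n_compounds), compounds)
    distractor_pool <- setdiff(pad_ids("x", spec$n_distractor_genes * 4),
                               names(disease$direction))
    signatures <- lapply(compounds, function(cp) {
      shared <- sample(names(disease$direction), n_shared)
      flip <- stats::runif(n_shared) < rho[cp]
      dir_shared <- ifelse(flip, -disease$direction[shared],
                           disease$direction[shared])
      distract <- sample(distractor_pool, spec$n_distractor_genes)
      dir_distract <- sample(c(-1, 1), spec$n_distractor_genes,
                             replace = TRUE)
      stats::setNames(c(dir_shared, dir_distract), c(shared, distract))
    })
    names(signatures) <- compounds
    list(signatures = signatures, truth = rho)
  })
}

smiles_grammar <- function() {
  list(
    chains = c("CCCCCC", "CCCCCCCC", "CCCCCCCCCC", "CCCCCCCCNC(=O)C",
               "CCCCCCCCCCNC(=O)C", "CCCCCCOC(=O)C"),
    rings = c("c1ccc(%s)cc1", "C1CCC(%s)CC1", "c1ccc(%s)nc1"),
    subs = c("OC", "OCC", "OCCC", "C#N", "Cl", "F", "C(=O)O", "N(C)C"),
    tails = c("OC", "OCC", "OCCC", "CC", "CCC", "")
  )
}

#' Generate a SMILES library from a packaged fragment grammar
#'
#' Structures are enumerated from a small grammar of alkyl/amide chains,
#' rings and common substituents — no external catalogue is consulted.
#' Deliberate near-duplicate pairs (same scaffold, one terminal tail
#' extended by a single carbon) are planted and recorded as truth; such
#' pairs sit above the 80% Tanimoto redundancy threshold while unrelated
#' scaffolds fall well below it.
#'
#' @param n number of compounds (>= 1).
#' @param seed integer seed.
#' @param n_pairs number of planted near-duplicate pairs (default
#'   `max(1, n %/% 6)`, capped at `n %/% 2`).
#' @return A list: `compounds` (data.frame `id`, `smiles`, `canonical`)
#'   and `pairs` (data.frame `id_a`, `id_b` of planted near-duplicates).
#' @export
gen_smiles_library <- function(n, seed = 1, n_pairs = NULL) {
  if (n < 1) stop("n must be >= 1")
  g <- smiles_grammar()
  if (is.null(n_pairs)) n_pairs <- max(if (n >= 2) 1 else 0, n %/% 6)
  n_pairs <- min(n_pairs, n %/% 2)
  with_seed(seed + 404L, {
    seen <- character(0)
    # bases destined for a near-duplicate pair draw a tail long enough that
    # one extra carbon perturbs only a few fingerprint bits (pair Tanimoto
    # stays above the 0.8 redundancy threshold)
    draw_base <- function(pairable = FALSE) {
      for (attempt in 1:100) {
        chain <- sample(g$chains, 1)
        ring <- sample(g$rings, 1)
        sub <- sample(g$subs, 1)
        tail <- if (pairable) sample(c("CCC", "OCCC"), 1)
                else sample(g$tails, 1)
        smi <- paste0(chain, sprintf(ring, sub), tail)
        can <- canonical_smiles(smi)
        if (!is.na(can) && !(can %in% seen)) {
          seen <<- c(seen, can)
          return(list(smiles = smi, canonical = can,
                      chain = chain, ring = ring, sub = sub, tail = tail))
        }
      }
      stop("could not draw a fresh structure from the grammar")
    }
    extend_tail <- function(base) {
      smi <- paste0(base$chain, sprintf(base$ring, base$sub),
                    paste0(base$tail, "C"))
      can <- canonical_smiles(smi)
      if (is.na(can) || can %in% seen) return(NULL)
      seen <<- c(seen, can)
      list(smiles = smi, canonical = can)
    }
    out <- list(); pairs <- list()
    while (length(out) < n) {
      want_pair <- length(pairs) < n_pairs && length(out) < n - 1L
      base <- draw_base(pairable = want_pair)
      out[[length(out) + 1L]] <- base[c("smiles", "canonical")]
      if (want_pair) {
        twin <- extend_tail(base)
        if (!is.null(twin)) {
          out[[length(out) + 1L]] <- twin
          pairs[[length(pairs) + 1L]] <- c(length(out) - 1L, length(out))
        }
      }
    }
    ids <- pad_ids("cmp", n)
    compounds <- data.frame(
      id = ids,
      smiles = vapply(out, `[[`, character(1), "smiles"),
      canonical = vapply(out, `[[`, character(1), "canonical"),
      stringsAsFactors = FALSE)
    pairs_df <- if (length(pairs) == 0)
      data.frame(id_a = character(0), id_b = character(0))
    else data.frame(id_a = ids[vapply(pairs, `[`, integer(1), 1)],
                    id_b = ids[vapply(pairs, `[`, integer(1), 2)],
                    stringsAsFactors = FALSE)
    list(compounds = compounds, pairs = pairs_df)
  })
}

#' Generate an IC50 response matrix with planted sensitive drugs
#'
#' Planted sensitive drugs have IC50 below 10 uM in every cell line;
#' all other drugs sit above it. Entries are removed completely at random
#' at `na_fraction`, and `n_overmissing` additional drugs are planted with
#' missingness above the 20% discard threshold.
#'
#' @param spec a `simulation_spec`.
#' @param screen label recorded as a `screen` attribute.
#' @return A list: `matrix` (cell lines x drugs, NAs for missing),
#'   `truth_sensitive` (sorted planted sensitive drug ids) and
#'   `truth_overmissing` (drugs planted above the missingness threshold).
#' @export
gen_response_matrix <- function(spec, screen = "screen1") {
  nl <- spec$n_cell_lines
  nd <- spec$n_response_drugs + spec$n_overmissing
  lines <- pad_ids("L", nl)
  drugs <- pad_ids("drug", nd)
  with_seed(spec$seed + 505L + utf8ToInt(substr(screen, nchar(screen),
                                                nchar(screen))), {
    sensitive <- sort(sample(drugs[seq_len(spec$n_response_drugs)],
                             spec$n_sensitive))
    m <- matrix(stats::runif(nl * nd, 12, 80), nl, nd,
                dimnames = list(lines, drugs))
    m[, sensitive] <- stats::runif(nl * length(sensitive), 0.5, 9.5)
    if (spec$na_fraction > 0) {
      mask <- stats::runif(nl * nd) < spec$na_fraction
      m[mask] <- NA
      # keep every line informative
      for (i in which(rowSums(!is.na(m)) == 0))
        m[i, sample(nd, 1)] <- stats::runif(1, 12, 80)
    }
    overmissing <- character(0)
    if (spec$n_overmissing > 0) {
      overmissing <- drugs[spec$n_response_drugs + seq_len(spec$n_overmissing)]
      for (d in overmissing) {
        frac <- stats::runif(1, 0.25, 0.5)
        m[sample(nl, ceiling(frac * nl)), d] <- NA
      }
    }
    attr(m, "screen") <- screen
    list(matrix = m, truth_sensitive = sensitive,
         truth_overmissing = overmissing)
  })
}

#' Generate a trajectory with planted correlated blocks
#'
#' Particles in the same block move coherently along x with a shared
#' sinusoidal collective coordinate, multiplied by the block's direction
#' (+1/-1), plus isotropic Gaussian noise. Blocks with opposite direction
#' are anti-correlated by construction.
#'
#' @param spec a `simulation_spec`.
#' @return A list: `trajectory` (a `trajectory` object) and `truth` (the
#'   block specification used).
#' @export
gen_trajectory <- function(spec) {
  np <- spec$n_particles; nf <- spec$n_frames
  blocks <- spec$block_spec
  if (is.null(blocks)) {
    half <- np %/% 2
    blocks <- list(list(particles = seq_len(half), direction = 1),
                   list(particles = seq(half + 1, np), direction = -1))
  }
  dir <- numeric(np)
  for (b in blocks) dir[b$particles] <- b$direction
  with_seed(spec$seed + 606L, {
    base <- matrix(stats::runif(np * 3, 0, 3), np, 3)
    s <- spec$traj_amplitude * sin(2 * pi * 3 * (seq_len(nf) - 1) / nf)
    coords <- array(NA_real_, dim = c(nf, np, 3))
    for (f in seq_len(nf)) {
      disp <- cbind(dir * s[f], 0, 0)
      coords[f, , ] <- base + disp +
        matrix(stats::rnorm(np * 3, 0, spec$noise_sd), np, 3)
    }
    traj <- structure(list(coords = coords, ids = pad_ids("p", np)),
                      class = "trajectory")
    list(trajectory = traj, truth = blocks)
  })
}

#' Write a complete synthetic toy workspace
#'
#' Generates every pipeline input (DEG table, ranked lists, signatures,
#' SMILES library, two response screens, trajectory) plus machine-readable
#' ground-truth files, in the exact formats the readers consume.
#'
#' @param spec a `simulation_spec`.
#' @param dir output directory (created if absent).
#' @return Invisibly, a named list of the paths written.
#' @export
simulate_workspace <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  deg <- gen_deg_table(spec)
  write_deg_table(deg$table, p("deg.tsv"))
  rk <- gen_rankings(spec)
  write_rankings(rk$rankings, p("rankings.tsv"))
  disease <- filter_degs(deg$table)
  write_gene_set(disease, p("disease_set.tsv"))
  sig <- gen_signatures(spec, disease)
  write_signatures(sig$signatures, p("signatures.tsv"))
  lib <- gen_smiles_library(spec$n_compounds, seed = spec$seed)
  write_smiles(lib$compounds, p("compounds.smi"))
  r1 <- gen_response_matrix(spec, "screen1")
  r2 <- gen_response_matrix(spec, "screen2")
  write_response_matrix(r1$matrix, p("response_screen1.tsv"))
  write_response_matrix(r2$matrix, p("response_screen2.tsv"))
  tr <- gen_trajectory(spec)
  write_trajectory(tr$trajectory, p("trajectory.xyz"))
  truth <- list(deg = deg$truth, ranking = rk$truth,
                reversal_strength = as.list(sig$truth),
                near_duplicate_pairs = lib$pairs,
                sensitive_screen1 = r1$truth_sensitive,
                sensitive_screen2 = r2$truth_sensitive)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stats::setNames(
    as.list(p(c("deg.tsv", "rankings.tsv", "disease_set.tsv",
                "signatures.tsv", "compounds.smi", "response_screen1.tsv",
                "response_screen2.tsv", "trajectory.xyz", "truth.json"))),
    c("deg", "rankings", "disease_set", "signatures", "smiles",
      "response_screen1", "response_screen2", "trajectory", "truth")))
}
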
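#' Pipeline configuration
#'
#' A `pipeline_config` is a named list of every tunable constant used by the
#' pipeline stages, validated against a small set of invariants. The defaults
#' are the study conditions: adjusted p < 0.05 and |log2FC| > 1 for the
#' differential-expression filter, a Pearson r > 0.3 significance screen for
#' cell-type association, a 50-drug cutoff per signature-reversal source,
#' composite-score weights (waS, wFS, wStS) = (0.45, 0.45, 0.1), Ward
#' clustering at a minimum Tanimoto similarity of 80%, network-score weights
#' omega_bm = 0.3 and omega_m2 = 0.7, a 20% missingness cap and 10 uM
#' sensitivity threshold for drug-response screens, and 298.15 K for the
#' binding-constant conversion.
#'
#' @param ... named overrides of the default values (see
#'   [default_config()] for the full key list).
#' @return A validated `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(rank_cutoff = 25)
#' cfg$codres_weights
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0)
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

#' Default pipeline configuration values
#'
#' @return A named list of defaults (not yet validated; see
#'   [pipeline_config()]).
#' @export
default_config <- function() {
  list(
    deg_p_threshold         = 0.05,
    deg_lfc_threshold       = 1.0,
    corr_threshold          = 0.3,
    corr_p_threshold        = 0.05,
    rank_cutoff             = 50L,
    codres_weights          = c(waS = 0.45, wFS = 0.45, wStS = 0.1),
    tanimoto_min_similarity = 0.80,
    fingerprint_length      = 2048L,
    omega_bm                = 0.3,
    omega_m2                = 0.7,
    na_max_fraction         = 0.20,
    ic50_sensitive_um       = 10.0,
    knn_k                   = 5L,
    temperature_k           = 298.15,
    random_seed             = 1L
  )
}

#' Load a pipeline configuration from a flat JSON file
#'
#' The file must be a flat JSON object; keys absent from the file keep their
#' defaults and unknown keys are an error (this guards against silently
#' ignored typos). `codres_weights` may be given as an array of three
#' numbers (waS, wFS, wStS).
#'
#' @param path path to a JSON configuration file.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop("failed to parse configuration JSON '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0) return(pipeline_config())
  if (!is.list(raw) || is.null(names(raw)))
    stop("configuration must be a flat JSON object of key/value pairs")
  if (any(vapply(raw, function(x) is.list(x), logical(1))))
    stop("configuration must be flat: nested objects are not allowed")
  if ("codres_weights" %in% names(raw)) {
    w <- as.numeric(raw$codres_weights)
    if (length(w) != 3)
      stop("validation error for key 'codres_weights': expected 3 numbers")
    raw$codres_weights <- c(waS = w[1], wFS = w[2], wStS = w[3])
  }
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  num1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("validation error for key '", key, "': must be a single finite number")
    v
  }
  for (key in c("deg_p_threshold", "deg_lfc_threshold", "corr_threshold",
                "corr_p_threshold", "rank_cutoff", "fingerprint_length",
                "na_max_fraction", "ic50_sensitive_um", "knn_k",
                "temperature_k")) {
    if (num1(key) <= 0)
      stop("validation error for key '", key, "': must be strictly positive")
  }
  w <- cfg$codres_weights
  if (!is.numeric(w) || length(w) != 3)
    stop("validation error for key 'codres_weights': expected 3 numbers")
  if (any(w < 0))
    stop("validation error for key 'codres_weights': weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9)
    stop("validation error for key 'codres_weights': weights must sum to 1")
  ob <- num1("omega_bm"); om <- num1("omega_m2")
  if (ob < 0 || om < 0)
    stop("validation error for key 'omega_bm'/'omega_m2': must be >= 0")
  if (abs(ob + om - 1) > 1e-9)
    stop("validation error for key 'omega_bm': omega_bm + omega_m2 must equal 1")
  ts <- num1("tanimoto_min_similarity")
  if (ts <= 0 || ts >= 1)
    stop("validation error for key 'tanimoto_min_similarity': must lie in (0,1)")
  cfg$rank_cutoff <- as.integer(cfg$rank_cutoff)
  cfg$fingerprint_length <- as.integer(cfg$fingerprint_length)
  cfg$knn_k <- as.integer(cfg$knn_k)
  cfg$random_seed <- as.integer(cfg$random_seed)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (key in names(x)) {
    v <- x[[key]]
    cat(sprintf("  %-24s %s\n", key, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
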
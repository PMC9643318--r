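#' Drop drugs with excessive missingness
#'
#' Removes a drug (column) iff its fraction of missing cell-line entries
#' strictly exceeds `max_na_frac` (study rule: more than 20% missing).
#' Column order of the survivors is preserved.
#'
#' @param m a cell-line x drug IC50 matrix (NA = missing).
#' @param max_na_frac maximum tolerated missing fraction (default 0.20).
#' @return The matrix restricted to surviving drugs.
#' @export
drop_missing_drugs <- function(m, max_na_frac = 0.20) {
  na_frac <- colMeans(is.na(m))
  m[, na_frac <= max_na_frac, drop = FALSE]
}

#' K-nearest-neighbour imputation of a response matrix
#'
#' Fills each missing (cell line, drug) entry with the unweighted mean of
#' that drug's values among the k nearest cell lines. Distances between
#' lines are root-mean-square differences over their jointly observed
#' drugs, after scaling each drug by its observed mean; neighbour ties are
#' broken by line id. Neighbours lacking the drug are skipped when
#' averaging (widening past k if none of the k observe it). Imputed values
#' are clamped to the drug's observed range.
#'
#' @param m a cell-line x drug IC50 matrix, already filtered by
#'   [drop_missing_drugs()]; every row needs at least one observed entry.
#' @param k neighbourhood size (default 5).
#' @return The completed matrix.
#' @export
knn_impute <- function(m, k = 5) {
  if (!any(is.na(m))) return(m)
  if (any(rowSums(!is.na(m)) == 0))
    stop("cell line(s) with no observed entry: ",
         paste(rownames(m)[rowSums(!is.na(m)) == 0], collapse = ", "))
  empty_cols <- colSums(!is.na(m)) == 0
  if (any(empty_cols))
    stop("no cell line observes drug(s): ",
         paste(colnames(m)[empty_cols], collapse = ", "))
  col_mean <- colMeans(m, na.rm = TRUE)
  scaled <- sweep(m, 2, col_mean, "/")
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  # pairwise RMS distance over jointly observed drugs
  dist_rows <- function(i) {
    di <- scaled[rep(i, n), , drop = FALSE] - scaled
    joint <- !is.na(di)
    d <- sqrt(rowSums(di^2, na.rm = TRUE) / pmax(rowSums(joint), 1))
    d[rowSums(joint) == 0] <- Inf
    d
  }
  out <- m
  for (i in which(rowSums(is.na(m)) > 0)) {
    d <- dist_rows(i)
    ord <- order(d[-i], ids[-i])
    neighbours <- seq_len(n)[-i][ord]
    for (j in which(is.na(m[i, ]))) {
      observers <- neighbours[!is.na(m[neighbours, j])]
      take <- utils::head(intersect(utils::head(neighbours, k), observers), k)
      if (length(take) == 0) take <- utils::head(observers, k)
      val <- mean(m[take, j])
      rng <- range(m[, j], na.rm = TRUE)
      out[i, j] <- min(max(val, rng[1]), rng[2])
    }
  }
  out
}

#' Ridge regression with unpenalized intercept
#'
#' Solves `min ||y - b0 - X beta||^2 + lambda ||beta||^2` in closed form
#' via the SVD of the centered design. When `lambda` is NULL it is chosen
#' by leave-one-out generalized cross-validation over a fixed log-spaced
#' grid. A constant response yields an intercept-only model.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response vector.
#' @param lambda ridge penalty (>= 0), or NULL for GCV selection.
#' @param lambda_grid grid searched when `lambda` is NULL.
#' @return A `ridge_fit`: list with `intercept`, `coefficients` (named by
#'   feature), `lambda`, `gcv` (the GCV curve when selected).
#' @export
ridge_fit <- function(X, y, lambda = NULL,
                      lambda_grid = 10^seq(-4, 4, length.out = 33)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < 2) stop("at least 2 training samples are required")
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  feat <- colnames(X)
  if (is.null(feat)) feat <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  xbar <- colMeans(X); ybar <- mean(y)
  if (stats::sd(y) == 0) {
    fit <- list(intercept = ybar,
                coefficients = stats::setNames(numeric(ncol(X)), feat),
                lambda = if (is.null(lambda)) NA_real_ else lambda,
                gcv = NULL)
    class(fit) <- "ridge_fit"
    return(fit)
  }
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  sv <- svd(Xc)
  uty <- crossprod(sv$u, yc)
  beta_at <- function(lam) {
    shrink <- sv$d / (sv$d^2 + lam)
    shrink[sv$d < 1e-12] <- 0
    drop(sv$v %*% (shrink * uty))
  }
  gcv <- NULL
  if (is.null(lambda)) {
    gcv <- vapply(lambda_grid, function(lam) {
      shrink <- sv$d^2 / (sv$d^2 + lam)
      shrink[sv$d < 1e-12] <- 0
      fitted <- drop(sv$u %*% (shrink * uty))
      df <- sum(shrink) + 1          # +1 for the unpenalized intercept
      rss <- sum((yc - fitted)^2)
      n * rss / (n - df)^2
    }, numeric(1))
    lambda <- lambda_grid[which.min(gcv)]
    gcv <- stats::setNames(gcv, format(lambda_grid))
  }
  beta <- beta_at(lambda)
  fit <- list(intercept = ybar - sum(xbar * beta),
              coefficients = stats::setNames(beta, feat),
              lambda = lambda, gcv = gcv)
  class(fit) <- "ridge_fit"
  fit
}

#' Predict from a ridge fit
#'
#' @param object a `ridge_fit`.
#' @param newdata numeric matrix, samples x features (same feature order
#'   as the training design).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " features; fit expects ",
         length(object$coefficients))
  drop(object$intercept + newdata %*% object$coefficients)
}

#' Predict drug sensitivity from expression
#'
#' The expression-to-response contract of the sensitivity stage: a ridge
#' model is trained per drug on cell-line expression against the natural
#' log of IC50 (GCV-selected penalty), and predictions are back-transformed
#' to the micromolar scale.
#'
#' @param expr_train genes x training-samples expression matrix.
#' @param ic50_train numeric vector of training IC50s (uM), parallel to
#'   the training samples; must be positive.
#' @param expr_new genes x new-samples expression matrix (same gene order).
#' @param lambda optional fixed penalty (NULL = GCV).
#' @return Numeric vector of predicted IC50s (uM) for the new samples.
#' @export
predict_sensitivity <- function(expr_train, ic50_train, expr_new,
                                lambda = NULL) {
  if (any(ic50_train <= 0)) stop("IC50 values must be strictly positive")
  fit <- ridge_fit(t(expr_train), log(ic50_train), lambda = lambda)
  exp(predict(fit, t(expr_new)))
}

#' Screen for sensitive drugs with cross-screen co-occurrence
#'
#' Per screen, a drug qualifies iff its mean predicted IC50 over the
#' bone-metastasis samples is strictly below the threshold (study rule:
#' IC50 < 10 uM); the final set is the intersection across screens (a drug
#' must replicate in both GDSC-style screens).
#'
#' @param predictions a named list (one element per screen) of
#'   samples x drugs matrices of predicted IC50 (uM) for the BM group.
#' @param threshold_um sensitivity threshold in uM (default 10).
#' @return Sorted character vector of co-occurring sensitive drugs, with a
#'   `per_screen` attribute listing each screen's qualifying set.
#' @export
sensitive_drugs <- function(predictions, threshold_um = 10) {
  if (length(predictions) < 2)
    stop("at least two screens are required for co-occurrence")
  per_screen <- lapply(predictions, function(p) {
    means <- colMeans(as.matrix(p))
    sort(names(means)[means < threshold_um])
  })
  out <- sort(Reduce(intersect, per_screen))
  attr(out, "per_screen") <- per_screen
  out
}

#' Compare predicted responses between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the predicted IC50s of two sample
#' groups (e.g. bone metastases vs primary tumours).
#'
#' @param values_a,values_b numeric vectors (>= 3 values each).
#' @return A list with `statistic` (W) and `p`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("at least 3 values per group are required")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
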
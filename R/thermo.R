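# gas constant in kcal / (mol K)
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Inhibition constant from a docking binding energy
#'
#' `Ki = exp(delta_g / (R T))` with R = 1.9872e-3 kcal/(mol K): a binding
#' energy of 0 gives Ki = 1 M, and more negative energies give tighter
#' (smaller) constants.
#'
#' @param delta_g binding free energy in kcal/mol (vectorized).
#' @param temperature_k absolute temperature in kelvin (default 298.15).
#' @return Ki in molar units.
#' @export
ki_from_energy <- function(delta_g, temperature_k = 298.15) {
  if (any(!is.finite(delta_g))) stop("delta_g must be finite")
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0))
    stop("temperature must be finite and > 0")
  exp(delta_g / (GAS_CONSTANT_KCAL * temperature_k))
}

#' Inhibition constant in nanomolar
#'
#' @inheritParams ki_from_energy
#' @return Ki in nM.
#' @export
ki_nm <- function(delta_g, temperature_k = 298.15) {
  ki_from_energy(delta_g, temperature_k) * 1e9
}

#' Annotate a docking table with inhibition constants
#'
#' @param df a data.frame with columns `target`, `compound`, `delta_g`
#'   (kcal/mol).
#' @param temperature_k temperature in kelvin.
#' @return The data.frame with a `ki_nM` column appended.
#' @export
binding_constants <- function(df, temperature_k = 298.15) {
  for (col in c("target", "compound", "delta_g"))
    if (!col %in% names(df)) stop("missing column: ", col)
  df$ki_nM <- ki_nm(df$delta_g, temperature_k)
  df
}

traj_coords <- function(t) {
  if (inherits(t, "trajectory")) t$coords
  else if (is.array(t) && length(dim(t)) == 3) t
  else stop("expected a trajectory or a frames x particles x 3 array")
}

#' Dynamic cross-correlation matrix of a trajectory
#'
#' The normalized covariance of particle displacements about their time
#' means: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, averaging
#' over frames (equally weighted, scalar-product convention). Correlated
#' motion gives entries near +1, anti-correlated motion near -1.
#'
#' @param t a `trajectory` (or frames x particles x 3 array), >= 2 frames.
#' @return A particles x particles correlation matrix with unit diagonal.
#' @export
dccm <- function(t) {
  x <- traj_coords(t)
  nf <- dim(x)[1]; np <- dim(x)[2]
  if (nf < 2) stop("at least 2 frames are required")
  centered <- sweep(x, c(2, 3), apply(x, c(2, 3), mean))
  # cross-covariance: sum over the three coordinates of per-axis covariances
  cov <- matrix(0, np, np)
  for (a in 1:3) cov <- cov + crossprod(centered[, , a]) / nf
  v <- diag(cov)
  zero <- v <= 0
  if (any(zero)) {
    ids <- if (inherits(t, "trajectory")) t$ids[zero] else which(zero)
    stop("zero-variance particle(s): ", paste(ids, collapse = ", "))
  }
  cc <- cov / sqrt(outer(v, v))
  diag(cc) <- 1
  if (inherits(t, "trajectory")) dimnames(cc) <- list(t$ids, t$ids)
  cc
}

#' Root-mean-square deviation between two frames
#'
#' `sqrt(mean_i |r_i - r_ref,i|^2)`; no superposition is performed, the
#' frames are assumed pre-aligned.
#'
#' @param frame,reference particles x 3 coordinate matrices (nm).
#' @return RMSD in nm.
#' @export
rmsd <- function(frame, reference) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  if (!all(dim(frame) == dim(reference)))
    stop("frame and reference particle counts differ")
  sqrt(mean(rowSums((frame - reference)^2)))
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' @param t a `trajectory`.
#' @param reference particles x 3 reference frame; defaults to the first
#'   frame.
#' @return Numeric vector, one RMSD (nm) per frame.
#' @export
rmsd_profile <- function(t, reference = NULL) {
  x <- traj_coords(t)
  if (is.null(reference)) reference <- x[1, , ]
  vapply(seq_len(dim(x)[1]), function(f) rmsd(x[f, , ], reference),
         numeric(1))
}

#' Per-particle root-mean-square fluctuation
#'
#' `rmsf_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` about the time-mean
#' position.
#'
#' @param t a `trajectory` (>= 2 frames).
#' @return Named numeric vector, one fluctuation (nm) per particle.
#' @export
rmsf <- function(t) {
  x <- traj_coords(t)
  if (dim(x)[1] < 2) stop("at least 2 frames are required")
  centered <- sweep(x, c(2, 3), apply(x, c(2, 3), mean))
  out <- sqrt(colMeans(centered[, , 1]^2 + centered[, , 2]^2 +
                       centered[, , 3]^2))
  if (inherits(t, "trajectory")) names(out) <- t$ids
  out
}

#' Radius of gyration of one frame
#'
#' `Rg = sqrt(sum_i m_i |r_i - r_com|^2 / sum_i m_i)` with uniform masses
#' by default.
#'
#' @param frame particles x 3 coordinate matrix (nm).
#' @param masses optional positive per-particle masses.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n) stop("masses must match the particle count")
  if (any(masses <= 0)) stop("masses must be positive")
  w <- masses / sum(masses)
  com <- colSums(frame * w)
  sqrt(sum(w * rowSums(sweep(frame, 2, com)^2)))
}

#' Per-frame radius of gyration of a trajectory
#'
#' @param t a `trajectory`.
#' @param masses optional per-particle masses.
#' @return Numeric vector, one Rg (nm) per frame.
#' @export
rg_profile <- function(t, masses = NULL) {
  x <- traj_coords(t)
  vapply(seq_len(dim(x)[1]),
         function(f) radius_of_gyration(x[f, , ], masses), numeric(1))
}
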
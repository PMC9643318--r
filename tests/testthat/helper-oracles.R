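# Independent oracles used to cross-check the implementation. Each one
# recomputes its quantity from the definition, by brute force, without
# calling the code path it checks.

# Agglomerative Ward clustering from the definition: Lance-Williams update
# on squared distances, merge the pair with the smallest criterion at every
# step, merge height = sqrt of the criterion. Stops at the cut height and
# returns the flat partition.
ward_oracle_partition <- function(sim, h_cut) {
  n <- nrow(sim)
  D2 <- (1 - sim)^2
  diag(D2) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    bestv <- Inf; bi <- bj <- NA
    for (a in idx) for (b in idx) if (a < b && D2[a, b] < bestv) {
      bestv <- D2[a, b]; bi <- a; bj <- b
    }
    if (sqrt(bestv) > h_cut) break
    for (k in idx) if (k != bi && k != bj) {
      D2[bi, k] <- D2[k, bi] <-
        ((sizes[bi] + sizes[k]) * D2[bi, k] +
         (sizes[bj] + sizes[k]) * D2[bj, k] -
         sizes[k] * D2[bi, bj]) / (sizes[bi] + sizes[bj] + sizes[k])
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    active[bj] <- FALSE
  }
  out <- integer(n)
  cl <- 0L
  for (a in which(active)) { cl <- cl + 1L; out[members[[a]]] <- cl }
  out
}

# two labelings describe the same partition iff co-membership matrices agree
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# random symmetric similarity matrix with unit diagonal
random_sim_matrix <- function(n) {
  s <- matrix(stats::runif(n * n), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  rownames(s) <- colnames(s) <- sprintf("m%02d", seq_len(n))
  s
}

# DCC matrix by the definition, double loop over particle pairs
dccm_oracle <- function(coords) {
  nf <- dim(coords)[1]; np <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  out <- matrix(NA_real_, np, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(nf)) {
      di <- coords[f, i, ] - mu[i, ]
      dj <- coords[f, j, ] - mu[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di)
      vj <- vj + sum(dj * dj)
    }
    out[i, j] <- num / sqrt(vi * vj)
  }
  out
}

# two-sided exact rank-sum p-value by exhaustive enumeration of group
# assignments (no ties assumed)
wilcox_perm_oracle <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(ws <= w_obs); hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Pearson r from the textbook formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
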
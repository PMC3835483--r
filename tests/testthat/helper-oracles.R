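# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: enumeration by brute-force tuple scans, PCA scoring
# via SVD of the data matrix (not eigen of the covariance), superposition via
# bio3d and via grid search.

adjacency_matrix <- function(graph) {
  n <- n_atoms(graph)
  a <- matrix(FALSE, n, n)
  a[graph$bonds] <- TRUE
  a[graph$bonds[, c(2, 1), drop = FALSE]] <- TRUE
  a
}

# every unordered neighbour pair around every central atom
brute_count_angles <- function(graph) {
  a <- adjacency_matrix(graph)
  n <- nrow(a)
  cnt <- 0L
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i < k && i != j && k != j && a[i, j] && a[j, k]) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# all distinct 4-paths a-b-c-d, each counted once
brute_count_dihedrals <- function(graph) {
  a <- adjacency_matrix(graph)
  n <- nrow(a)
  seen <- character(0)
  for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (!a[b, cc]) next
    for (aa in which(a[, b])) for (d in which(a[cc, ])) {
      if (aa == cc || d == b || aa == d) next
      key <- if (aa < d) paste(aa, b, cc, d) else paste(d, cc, b, aa)
      seen <- union(seen, key)
    }
  }
  length(seen)
}

# random connected molecular graph: a random tree plus extra edges
random_test_graph <- function(n, extra_edges = 0L) {
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1L, 1L), integer(1)))
  bonds <- cbind(2:n, parent[2:n])
  added <- 0L
  guard <- 0L
  while (added < extra_edges && guard < 200L) {
    guard <- guard + 1L
    e <- sort(sample(n, 2L))
    dup <- any(bonds[, 1] == e[1] & bonds[, 2] == e[2] |
                 bonds[, 1] == e[2] & bonds[, 2] == e[1])
    if (!dup) {
      bonds <- rbind(bonds, e)
      added <- added + 1L
    }
  }
  mol_graph(rep("C", n), bonds)
}

# Eq-style scores via SVD of the centred data matrix: lambda_j = d_j^2/(n-1),
# loadings = right singular vectors (sign-fixed the same way), J by cumsum.
svd_score_oracle <- function(centered, threshold = 0.90, fraction = 0.10) {
  sv <- svd(centered)
  lam <- sv$d^2 / (nrow(centered) - 1)
  v <- sv$v
  # pad spectrum to feature count when frames < features
  if (length(lam) < ncol(centered)) {
    lam <- c(lam, rep(0, ncol(centered) - length(lam)))
  }
  for (j in seq_len(ncol(v))) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) v[, j] <- -v[, j]
  }
  cumfrac <- cumsum(lam) / sum(lam)
  k <- which(cumfrac >= threshold - 1e-12)[1]
  jset <- seq_len(k)
  jv <- jset[jset <= ncol(v)]
  scores <- as.vector(abs(v[, jv, drop = FALSE]) %*% lam[jv])
  top_size <- ceiling(fraction * ncol(centered))
  ord <- order(-scores, seq_along(scores))
  list(scores = scores, top = sort(ord[seq_len(top_size)]), pcs = jset)
}

# RMSD by grid search over in-plane rotations (planar systems only)
planar_grid_rmsd <- function(mobile, reference, step = 0.01) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  best <- Inf
  for (th in seq(0, 360 - step, by = step) * pi / 180) {
    r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    rmsd <- sqrt(mean(rowSums((a %*% r - b)^2)))
    best <- min(best, rmsd)
  }
  best
}

# Mass-weighted minimum RMSD via Horn's closed-form quaternion method —
# algorithmically independent of the SVD Kabsch route it checks.
horn_rmsd <- function(mobile, reference, w) {
  w <- w / sum(w)
  a <- sweep(mobile, 2, colSums(mobile * w))
  b <- sweep(reference, 2, colSums(reference * w))
  m <- t(a * w) %*% b
  k <- matrix(c(
    m[1, 1] + m[2, 2] + m[3, 3], m[2, 3] - m[3, 2],
    m[3, 1] - m[1, 3], m[1, 2] - m[2, 1],
    m[2, 3] - m[3, 2], m[1, 1] - m[2, 2] - m[3, 3],
    m[1, 2] + m[2, 1], m[3, 1] + m[1, 3],
    m[3, 1] - m[1, 3], m[1, 2] + m[2, 1],
    -m[1, 1] + m[2, 2] - m[3, 3], m[2, 3] + m[3, 2],
    m[1, 2] - m[2, 1], m[3, 1] + m[1, 3],
    m[2, 3] + m[3, 2], -m[1, 1] - m[2, 2] + m[3, 3]), 4, 4, byrow = TRUE)
  lam <- eigen(k, symmetric = TRUE)$values[1]
  ssd <- sum(w * (rowSums(a^2) + rowSums(b^2))) - 2 * lam
  sqrt(max(ssd, 0))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
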
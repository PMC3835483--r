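# Covariance PCA of an internal-coordinate feature matrix and the
# eigenvalue-weighted feature ranking:
#
#   S_i = sum_{j in J} lambda_j |c_ij|,   J = smallest PC prefix recovering
#                                             90% of the variance,
#
# with the top 10% of features by S_i deemed thermodynamically most relevant.

# ---- circular helpers (degrees) ---------------------------------------------

#' Circular mean of angles in degrees
#' @param x angles (degrees); `NA` dropped.
#' @return mean direction in (-180, 180]; `NA` if all inputs are `NA`.
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  ang <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# mean resultant length; near 0 = near-uniform circular spread
circular_resultant <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

# wrap x into (mu - 180, mu + 180]
wrap_about <- function(x, mu) {
  d <- (x - mu) %% 360
  d[!is.na(d) & d > 180] <- d[!is.na(d) & d > 180] - 360
  mu + d
}

#' Centre a feature matrix for PCA
#'
#' Bond and angle columns are mean-centred. Dihedral columns are first
#' re-wrapped about their circular mean into `(mu - 180, mu + 180]` so the
#' +/-180 degree branch cut does not create spurious variance, then
#' mean-centred. Masked degenerate cells are imputed by the column circular
#' mean (dihedrals) or arithmetic mean and reported in the result.
#'
#' @param fm a `feature_matrix`.
#' @return list: `centered` (frames x features), `center` (column means on
#'   the unwrapped-or-wrapped scale), `imputed` (logical matrix),
#'   `unreliable` (features whose circular spread is near the uniform limit;
#'   dihedrals only), `features`.
#' @export
ic_preprocess <- function(fm) {
  vals <- fm$values
  mask <- fm$mask
  fully_masked <- which(colSums(!mask) == 0)
  if (length(fully_masked)) {
    stop("preprocessing error: feature '",
         fm$features$labels[fully_masked[1]],
         "' is degenerate in every frame")
  }
  unreliable <- rep(FALSE, ncol(vals))
  if (fm$features$kind == "dihedral") {
    for (j in seq_len(ncol(vals))) {
      mu <- circular_mean(vals[, j])
      unreliable[j] <- circular_resultant(vals[, j]) < 0.1
      col <- wrap_about(vals[, j], mu)
      col[is.na(col)] <- mu
      vals[, j] <- col
    }
  } else if (any(mask)) {
    for (j in which(colSums(mask) > 0)) {
      vals[is.na(vals[, j]), j] <- mean(vals[, j], na.rm = TRUE)
    }
  }
  ctr <- colMeans(vals)
  list(centered = sweep(vals, 2, ctr), center = ctr, imputed = mask,
       unreliable = unreliable, features = fm$features)
}

#' PCA of a centred matrix
#'
#' Eigendecomposition of the sample covariance (n-1 denominator).
#' Eigenvalues are returned in descending order (negatives from numerical
#' noise clipped at 0); loading columns are orthonormal with a deterministic
#' sign convention: the largest-magnitude entry of each PC is positive
#' (ties broken by lowest feature index).
#'
#' @param centered frames x features matrix with zero column means.
#' @param use_correlation if `TRUE`, standardise columns (correlation PCA);
#'   default `FALSE` — the ranking weights by fluctuation magnitude, which
#'   presumes covariances.
#' @return list: `eigenvalues`, `loadings`, `explained` (fractions),
#'   `total_variance`.
#' @export
ic_pca <- function(centered, use_correlation = FALSE) {
  centered <- as.matrix(centered)
  if (nrow(centered) < 2) stop("PCA needs at least 2 frames")
  if (use_correlation) {
    sds <- apply(centered, 2, stats::sd)
    if (any(sds == 0)) stop("correlation PCA undefined for a constant column")
    centered <- sweep(centered, 2, sds, "/")
  }
  cv <- stats::cov(centered)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    top <- which.max(abs(load[, j]))  # which.max: lowest index on ties
    if (load[top, j] < 0) load[, j] <- -load[, j]
  }
  total <- sum(diag(cv))
  list(eigenvalues = lam, loadings = load,
       explained = if (total > 0) lam / total else lam * 0,
       total_variance = total)
}

#' Select the PC prefix recovering a variance fraction
#'
#' Smallest prefix `1..k` of the descending eigenvalues whose cumulative
#' explained-variance fraction reaches the threshold (default 0.90).
#'
#' @param eigenvalues descending eigenvalues.
#' @param threshold cumulative variance fraction to recover, in (0, 1].
#' @return integer vector `1:k`.
#' @export
select_pcs <- function(eigenvalues, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  total <- sum(eigenvalues)
  if (total <= 0) stop("no variance: all eigenvalues are zero")
  cumfrac <- cumsum(eigenvalues) / total
  k <- which(cumfrac >= threshold - 1e-12)[1]
  seq_len(k)
}

#' Eigenvalue-weighted feature scoring and top-fraction ranking
#'
#' Computes `S_i = sum_{j in J} lambda_j |c_ij|` for every feature, sorts
#' descending (ties broken by ascending feature index, deterministically) and
#' flags the top `ceil(fraction * n_features)` features.
#'
#' @param eigenvalues descending eigenvalues.
#' @param loadings orthonormal loading matrix (features x PCs).
#' @param pcs integer PC subset J (from [select_pcs()]).
#' @param fraction top fraction of features to isolate, in (0, 1]; default 0.10.
#' @param features optional `feature_set` for labelling.
#' @return object of class `pca_ranking`: `scores`, `order` (feature indices
#'   by descending score), `top` (indices of the top set), `top_size`,
#'   `eigenvalues`, `loadings`, `explained`, `pcs`, `fraction`, `features`.
#' @export
score_rank <- function(eigenvalues, loadings, pcs, fraction = 0.10,
                       features = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  lam <- eigenvalues[pcs]
  scores <- as.vector(abs(loadings[, pcs, drop = FALSE]) %*% lam)
  ord <- order(-scores, seq_along(scores))
  top_size <- as.integer(ceiling(fraction * length(scores)))
  structure(
    list(scores = scores, order = ord, top = sort(ord[seq_len(top_size)]),
         top_size = top_size, eigenvalues = eigenvalues, loadings = loadings,
         explained = eigenvalues / sum(eigenvalues), pcs = pcs,
         fraction = fraction, features = features),
    class = "pca_ranking"
  )
}

#' @export
print.pca_ranking <- function(x, ...) {
  cat("pca_ranking:", length(x$scores), "features;",
      length(x$pcs), "PCs recover",
      sprintf("%.1f%%", 100 * sum(x$explained[x$pcs])),
      "of variance; top set:", x$top_size, "features\n")
  invisible(x)
}

#' Full ranking pipeline for one feature matrix
#'
#' Convenience wrapper: [ic_preprocess()] then [ic_pca()] then [select_pcs()]
#' then [score_rank()].
#'
#' @param fm a `feature_matrix`.
#' @param variance_threshold cumulative variance fraction (default 0.90).
#' @param top_fraction top feature fraction (default 0.10).
#' @param use_correlation standardise columns first (default `FALSE`).
#' @return a `pca_ranking`.
#' @export
pca_rank <- function(fm, variance_threshold = 0.90, top_fraction = 0.10,
                     use_correlation = FALSE) {
  prep <- ic_preprocess(fm)
  dec <- ic_pca(prep$centered, use_correlation = use_correlation)
  pcs <- select_pcs(dec$eigenvalues, variance_threshold)
  rk <- score_rank(dec$eigenvalues, dec$loadings, pcs, top_fraction,
                   features = fm$features)
  rk$unreliable <- prep$unreliable
  rk
}

#' Cross-ensemble overlap of top-ranked features
#'
#' Given named rankings over the same feature set, reports for every feature
#' which ensembles placed it in their top set, its multiplicity, and summary
#' counts of features flagged by exactly 1, 2, ... ensembles. A feature
#' flagged by several independently parameterised ensembles marks a
#' parameterisation-independent degree of freedom.
#'
#' @param rankings named list of `pca_ranking` objects over one feature set.
#' @return object of class `overlap_report`: `membership` (features x
#'   ensembles logical), `multiplicity`, `summary` (count of features per
#'   multiplicity 1..n), `features`.
#' @export
compare_rankings <- function(rankings) {
  if (is.null(names(rankings)) || any(!nzchar(names(rankings)))) {
    stop("rankings must be a named list")
  }
  nf <- vapply(rankings, function(r) length(r$scores), integer(1))
  if (length(unique(nf)) != 1) stop("rankings cover different feature sets")
  lab <- lapply(rankings, function(r)
    if (is.null(r$features)) NULL else r$features$labels)
  lab <- lab[!vapply(lab, is.null, logical(1))]
  if (length(lab) > 1 &&
      !all(vapply(lab[-1], identical, logical(1), lab[[1]]))) {
    stop("rankings cover different feature sets")
  }
  membership <- vapply(rankings, function(r)
    seq_len(nf[1]) %in% r$top, logical(nf[1]))
  multiplicity <- rowSums(membership)
  structure(
    list(membership = membership, multiplicity = multiplicity,
         summary = vapply(seq_along(rankings), function(m)
           sum(multiplicity == m), integer(1)),
         features = if (length(lab)) rankings[[1]]$features else NULL),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:", ncol(x$membership), "ensembles,",
      nrow(x$membership), "features\n")
  for (m in seq_along(x$summary)) {
    cat("  flagged by exactly", m, "ensemble(s):", x$summary[m],
        "feature(s)\n")
  }
  invisible(x)
}

#' Export a ranking as TSV
#' @param ranking a `pca_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  idx <- ranking$order
  df <- data.frame(
    rank = seq_along(idx),
    feature = if (is.null(ranking$features)) idx else
      ranking$features$labels[idx],
    score = ranking$scores[idx],
    in_top_set = idx %in% ranking$top
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an overlap report as TSV
#' @param report an `overlap_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  df <- data.frame(
    feature = if (is.null(report$features))
      seq_len(nrow(report$membership)) else report$features$labels,
    multiplicity = report$multiplicity
  )
  df <- cbind(df, as.data.frame(report$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
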
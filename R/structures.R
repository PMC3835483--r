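# Mass-weighted rigid-body superposition (Kabsch), ensemble mean structure
# and most-representative-frame selection.

# weighted centroid
.centroid <- function(xyz, w) colSums(xyz * w) / sum(w)

#' Mass-weighted rigid-body superposition
#'
#' Optimal rotation + translation (Kabsch, SVD formulation) of `mobile` onto
#' `reference` minimising the mass-weighted RMSD. Reflections are excluded:
#' the rotation determinant is forced positive, preserving chirality (a
#' mirror fit of a sterol would be meaningless).
#'
#' @param mobile a `structure3d` (or n x 3 matrix).
#' @param reference a `structure3d` (or n x 3 matrix) with identical atom
#'   count and ordering.
#' @param weights per-atom weights; defaults to the masses carried by the
#'   structures (all-atom fitting includes hydrogens), or uniform weights for
#'   bare matrices.
#' @return list: `xyz` (fitted mobile coordinates), `rmsd` (mass-weighted,
#'   Angstrom), `rotation` (3 x 3), `translation`.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mx <- if (inherits(mobile, "structure3d")) mobile$xyz else
    matrix(as.numeric(mobile), ncol = 3)
  rx <- if (inherits(reference, "structure3d")) reference$xyz else
    matrix(as.numeric(reference), ncol = 3)
  if (nrow(mx) != nrow(rx)) {
    stop("superpose: atom counts differ (", nrow(mx), " vs ", nrow(rx), ")")
  }
  if (is.null(weights)) {
    weights <- if (inherits(mobile, "structure3d")) mobile$masses else
      rep(1, nrow(mx))
  }
  w <- weights / sum(weights)
  cm <- .centroid(mx, w)
  cr <- .centroid(rx, w)
  a <- sweep(mx, 2, cm)
  b <- sweep(rx, 2, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(a %*% t(rot), 2, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - rx)^2)))
  list(xyz = fitted, rmsd = rmsd, rotation = rot,
       translation = as.vector(cr - rot %*% cm))
}

#' Mass-weighted RMSD after optimal superposition
#' @inheritParams superpose
#' @return numeric RMSD (Angstrom).
#' @export
fit_rmsd <- function(mobile, reference, weights = NULL) {
  superpose(mobile, reference, weights)$rmsd
}

#' Ensemble mean structure and representative frame
#'
#' Superposes all frames (mass-weighted, all atoms) onto an arbitrarily
#' chosen reference frame, averages the fitted coordinates, then re-superposes
#' every original frame onto that mean to obtain per-frame RMSDs. The
#' representative frame is the one with minimum RMSD from the mean (ties go
#' to the lowest frame index). An optional iterative mode re-fits to the
#' current mean until it moves less than `tol`, removing the (mild)
#' dependence on the reference choice.
#'
#' @param ens an `ensemble`.
#' @param reference reference frame index (default 1).
#' @param iterative re-fit to convergence instead of the single pass.
#' @param tol convergence threshold on the mean shift (Angstrom).
#' @param max_iter iteration cap.
#' @return object of class `ensemble_summary`: `mean` (a `structure3d`),
#'   `rmsd` (per frame, Angstrom), `representative` (frame index),
#'   `reference`, `iterations`.
#' @export
mean_structure <- function(ens, reference = 1L, iterative = FALSE,
                           tol = 1e-6, max_iter = 50L) {
  nf <- n_frames(ens)
  if (reference < 1 || reference > nf) stop("reference frame out of range")
  w <- ens$masses
  target <- ens$frames[[reference]]
  iterations <- 0L
  repeat {
    fitted <- lapply(ens$frames, function(f) superpose(f, target, w)$xyz)
    mean_xyz <- Reduce(`+`, fitted) / nf
    iterations <- iterations + 1L
    if (!iterative) break
    shift <- max(abs(mean_xyz - target))
    target <- mean_xyz
    if (shift < tol || iterations >= max_iter) break
  }
  rmsd <- vapply(ens$frames, function(f) superpose(f, mean_xyz, w)$rmsd,
                 numeric(1))
  structure(
    list(mean = structure3d(ens$elements, mean_xyz, ens$labels, ens$masses),
         rmsd = rmsd, representative = which.min(rmsd),
         reference = as.integer(reference), iterations = iterations),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("ensemble_summary:", length(x$rmsd), "frames; representative frame",
      x$representative,
      sprintf("(RMSD to mean %.4f A)", x$rmsd[x$representative]), "\n")
  invisible(x)
}

#' Export per-frame RMSDs as TSV
#' @param summary an `ensemble_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_summary <- function(summary, path) {
  df <- data.frame(frame = seq_along(summary$rmsd), rmsd = summary$rmsd,
                   representative = seq_along(summary$rmsd) ==
                     summary$representative)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
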
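# Enumeration and frame-by-frame measurement of internal coordinates
# (bond lengths, bond angles, proper dihedrals) on a molecular graph.

#' Feature set constructor
#'
#' @param kind one of `"bond"`, `"angle"`, `"dihedral"`.
#' @param tuples integer matrix, one feature per row (2, 3 or 4 columns).
#' @param graph the `mol_graph` the indices refer to (used for labels).
#' @return object of class `feature_set` with `kind`, `tuples`, `labels`.
#' @export
feature_set <- function(kind, tuples, graph = NULL) {
  kind <- match.arg(kind, c("bond", "angle", "dihedral"))
  width <- c(bond = 2L, angle = 3L, dihedral = 4L)[[kind]]
  tuples <- matrix(as.integer(tuples), ncol = width)
  # canonical orientation: first endpoint index < last endpoint index
  rev_rows <- tuples[, 1] > tuples[, width]
  tuples[rev_rows, ] <- tuples[rev_rows, rev(seq_len(width))]
  if (anyDuplicated(apply(tuples, 1, paste, collapse = "-"))) {
    stop("duplicate feature tuple")
  }
  labels <- if (is.null(graph)) {
    apply(tuples, 1, paste, collapse = "-")
  } else {
    apply(tuples, 1, function(r) paste(graph$labels[r], collapse = "-"))
  }
  structure(list(kind = kind, tuples = tuples, labels = labels),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", nrow(x$tuples), x$kind, "features\n")
  invisible(x)
}

#' Number of features in a set
#' @param features a `feature_set`.
#' @return integer count.
#' @export
n_features <- function(features) nrow(features$tuples)

#' Enumerate all bonds of a molecular graph
#'
#' Every bonded pair exactly once in canonical order. For the all-atom
#' cholesterol fixture this yields 77 features.
#' @param graph a `mol_graph`.
#' @return a `feature_set` of kind `"bond"`.
#' @export
enumerate_bonds <- function(graph) {
  feature_set("bond", graph$bonds, graph)
}

#' Enumerate all bond angles of a molecular graph
#'
#' One feature per unordered neighbour pair around each central atom, i.e.
#' \eqn{\sum_a \binom{\deg a}{2}} features; 157 on the cholesterol fixture.
#' @param graph a `mol_graph`.
#' @return a `feature_set` of kind `"angle"`.
#' @export
enumerate_angles <- function(graph) {
  rows <- list()
  for (b in seq_len(n_atoms(graph))) {
    nb <- graph$adj[[b]]
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    rows[[length(rows) + 1]] <- cbind(pairs[1, ], b, pairs[2, ])
  }
  tuples <- do.call(rbind, rows)
  if (is.null(tuples)) tuples <- matrix(integer(0), ncol = 3)
  feature_set("angle", tuples, graph)
}

#' Enumerate all proper dihedrals of a molecular graph
#'
#' For every bond (b, c), every a in N(b)\\{c} and d in N(c)\\{b} with a != d
#' defines one proper torsion a-b-c-d; each 4-tuple appears once after
#' canonicalisation. Improper torsions are excluded. 259 features on the
#' cholesterol fixture.
#' @param graph a `mol_graph`.
#' @return a `feature_set` of kind `"dihedral"`.
#' @export
enumerate_dihedrals <- function(graph) {
  rows <- list()
  for (k in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[k, 1]; cc <- graph$bonds[k, 2]
    as_ <- setdiff(graph$adj[[b]], cc)
    ds_ <- setdiff(graph$adj[[cc]], b)
    if (!length(as_) || !length(ds_)) next
    grid <- expand.grid(a = as_, d = ds_)
    grid <- grid[grid$a != grid$d, , drop = FALSE]  # 3-cycles
    if (!nrow(grid)) next
    rows[[length(rows) + 1]] <- cbind(grid$a, b, cc, grid$d)
  }
  tuples <- do.call(rbind, rows)
  if (is.null(tuples)) tuples <- matrix(integer(0), ncol = 4)
  # canonicalise then drop duplicates arising from 4-cycles traversed twice
  w <- 4L
  rev_rows <- tuples[, 1] > tuples[, w]
  tuples[rev_rows, ] <- tuples[rev_rows, w:1]
  tuples <- unique(tuples)
  tuples <- tuples[order(tuples[, 1], tuples[, 2], tuples[, 3], tuples[, 4]),
                   , drop = FALSE]
  feature_set("dihedral", tuples, graph)
}

# ---- geometry ---------------------------------------------------------------

# xyz: n_atoms x 3 matrix. All angles in degrees.

.vec_norm <- function(v) sqrt(sum(v * v))

bond_length <- function(xyz, i, j) .vec_norm(xyz[j, ] - xyz[i, ])

interior_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  cosang <- sum(u * v) / (.vec_norm(u) * .vec_norm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Signed proper torsion, IUPAC convention (cis = 0, sign by right-hand rule
# about b->c), range (-180, 180]. Returns NA for degenerate (collinear)
# configurations instead of erroring.
torsion_angle <- function(xyz, a, b, cc, d) {
  b1 <- xyz[b, ] - xyz[a, ]
  b2 <- xyz[cc, ] - xyz[b, ]
  b3 <- xyz[d, ] - xyz[cc, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (.vec_norm(n1) < 1e-10 || .vec_norm(n2) < 1e-10) return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(b1 * n2) * .vec_norm(b2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360  # map -180 onto +180
  ang
}

#' Measure internal coordinates frame by frame
#'
#' Produces the frames-by-features value matrix for one feature kind: bond
#' lengths in Angstrom, interior angles in degrees within `[0, 180]`, signed
#' proper torsions in degrees within `(-180, 180]` (IUPAC convention, cis = 0).
#' Degenerate torsions (collinear defining atoms) are masked `NA` in the value
#' matrix with a logical `mask` recording them; no exception is raised, so one
#' pathological frame cannot abort an ensemble analysis.
#'
#' @param ensemble an `ensemble` (see [read_xyz_ensemble()]).
#' @param features a `feature_set`.
#' @return object of class `feature_matrix`: `values` (frames x features),
#'   `mask` (TRUE where degenerate), `features`, `units`.
#' @export
measure_features <- function(ensemble, features) {
  nat <- nrow(ensemble$frames[[1]])
  if (n_features(features) && max(features$tuples) > nat) {
    stop("feature index exceeds atom count of ensemble")
  }
  nf <- length(ensemble$frames)
  k <- n_features(features)
  vals <- matrix(NA_real_, nf, k)
  tp <- features$tuples
  for (f in seq_len(nf)) {
    xyz <- ensemble$frames[[f]]
    vals[f, ] <- switch(
      features$kind,
      bond = vapply(seq_len(k), function(i)
        bond_length(xyz, tp[i, 1], tp[i, 2]), numeric(1)),
      angle = vapply(seq_len(k), function(i)
        interior_angle(xyz, tp[i, 1], tp[i, 2], tp[i, 3]), numeric(1)),
      dihedral = vapply(seq_len(k), function(i)
        torsion_angle(xyz, tp[i, 1], tp[i, 2], tp[i, 3], tp[i, 4]),
        numeric(1))
    )
  }
  feature_matrix(vals, features)
}

#' Feature matrix constructor
#'
#' @param values numeric frames-by-features matrix (`NA` = degenerate cell).
#' @param features the `feature_set` identifying the columns.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, features) {
  values <- as.matrix(values)
  if (ncol(values) != n_features(features)) {
    stop("column count does not match feature set size")
  }
  colnames(values) <- features$labels
  structure(
    list(values = values, mask = is.na(values), features = features,
         units = c(bond = "angstrom", angle = "degree",
                   dihedral = "degree")[[features$kind]]),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "frames x", ncol(x$values),
      x$features$kind, "features [", x$units, "];",
      sum(x$mask), "masked cells\n")
  invisible(x)
}

#' Export a feature set as TSV
#' @param features a `feature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(features, path) {
  df <- data.frame(kind = features$kind, feature = features$labels,
                   apply(features$tuples, 2, identity))
  names(df)[-(1:2)] <- paste0("atom", seq_len(ncol(features$tuples)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a feature matrix as TSV (header row of feature identities)
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(fm$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
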
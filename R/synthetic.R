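# Seeded generators for every input the pipeline needs: the cholesterol
# fixture graph, feature matrices with a known hot/cold variance structure,
# Cartesian chain ensembles rebuilt from internal coordinates, charge sets
# and energy tables. Every generator is a pure function of its arguments and
# seed; no hidden global state is relied upon beyond R's RNG, which is always
# seeded explicitly here.

#' All-atom 3beta-hydroxy-cholest-5-ene (cholesterol) molecular graph
#'
#' Standard sterol numbering: carbons C1-C27, the 3beta-hydroxyl oxygen, and
#' all 46 hydrogens (appended after the heavy atoms, grouped by parent atom
#' in heavy-atom order). Rings A (C1-C2-C3-C4-C5-C10), B (C5-C6-C7-C8-C9-C10),
#' C (C8-C9-C11-C12-C13-C14), D (C13-C14-C15-C16-C17); angular methyls C18 at
#' C13 and C19 at C10; the iso-octyl side chain C20-C27 at C17; the C5=C6
#' unsaturation is encoded only as connectivity (C5 quaternary sp2, C6 with
#' one hydrogen). 74 atoms (C27H46O), 77 bonds, 4 independent cycles.
#'
#' @return a `mol_graph`.
#' @examples
#' g <- cholesterol_graph()
#' n_features(enumerate_bonds(g))      # 77
#' @export
cholesterol_graph <- function() {
  # heavy atoms: C1..C27 then O (index 28)
  o_idx <- 28L
  heavy_elements <- c(rep("C", 27), "O")
  heavy_labels <- c(paste0("C", 1:27), "O3")
  cc_bonds <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 10), c(10, 1),   # ring A
    c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 10),             # ring B
    c(9, 11), c(11, 12), c(12, 13), c(13, 14), c(14, 8),      # ring C
    c(13, 17), c(17, 16), c(16, 15), c(15, 14),               # ring D
    c(13, 18), c(10, 19),                                     # methyls
    c(17, 20), c(20, 21), c(20, 22), c(22, 23), c(23, 24),    # side chain
    c(24, 25), c(25, 26), c(25, 27)
  )
  bonds <- rbind(cc_bonds, c(3, o_idx))
  # hydrogen counts per heavy atom (sp3 carbons filled to valence 4; C5
  # quaternary sp2, C6 sp2 with one H; hydroxyl O carries one H)
  h_count <- c(2, 2, 1, 2, 0, 1, 2, 1, 1, 0, 2, 2, 0, 1, 2, 2, 1, 3, 3,
               1, 3, 2, 2, 2, 1, 3, 3, 1)
  elements <- heavy_elements
  labels <- heavy_labels
  idx <- o_idx
  for (parent in seq_len(28L)) {
    k <- h_count[parent]
    if (k == 0) next
    suffix <- if (k == 1) "" else letters[seq_len(k)]
    for (s in suffix) {
      idx <- idx + 1L
      elements <- c(elements, "H")
      labels <- c(labels,
                  if (parent == o_idx) "HO" else paste0("H", parent, s))
      bonds <- rbind(bonds, c(parent, idx))
    }
  }
  mol_graph(elements, bonds, labels = labels)
}

#' Model-built cholesterol geometry matching the fixture graph
#'
#' A synthetic (model-built, not experimentally or MD-derived) 3D geometry
#' whose atom order matches [cholesterol_graph()], shipped as plain-text XYZ.
#' Used only for geometry-dependent demonstrations such as the surface ESP
#' map; no conformational claim is attached to it.
#'
#' @return a `structure3d` with the fixture's labels and masses.
#' @export
cholesterol_structure <- function() {
  path <- system.file("extdata", "cholesterol_modelbuilt_synthetic.xyz",
                      package = "icpca", mustWork = TRUE)
  ens <- read_xyz_ensemble(path)
  g <- cholesterol_graph()
  if (!identical(ens$elements, g$elements)) {
    stop("shipped geometry does not match the fixture graph")
  }
  structure3d(g$elements, ens$frames[[1]], g$labels, g$masses)
}

#' Generate a feature matrix with designated high-variance features
#'
#' Frames are drawn independently; each feature is Gaussian about a fixed
#' baseline with standard deviation `sd_hot` for the designated hot features
#' and `sd_cold` otherwise. This emulates what a force-field ensemble looks
#' like after internal-coordinate measurement: a few soft degrees of freedom
#' carrying large fluctuations over a stiff background. Dihedral-kind output
#' is wrapped into `(-180, 180]`, optionally with hot baselines near the
#' +/-180 branch cut to exercise the circular handling.
#'
#' @param n_frames frames (default 250, one emulated 5 ns sampling).
#' @param n_features feature count (default 77, the fixture bond count).
#' @param hot integer indices of the high-variance features.
#' @param sd_hot hot standard deviation (feature units; default 20).
#' @param sd_cold background standard deviation (default 1).
#' @param kind feature kind label for the matrix (default `"dihedral"`).
#' @param baseline scalar or per-feature baseline; default 0 for bond/angle
#'   kind, -60 for dihedral kind.
#' @param hot_near_cut place hot baselines at 180 degrees so fluctuations
#'   straddle the branch cut (dihedral kind only; default `FALSE`).
#' @param seed mandatory RNG seed.
#' @return a `feature_matrix`.
#' @export
generate_feature_matrix <- function(n_frames = 250, n_features = 77,
                                    hot = integer(0), sd_hot = 20,
                                    sd_cold = 1, kind = "dihedral",
                                    baseline = NULL, hot_near_cut = FALSE,
                                    seed) {
  if (missing(seed)) stop("a seed is mandatory for stochastic generation")
  if (sd_hot <= 0 || sd_cold <= 0) stop("standard deviations must be > 0")
  if (length(hot) && (min(hot) < 1 || max(hot) > n_features)) {
    stop("hot feature index out of range")
  }
  set.seed(seed)
  if (is.null(baseline)) baseline <- if (kind == "dihedral") -60 else 0
  base <- rep_len(baseline, n_features)
  if (hot_near_cut && kind == "dihedral") base[hot] <- 180
  sds <- rep(sd_cold, n_features)
  sds[hot] <- sd_hot
  vals <- matrix(stats::rnorm(n_frames * n_features), n_frames, n_features)
  vals <- sweep(vals, 2, sds, "*")
  vals <- sweep(vals, 2, base, "+")
  if (kind == "dihedral") {
    vals <- ((vals + 180) %% 360) - 180
    vals[vals == -180] <- 180
  }
  fs <- feature_set(kind, .placeholder_tuples(kind, n_features))
  fm <- feature_matrix(vals, fs)
  fm
}

# synthetic tuples for matrices not tied to a real graph: consecutive index
# runs, unique by construction
.placeholder_tuples <- function(kind, n) {
  w <- c(bond = 2L, angle = 3L, dihedral = 4L)[[kind]]
  t(vapply(seq_len(n), function(i) as.integer(i + 0:(w - 1)), integer(w)))
}

#' Generate a Cartesian chain ensemble with one oscillating torsion
#'
#' Builds an unbranched heavy-atom chain from an internal-coordinate template
#' (bonds 1.53 Angstrom, angles 111 degrees, torsions 180 degrees) and
#' rebuilds Cartesians frame by frame by sequential atom placement. The
#' designated torsion oscillates sinusoidally with the given amplitude;
#' Gaussian jitter is added to all torsions. Bond lengths and angles are not
#' perturbed, so only torsional degrees of freedom fluctuate.
#'
#' @param n_atoms chain length (>= 4).
#' @param n_frames frames (default 250).
#' @param hot_torsion 1-based index of the oscillating torsion (torsion `i`
#'   spans atoms `i, i+1, i+2, i+3`).
#' @param amplitude oscillation amplitude (degrees, default 60).
#' @param jitter Gaussian jitter standard deviation on all torsions
#'   (degrees, default 2).
#' @param seed mandatory RNG seed.
#' @return list: `ensemble`, `graph` (the chain), `torsions` (frames x
#'   torsions matrix actually used to build the Cartesians).
#' @export
generate_chain_ensemble <- function(n_atoms = 6, n_frames = 250,
                                    hot_torsion = 2, amplitude = 60,
                                    jitter = 2, seed) {
  if (missing(seed)) stop("a seed is mandatory for stochastic generation")
  if (n_atoms < 4) stop("chain length must be >= 4")
  n_tor <- n_atoms - 3L
  if (hot_torsion < 1 || hot_torsion > n_tor) {
    stop("hot torsion index out of range")
  }
  set.seed(seed)
  base <- rep(180, n_tor)
  tors <- matrix(rep(base, each = n_frames), n_frames, n_tor)
  tors[, hot_torsion] <- tors[, hot_torsion] +
    amplitude * sin(2 * pi * seq_len(n_frames) / 25)
  if (jitter > 0) {
    tors <- tors + matrix(stats::rnorm(n_frames * n_tor, sd = jitter),
                          n_frames, n_tor)
  }
  tors <- ((tors + 180) %% 360) - 180
  tors[tors == -180] <- 180
  frames <- lapply(seq_len(n_frames), function(f)
    build_chain_xyz(n_atoms, bond = 1.53, angle = 111, torsions = tors[f, ]))
  bonds <- cbind(seq_len(n_atoms - 1L), seq_len(n_atoms - 1L) + 1L)
  graph <- mol_graph(rep("C", n_atoms), bonds)
  list(ensemble = ensemble(frames, rep("C", n_atoms)), graph = graph,
       torsions = tors)
}

#' Rebuild chain Cartesians from internal coordinates
#'
#' Sequential (natural extension reference frame) placement for an unbranched
#' chain: atom k is placed from atoms k-1, k-2, k-3 at the given bond length,
#' supplement of the given interior angle, and signed torsion.
#'
#' @param n_atoms chain length.
#' @param bond bond length (Angstrom), scalar or per-bond.
#' @param angle interior angle (degrees), scalar or per-angle.
#' @param torsions signed torsions (degrees), length `n_atoms - 3`.
#' @return an `n_atoms` x 3 coordinate matrix.
#' @export
build_chain_xyz <- function(n_atoms, bond = 1.53, angle = 111,
                            torsions = numeric(0)) {
  bond <- rep_len(bond, n_atoms - 1L)
  angle <- rep_len(angle, max(n_atoms - 2L, 0L))
  xyz <- matrix(0, n_atoms, 3)
  xyz[2, ] <- c(bond[1], 0, 0)
  if (n_atoms >= 3) {
    th <- (180 - angle[1]) * pi / 180
    xyz[3, ] <- xyz[2, ] + bond[2] * c(cos(th), sin(th), 0)
  }
  if (n_atoms >= 4) {
    for (k in 4:n_atoms) {
      a <- xyz[k - 3, ]; b <- xyz[k - 2, ]; cc <- xyz[k - 1, ]
      r <- bond[k - 1]
      theta <- angle[k - 2] * pi / 180
      phi <- torsions[k - 3] * pi / 180
      bc <- cc - b
      bc <- bc / sqrt(sum(bc^2))
      ab <- b - a
      n <- c(ab[2] * bc[3] - ab[3] * bc[2],
             ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
      n <- n / sqrt(sum(n^2))
      m <- c(n[2] * bc[3] - n[3] * bc[2],
             n[3] * bc[1] - n[1] * bc[3],
             n[1] * bc[2] - n[2] * bc[1])
      d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi),
              r * sin(theta) * sin(phi))
      xyz[k, ] <- cc + d2[1] * bc + d2[2] * m + d2[3] * n
    }
  }
  xyz
}

#' Generate a charge set for a graph
#'
#' Patterns: `neutral` (all zero), `dipole` (+q/-q on two chosen atoms, net
#' zero), `fixture-like` (hydroxyl-polarised: negative O, positive hydroxyl H
#' and anchor carbon C3, all other atoms zero, net zero — emulating the very
#' restricted charge assignments some force fields use for sterols).
#'
#' @param graph a `mol_graph`.
#' @param pattern `"neutral"`, `"dipole"` or `"fixture-like"`.
#' @param dipole_atoms two atom indices for the dipole pattern.
#' @param q dipole magnitude (e, default 0.5).
#' @param radii per-atom radii; default vdW table.
#' @return a `charge_set`.
#' @export
generate_charges <- function(graph, pattern = c("neutral", "dipole",
                                                "fixture-like"),
                             dipole_atoms = c(1L, n_atoms(graph)), q = 0.5,
                             radii = NULL) {
  pattern <- match.arg(pattern)
  n <- n_atoms(graph)
  if (is.null(radii)) radii <- vdw_radii(graph$elements)
  charge <- rep(0, n)
  if (pattern == "dipole") {
    charge[dipole_atoms[1]] <- q
    charge[dipole_atoms[2]] <- -q
  } else if (pattern == "fixture-like") {
    o <- which(graph$elements == "O")[1]
    if (is.na(o)) stop("fixture-like pattern needs an oxygen atom")
    h_o <- graph$adj[[o]][graph$elements[graph$adj[[o]]] == "H"][1]
    anchor <- graph$adj[[o]][graph$elements[graph$adj[[o]]] == "C"][1]
    charge[o] <- -0.65
    charge[h_o] <- 0.40
    charge[anchor] <- 0.25
  }
  charge_set(charge, radii)
}

#' Generate a per-frame energy table
#'
#' Gaussian series about stated per-column means, reproducible from seed.
#'
#' @param n_frames frames (default 250).
#' @param means named numeric vector of column means; must include `kinetic`
#'   and `potential`; optional `bond`, `angle`, `urey_bradley`, `dihedral`.
#' @param noise Gaussian standard deviation, scalar or per column (> 0, or 0
#'   for a deterministic table).
#' @param seed mandatory RNG seed.
#' @return an `energy_table` data.frame.
#' @export
generate_energy_table <- function(n_frames = 250,
                                  means = c(kinetic = 100, potential = 100),
                                  noise = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory for stochastic generation")
  if (any(noise < 0)) stop("noise scale must be >= 0")
  set.seed(seed)
  noise <- rep_len(noise, length(means))
  cols <- lapply(seq_along(means), function(j)
    means[[j]] + if (noise[j] > 0)
      stats::rnorm(n_frames, sd = noise[j]) else rep(0, n_frames))
  df <- as.data.frame(cols, col.names = names(means))
  class(df) <- c("energy_table", "data.frame")
  df
}
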
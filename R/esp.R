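# Simplified membrane-internal electrostatic potential on a molecular dot
# surface. Two-region continuum: polar head-group domain (methanol-like
# dielectric) vs hydrophobic core domain (cyclohexane-like), sharp boundary
# at the per-atom region tag; region-wise screened Coulomb, not a Poisson
# solver. Magnitudes are therefore indicative; signs and patch locations are
# the comparable quantities.

# Coulomb constant in eV*Angstrom/e^2 and Boltzmann constant in eV/K
.K_COULOMB <- 14.3996
.K_BOLTZMANN <- 8.617333262e-5

# Bondi-style van der Waals radii (Angstrom)
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Look up van der Waals radii for a set of elements
#' @param elements element symbols.
#' @return numeric radii (Angstrom).
#' @export
vdw_radii <- function(elements) {
  r <- .VDW_RADII[as.character(elements)]
  if (anyNA(r)) {
    stop("no vdW radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Assign atoms to the polar head-group or hydrophobic core region
#'
#' The listed atoms — for cholesterol, the hydroxyl group plus ring positions
#' C2, C3, C4 — are tagged `polar_head`; by default their bonded hydrogens
#' are pulled in with them; every other atom is tagged `core`. Each region
#' carries its own dielectric constant (defaults: methanol-like 32.6 for the
#' head-group domain, cyclohexane-like 2.02 for the core).
#'
#' @param graph a `mol_graph`.
#' @param polar_atoms 1-based indices of the polar seed atoms (may be empty:
#'   all atoms become core, with a warning).
#' @param include_hydrogens also tag hydrogens bonded to the seed atoms
#'   (default `TRUE`).
#' @param eps_polar dielectric constant of the polar head-group region.
#' @param eps_core dielectric constant of the hydrophobic core region.
#' @return object of class `region_assignment`: `region` (factor per atom),
#'   `eps` (named dielectric constants).
#' @export
assign_regions <- function(graph, polar_atoms, include_hydrogens = TRUE,
                           eps_polar = 32.6, eps_core = 2.02) {
  n <- n_atoms(graph)
  polar_atoms <- as.integer(polar_atoms)
  if (length(polar_atoms) && (min(polar_atoms) < 1 || max(polar_atoms) > n)) {
    stop("polar atom index out of range")
  }
  if (eps_polar < 1 || eps_core < 1) stop("dielectric constants must be >= 1")
  polar <- logical(n)
  polar[polar_atoms] <- TRUE
  if (include_hydrogens && length(polar_atoms)) {
    for (i in polar_atoms) {
      nb <- graph$adj[[i]]
      polar[nb[graph$elements[nb] == "H"]] <- TRUE
    }
  }
  if (!any(polar)) warning("polar head-group region is empty")
  if (all(polar)) warning("hydrophobic core region is empty")
  structure(
    list(region = factor(ifelse(polar, "polar_head", "core"),
                         levels = c("polar_head", "core")),
         eps = c(polar_head = eps_polar, core = eps_core)),
    class = "region_assignment"
  )
}

#' @export
print.region_assignment <- function(x, ...) {
  cat("region_assignment:", sum(x$region == "polar_head"),
      "polar-head atoms (eps", x$eps[["polar_head"]], "),",
      sum(x$region == "core"), "core atoms (eps", x$eps[["core"]], ")\n")
  invisible(x)
}

#' Sample a molecular dot surface
#'
#' Quasi-uniform (Fibonacci lattice) sampling of each atom's sphere at
#' `radius * scale`; points buried inside any other atom's scaled sphere are
#' removed. Every surviving point is tagged with its parent atom.
#'
#' @param struct a `structure3d`.
#' @param radii per-atom radii (Angstrom); default Bondi-style vdW table.
#' @param scale radius scale factor >= 1 (default 1.1, slightly increased
#'   vdW radii).
#' @param density target point density (points per square Angstrom,
#'   default 5).
#' @return data.frame: `x`, `y`, `z`, `atom` (parent index).
#' @export
sample_surface <- function(struct, radii = NULL, scale = 1.1, density = 5) {
  if (is.null(radii)) radii <- vdw_radii(struct$elements)
  if (any(radii <= 0)) stop("radii must be > 0")
  if (scale < 1) stop("radius scale must be >= 1")
  n <- length(struct$elements)
  r <- radii * scale
  pts <- vector("list", n)
  golden <- pi * (3 - sqrt(5))
  for (i in seq_len(n)) {
    m <- max(12L, as.integer(ceiling(density * 4 * pi * r[i]^2)))
    k <- seq_len(m) - 0.5
    z <- 1 - 2 * k / m
    rho <- sqrt(pmax(0, 1 - z^2))
    th <- golden * k
    sph <- cbind(rho * cos(th), rho * sin(th), z) * r[i]
    sph <- sweep(sph, 2, struct$xyz[i, ], "+")
    # occlusion: drop points inside any other scaled sphere
    keep <- rep(TRUE, m)
    for (j in seq_len(n)[-i]) {
      dc <- sqrt(sum((struct$xyz[i, ] - struct$xyz[j, ])^2))
      if (dc >= r[i] + r[j]) next
      dj <- sqrt(rowSums(sweep(sph, 2, struct$xyz[j, ])^2))
      keep <- keep & dj >= r[j] * (1 - 1e-12)
    }
    if (any(keep)) {
      pts[[i]] <- data.frame(x = sph[keep, 1], y = sph[keep, 2],
                             z = sph[keep, 3], atom = i)
    }
  }
  out <- do.call(rbind, pts)
  if (is.null(out) || !nrow(out)) {
    stop("degenerate geometry: no surface points survive occlusion")
  }
  rownames(out) <- NULL
  out
}

#' Screened-Coulomb electrostatic potential at surface points
#'
#' For a point p on an atom tagged with region R:
#' \deqn{\phi(p) = \frac{k_C}{\varepsilon_R} \sum_i \frac{q_i}{|p - r_i|}}
#' expressed in kT per unit elementary charge at the given temperature
#' (default 300 K). Values are reported raw and clamped to the display range
#' (default +/- 5 kT/e). A point coincident with a charge centre is masked.
#'
#' @param points data.frame from [sample_surface()] (`x`, `y`, `z`, `atom`).
#' @param struct the `structure3d` carrying the charge centres.
#' @param charges a `charge_set` aligned to `struct`.
#' @param regions a `region_assignment` for the same atoms.
#' @param temperature Kelvin (default 300).
#' @param clamp display clamp range in kT/e (default 5).
#' @return object of class `surface_esp`: the input points plus `region`,
#'   `phi` (kT/e, raw), `phi_clamped`, `masked`; attributes `temperature`,
#'   `clamp`.
#' @export
esp_at_points <- function(points, struct, charges, regions,
                          temperature = 300, clamp = 5) {
  n <- length(struct$elements)
  if (length(charges$charge) != n) {
    stop("charge alignment error: ", length(charges$charge),
         " charges for a ", n, "-atom structure")
  }
  kT <- .K_BOLTZMANN * temperature
  eps <- regions$eps[as.character(regions$region[points$atom])]
  p <- as.matrix(points[, c("x", "y", "z")])
  phi <- numeric(nrow(p))
  masked <- rep(FALSE, nrow(p))
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(p, 2, struct$xyz[i, ])^2))
    coincident <- d < 1e-10
    masked <- masked | coincident
    d[coincident] <- Inf
    phi <- phi + charges$charge[i] / d
  }
  phi <- .K_COULOMB * phi / (eps * kT)
  phi[masked] <- NA_real_
  out <- points
  out$region <- regions$region[points$atom]
  out$phi <- phi
  out$phi_clamped <- pmin(pmax(phi, -clamp), clamp)
  out$masked <- masked
  attr(out, "temperature") <- temperature
  attr(out, "clamp") <- clamp
  class(out) <- c("surface_esp", "data.frame")
  out
}

#' Export a surface ESP point cloud as TSV
#' @param esp a `surface_esp`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_esp <- function(esp, path) {
  utils::write.table(as.data.frame(esp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a structure with per-atom mean clamped ESP in the B-factor column
#'
#' A PDB dialect consumable by external viewers: each atom's B-factor holds
#' the mean clamped potential over its surviving surface points.
#'
#' @param struct a `structure3d`.
#' @param esp a `surface_esp` computed on it.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_esp_pdb <- function(struct, esp, path) {
  b <- rep(0, length(struct$elements))
  agg <- tapply(esp$phi_clamped, esp$atom, mean, na.rm = TRUE)
  b[as.integer(names(agg))] <- round(agg, 2)
  b[is.na(b)] <- 0
  write_pdb_structure(struct, path, b = b)
}
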
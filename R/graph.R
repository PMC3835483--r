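# Molecular graph: atoms (element, mass, display label) + covalent bonds.
# Internally 0-based nothing: R is 1-based throughout; user-facing files are
# 1-based too, so indices pass through unchanged.

.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

#' Construct a molecular graph
#'
#' A molecular graph carries the atoms of one molecule (element, mass and a
#' display label) together with its covalent bonds as unordered index pairs.
#' It is the sole source of internal-coordinate enumeration: no distance-based
#' bond perception is ever performed, so feature counts are fixed by the
#' connectivity the caller supplies.
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"H"`).
#' @param bonds two-column integer matrix of 1-based atom index pairs.
#' @param labels optional display labels (default `element + index`).
#' @param masses optional atomic masses (amu); defaults to a built-in table.
#' @param check if `TRUE` (default), validate invariants: no self bonds, no
#'   duplicate bonds, all indices valid, single connected component.
#' @return an object of class `mol_graph` with components `elements`,
#'   `masses`, `labels`, `bonds` (canonicalised, first index < second) and
#'   `adj` (adjacency list).
#' @examples
#' g <- mol_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
#' graph_degrees(g)
#' @export
mol_graph <- function(elements, bonds, labels = NULL, masses = NULL,
                      check = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(masses)) {
    masses <- .ATOMIC_MASSES[elements]
    if (anyNA(masses)) {
      stop("unknown element(s): ",
           paste(unique(elements[is.na(masses)]), collapse = ", "))
    }
    masses <- unname(masses)
  }
  if (is.null(labels)) labels <- paste0(elements, seq_len(n))
  if (check) {
    if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
    if (any(masses <= 0)) stop("masses must be strictly positive")
  }
  # canonical orientation: smaller index first, rows sorted
  swap <- bonds[, 1] > bonds[, 2]
  bonds[swap, ] <- bonds[swap, c(2, 1)]
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  if (check && anyDuplicated(paste(bonds[, 1], bonds[, 2]))) {
    stop("duplicate bond")
  }
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)
  g <- structure(
    list(elements = elements, masses = masses, labels = as.character(labels),
         bonds = bonds, adj = adj),
    class = "mol_graph"
  )
  if (check && n > 1 && n_components(g) != 1L) {
    stop("graph is not connected: a single molecule must form one component")
  }
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat("mol_graph:", length(x$elements), "atoms (", formula, "),",
      nrow(x$bonds), "bonds,", graph_cycles(x), "independent cycles\n")
  invisible(x)
}

#' Number of atoms in a graph
#' @param graph a `mol_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(graph) length(graph$elements)

#' Per-atom degree (number of covalent neighbours)
#' @param graph a `mol_graph`.
#' @return integer vector, one entry per atom.
#' @export
graph_degrees <- function(graph) vapply(graph$adj, length, integer(1))

# connected components by BFS
n_components <- function(graph) {
  n <- n_atoms(graph)
  seen <- logical(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- graph$adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  ncomp
}

#' Number of independent cycles (circuit rank)
#'
#' For a connected molecular graph this equals `bonds - atoms + 1`; the
#' cholesterol fixture gives 4 (tetracyclic sterol ring system).
#' @param graph a `mol_graph`.
#' @return integer circuit rank.
#' @export
graph_cycles <- function(graph) {
  nrow(graph$bonds) - n_atoms(graph) + n_components(graph)
}

#' Read a plain bond-list file
#'
#' Two 1-based integer atom indices per line, whitespace-separated; blank
#' lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param elements element symbols of the atoms the bond list refers to.
#' @param ... passed to [mol_graph()].
#' @return a `mol_graph`.
#' @export
read_bond_list <- function(path, elements, ...) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) stop("bond-list line ", bad[1], " does not hold two indices")
  bonds <- do.call(rbind, lapply(parts, as.integer))
  if (anyNA(bonds)) stop("non-integer bond index in bond list")
  mol_graph(elements, bonds, ...)
}

#' Write a bond list
#' @param graph a `mol_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bond_list <- function(graph, path) {
  writeLines(paste(graph$bonds[, 1], graph$bonds[, 2]), path)
  invisible(path)
}
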
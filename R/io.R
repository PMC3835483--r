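# Readers/writers for the formats the pipeline touches: multi-frame XYZ,
# multi-MODEL PDB, PQR charge files, delimited energy tables. No science here.
# All coordinates are Angstrom; no unit auto-detection. Atom indices are
# 1-based everywhere (R convention and file convention coincide).

#' Single-conformer structure
#'
#' @param elements element symbols.
#' @param xyz numeric n x 3 coordinate matrix (Angstrom).
#' @param labels optional atom labels.
#' @param masses optional masses (amu); default from a built-in table.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(elements, xyz, labels = NULL, masses = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (nrow(xyz) != length(elements)) {
    stop("coordinate count does not equal atom count")
  }
  if (is.null(masses)) {
    masses <- .ATOMIC_MASSES[as.character(elements)]
    if (anyNA(masses)) {
      stop("unknown element(s): ",
           paste(unique(elements[is.na(masses)]), collapse = ", "))
    }
    masses <- unname(masses)
  }
  if (any(masses <= 0)) stop("masses must be strictly positive")
  if (is.null(labels)) labels <- paste0(elements, seq_along(elements))
  structure(list(elements = as.character(elements), xyz = xyz,
                 labels = as.character(labels), masses = masses),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", length(x$elements), "atoms\n")
  invisible(x)
}

#' Conformational ensemble
#'
#' Shared atom metadata plus an ordered list of coordinate frames.
#'
#' @param frames list of n x 3 coordinate matrices (Angstrom), identical atom
#'   count and ordering.
#' @param elements shared element symbols.
#' @param labels optional shared atom labels.
#' @param masses optional masses (amu).
#' @param provenance optional per-frame tags (source file, model number).
#' @return object of class `ensemble`.
#' @export
ensemble <- function(frames, elements, labels = NULL, masses = NULL,
                     provenance = NULL) {
  if (!length(frames)) stop("an ensemble needs at least 1 frame")
  nat <- length(elements)
  frames <- lapply(frames, function(f) matrix(as.numeric(f), ncol = 3))
  counts <- vapply(frames, nrow, integer(1))
  if (any(counts != nat)) {
    stop("frame ", which(counts != nat)[1], " has ", counts[counts != nat][1],
         " atoms, expected ", nat)
  }
  proto <- structure3d(elements, frames[[1]], labels, masses)
  structure(list(frames = frames, elements = proto$elements,
                 labels = proto$labels, masses = proto$masses,
                 provenance = provenance),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", length(x$frames), "frames x", length(x$elements), "atoms\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Extract one frame as a structure
#' @param ens an `ensemble`.
#' @param i frame index.
#' @return a `structure3d`.
#' @export
get_frame <- function(ens, i) {
  structure3d(ens$elements, ens$frames[[i]], ens$labels, ens$masses)
}

# ---- XYZ --------------------------------------------------------------------

#' Read a multi-frame XYZ file
#'
#' Each frame block: atom-count line, comment line, then that many atom lines
#' (`element x y z`). Frames are returned in file order.
#'
#' @param path file path.
#' @return an `ensemble`.
#' @export
read_xyz_ensemble <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  frames <- list()
  elements <- NULL
  pos <- 1L
  frame_no <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    frame_no <- frame_no + 1L
    if (is.na(nat) || nat < 1) {
      stop("XYZ format error in frame ", frame_no, ": bad atom-count line ",
           pos)
    }
    if (pos + 1L + nat > length(lines)) {
      stop("XYZ format error in frame ", frame_no,
           ": file truncated, expected ", nat, " atom lines")
    }
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    short <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(short)) {
      stop("XYZ format error in frame ", frame_no, ": malformed atom line ",
           pos + 1L + short[1])
    }
    el <- vapply(parts, `[[`, character(1), 1)
    coords <- t(vapply(parts, function(p)
      suppressWarnings(as.numeric(p[2:4])), numeric(3)))
    if (anyNA(coords)) {
      bad <- which(apply(is.na(coords), 1, any))[1]
      stop("XYZ parse error: non-numeric coordinate at line ",
           pos + 1L + bad)
    }
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("XYZ format error: frame ", frame_no, " has ", length(el),
           " atoms, frame 1 has ", length(elements))
    }
    frames[[frame_no]] <- coords
    pos <- pos + 2L + nat
  }
  ensemble(frames, elements,
           provenance = data.frame(source = path,
                                   frame = seq_along(frames)))
}

#' Write an ensemble (or structure) as multi-frame XYZ
#' @param x an `ensemble` or `structure3d`.
#' @param path output path.
#' @param comment per-frame comment line(s).
#' @param digits coordinate decimals (default 6).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = NULL, digits = 6) {
  if (inherits(x, "structure3d")) x <- ensemble(list(x$xyz), x$elements,
                                                x$labels, x$masses)
  nfr <- n_frames(x)
  if (is.null(comment)) comment <- paste("frame", seq_len(nfr))
  comment <- rep_len(comment, nfr)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-3s %", digits + 6, ".", digits, "f %",
                digits + 6, ".", digits, "f %", digits + 6, ".", digits, "f")
  for (f in seq_len(nfr)) {
    writeLines(as.character(length(x$elements)), con)
    writeLines(comment[f], con)
    writeLines(sprintf(fmt, x$elements, x$frames[[f]][, 1],
                       x$frames[[f]][, 2], x$frames[[f]][, 3]), con)
  }
  invisible(path)
}

# ---- PDB --------------------------------------------------------------------

.TWO_LETTER_ELEMENTS <- c("Cl", "Br", "Na", "Mg", "Zn", "Fe", "Ca", "Mn",
                          "Cu", "Se", "Si", "Al", "Li", "Be", "Ne", "Ar")

#' Infer an element symbol from a PDB atom name
#'
#' Fallback used when the PDB element column is blank: the first alphabetic
#' character(s) of the atom name, preferring a two-letter periodic-table
#' match (Cl, Br, ...) over a single letter. Common in legacy snapshot files.
#'
#' @param atom_name character vector of atom names (e.g. `"C12"`, `"1HB"`).
#' @return character vector of element symbols.
#' @export
infer_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    alpha <- sub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", nm))
    if (!nzchar(alpha)) stop("cannot infer element from atom name '", nm, "'")
    if (nchar(alpha) >= 2) {
      two <- paste0(toupper(substr(alpha, 1, 1)),
                    tolower(substr(alpha, 2, 2)))
      if (two %in% .TWO_LETTER_ELEMENTS) return(two)
    }
    toupper(substr(alpha, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a (possibly multi-MODEL) PDB file as an ensemble
#'
#' Frames are MODEL blocks in file order (a file without MODEL records is one
#' implicit model). Elements come from the element column when present,
#' otherwise from the atom name via a two-letter-element lookup fallback.
#'
#' @param path file path.
#' @return an `ensemble`.
#' @export
read_pdb_ensemble <- function(path) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    # pre-check per-MODEL atom counts so the error names the offending frame
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(i)
      sum(is_atom[bounds[i]:(bounds[i + 1] - 1L)]), integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop("PDB format error: MODEL ", bad, " has ", counts[bad],
           " atoms, MODEL 1 has ", counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elesy <- trimws(pdb$atom$elesy)
  name <- trimws(pdb$atom$elety)
  blank <- is.na(elesy) | !nzchar(elesy)
  elesy[blank] <- infer_element(name[blank])
  elesy[!blank] <- paste0(toupper(substr(elesy[!blank], 1, 1)),
                          tolower(substr(elesy[!blank], 2, 10)))
  nmodel <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nmodel), function(m)
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE))
  ensemble(frames, elesy, labels = name,
           provenance = data.frame(source = path, model = seq_len(nmodel)))
}

#' Write a structure as a single-model PDB
#'
#' @param struct a `structure3d`.
#' @param path output path.
#' @param b optional per-atom B-factor column values (e.g. a mapped potential).
#' @param resid residue name (default `"MOL"`).
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(struct, path, b = NULL, resid = "MOL") {
  n <- length(struct$elements)
  if (is.null(b)) b <- rep(0, n)
  bio3d::write.pdb(file = path, xyz = as.vector(t(struct$xyz)),
                   type = rep("HETATM", n), resno = rep(1L, n),
                   resid = rep(resid, n), eleno = seq_len(n),
                   elety = struct$labels, chain = rep("A", n),
                   o = rep(1, n), b = b, elesy = struct$elements)
  invisible(path)
}

# ---- charges (PQR / tabular) ------------------------------------------------

#' Charge set constructor
#' @param charge per-atom partial charge (e).
#' @param radius per-atom radius (Angstrom).
#' @return object of class `charge_set`.
#' @export
charge_set <- function(charge, radius) {
  if (length(charge) != length(radius)) {
    stop("charge and radius vectors differ in length")
  }
  if (any(radius <= 0)) stop("radii must be > 0")
  structure(list(charge = as.numeric(charge), radius = as.numeric(radius)),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat("charge_set:", length(x$charge), "atoms, net charge",
      format(sum(x$charge), digits = 4), "e\n")
  invisible(x)
}

#' Read per-atom partial charges and radii
#'
#' Accepts PQR (whitespace-separated ATOM/HETATM records, charge then radius
#' after the coordinates) or a 2-column table `charge radius` (one row per
#' atom, optional header), selected by content.
#'
#' @param path file path.
#' @param n_atoms_expected if given, the reader errors unless the file holds
#'   exactly this many entries (alignment check against a structure).
#' @return a `charge_set` aligned to structure atom order.
#' @export
read_charges <- function(path, n_atoms_expected = NULL) {
  first <- readLines(path, n = 50)
  if (any(grepl("^(ATOM|HETATM)", first))) {
    pqr <- bio3d::read.pqr(path, verbose = FALSE)
    cs <- charge_set(pqr$atom$o, pqr$atom$b)
  } else {
    df <- utils::read.table(path, header = .has_header(path))
    if (ncol(df) < 2) stop("tabular charge file needs 2 columns: charge radius")
    cs <- charge_set(df[[1]], df[[2]])
  }
  if (!is.null(n_atoms_expected) && length(cs$charge) != n_atoms_expected) {
    stop("charge alignment error: ", length(cs$charge),
         " entries for a ", n_atoms_expected, "-atom structure")
  }
  cs
}

.has_header <- function(path) {
  l1 <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  any(is.na(suppressWarnings(as.numeric(l1))))
}

#' Write charges alongside a structure as PQR
#' @param struct a `structure3d`.
#' @param charges a `charge_set` aligned to it.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charges <- function(struct, charges, path) {
  n <- length(struct$elements)
  if (length(charges$charge) != n) {
    stop("charge alignment error: ", length(charges$charge),
         " entries for a ", n, "-atom structure")
  }
  bio3d::write.pqr(file = path, xyz = as.vector(t(struct$xyz)),
                   resno = rep(1L, n), resid = rep("MOL", n),
                   eleno = seq_len(n), elety = struct$labels,
                   o = charges$charge, b = charges$radius)
  invisible(path)
}

# ---- energy tables ----------------------------------------------------------

.ENERGY_OPTIONAL <- c("bond", "angle", "urey_bradley", "dihedral")

#' Read a per-frame energy-term table
#'
#' Delimited (comma, tab or whitespace) with a header naming at least
#' `kinetic` and `potential`; optional columns `bond`, `angle`,
#' `urey_bradley`, `dihedral`. Missing optional columns are absent, not zero.
#' Unknown columns are kept but ignored downstream.
#'
#' @param path file path.
#' @return data.frame, one row per frame, class `energy_table`.
#' @export
read_energy_table <- function(path) {
  l1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  for (must in c("kinetic", "potential")) {
    if (!must %in% names(df)) {
      stop("energy table schema error: missing mandatory column '", must, "'")
    }
  }
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Write a per-frame energy-term table (TSV)
#' @param df a data.frame of energy terms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
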
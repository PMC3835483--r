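# End-to-end orchestration: measure -> PCA-rank per feature kind ->
# cross-ensemble overlap -> mean/representative structure -> ESP on the
# representative. All stage outputs are plain text (TSV/JSON/PDB/XYZ); a JSON
# manifest ties every output file to the configuration that produced it.

#' Build a pipeline run configuration
#'
#' @param ensembles named list: each element an `ensemble` object or a path
#'   to a multi-frame XYZ/PDB file. Names identify the force fields or
#'   sources being compared.
#' @param graph a `mol_graph`, or a bond-list file path (then `elements`
#'   must be given).
#' @param elements element symbols when `graph` is a bond-list path.
#' @param kinds feature kinds to analyse (subset of bond/angle/dihedral).
#' @param variance_threshold cumulative explained-variance fraction for PC
#'   selection (default 0.90).
#' @param top_fraction top feature fraction (default 0.10).
#' @param reference reference frame index for mean structures (default 1).
#' @param charges optional `charge_set` (or PQR path) for the ESP stage;
#'   `NULL` skips ESP.
#' @param polar_atoms polar head-group seed atoms for the ESP stage.
#' @param eps_polar,eps_core region dielectric constants.
#' @param radius_scale vdW radius scale for the dot surface.
#' @param clamp ESP display clamp (kT/e).
#' @param temperature Kelvin for the kT conversion.
#' @param out_dir output directory.
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when inputs were generated).
#' @return a `run_config` list.
#' @export
run_config <- function(ensembles, graph, elements = NULL,
                       kinds = c("bond", "angle", "dihedral"),
                       variance_threshold = 0.90, top_fraction = 0.10,
                       reference = 1L, charges = NULL,
                       polar_atoms = integer(0), eps_polar = 32.6,
                       eps_core = 2.02, radius_scale = 1.1, clamp = 5,
                       temperature = 300, out_dir = ".", seed = 1L) {
  if (!length(ensembles)) stop("at least one ensemble is required")
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles)))) {
    stop("ensembles must be named")
  }
  kinds <- match.arg(kinds, c("bond", "angle", "dihedral"),
                     several.ok = TRUE)
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance threshold must be in (0, 1]")
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top fraction must be in (0, 1]")
  }
  structure(as.list(environment()), class = "run_config")
}

.load_ensemble <- function(x) {
  if (inherits(x, "ensemble")) return(x)
  if (grepl("\\.pdb$", x, ignore.case = TRUE)) read_pdb_ensemble(x)
  else read_xyz_ensemble(x)
}

#' Run the full pipeline
#'
#' For every ensemble and every requested feature kind: measure the internal
#' coordinates, rank them by the eigenvalue-weighted PCA score, and write the
#' ranking; then compare top sets across ensembles per kind; compute the mean
#' and representative structure per ensemble; and, when charges are supplied,
#' map the two-dielectric surface ESP of each representative structure.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `rankings` (by kind, by ensemble),
#'   `overlaps` (by kind), `summaries` (by ensemble), `esp` (by ensemble or
#'   NULL) and `manifest` (also written as JSON to the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      # mark partial outputs so a half-written run is never mistaken for a
      # complete one
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  graph <- stage("graph", {
    if (inherits(config$graph, "mol_graph")) config$graph
    else read_bond_list(config$graph, config$elements)
  })
  ens <- stage("read-ensembles", lapply(config$ensembles, .load_ensemble))
  say("loaded ", length(ens), " ensemble(s): ",
      paste(names(ens), collapse = ", "))

  enumerators <- list(bond = enumerate_bonds, angle = enumerate_angles,
                      dihedral = enumerate_dihedrals)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  rankings <- list()
  overlaps <- list()
  for (kind in config$kinds) {
    fs <- enumerators[[kind]](graph)
    say(kind, " features enumerated: ", n_features(fs))
    rk_kind <- list()
    for (nm in names(ens)) {
      fm <- stage(paste0("measure-", kind, "-", nm),
                  measure_features(ens[[nm]], fs))
      rk <- stage(paste0("rank-", kind, "-", nm),
                  pca_rank(fm, config$variance_threshold,
                           config$top_fraction))
      write_ranking(rk, emit(file.path(config$out_dir,
                                       paste0("ranking_", kind, "_", nm,
                                              ".tsv"))))
      rk_kind[[nm]] <- rk
      say("ranked ", kind, "/", nm, ": top set ", rk$top_size,
          " of ", length(rk$scores))
    }
    rankings[[kind]] <- rk_kind
    if (length(rk_kind) > 1) {
      ov <- stage(paste0("compare-", kind), compare_rankings(rk_kind))
      write_overlap_report(ov, emit(file.path(config$out_dir,
                                              paste0("overlap_", kind,
                                                     ".tsv"))))
      overlaps[[kind]] <- ov
    }
  }

  summaries <- list()
  esp_out <- list()
  charges <- if (is.null(config$charges)) NULL
             else if (inherits(config$charges, "charge_set")) config$charges
             else read_charges(config$charges, n_atoms(graph))
  for (nm in names(ens)) {
    sm <- stage(paste0("meanstruct-", nm),
                mean_structure(ens[[nm]], config$reference))
    write_ensemble_summary(sm, emit(file.path(config$out_dir,
                                              paste0("rmsd_", nm, ".tsv"))))
    write_xyz(sm$mean, emit(file.path(config$out_dir,
                                      paste0("mean_", nm, ".xyz"))))
    rep_struct <- get_frame(ens[[nm]], sm$representative)
    write_xyz(rep_struct, emit(file.path(config$out_dir,
                                         paste0("representative_", nm,
                                                ".xyz"))))
    summaries[[nm]] <- sm
    say("mean structure ", nm, ": representative frame ", sm$representative)
    if (!is.null(charges)) {
      esp <- stage(paste0("esp-", nm), {
        regions <- assign_regions(graph, config$polar_atoms,
                                  eps_polar = config$eps_polar,
                                  eps_core = config$eps_core)
        pts <- sample_surface(rep_struct, scale = config$radius_scale)
        esp_at_points(pts, rep_struct, charges, regions,
                      temperature = config$temperature,
                      clamp = config$clamp)
      })
      write_surface_esp(esp, emit(file.path(config$out_dir,
                                            paste0("esp_", nm, ".tsv"))))
      write_esp_pdb(rep_struct, esp,
                    emit(file.path(config$out_dir,
                                   paste0("esp_", nm, ".pdb"))))
      esp_out[[nm]] <- esp
      say("ESP ", nm, ": ", nrow(esp), " surface points, range [",
          sprintf("%.2f", min(esp$phi, na.rm = TRUE)), ", ",
          sprintf("%.2f", max(esp$phi, na.rm = TRUE)), "] kT/e")
    }
  }

  cfg_public <- config[!vapply(config, is.environment, logical(1))]
  cfg_public$ensembles <- lapply(cfg_public$ensembles, function(x)
    if (is.character(x)) x else "<in-memory ensemble>")
  cfg_public$graph <- if (is.character(cfg_public$graph)) cfg_public$graph
                      else "<in-memory graph>"
  cfg_public$charges <- if (is.null(cfg_public$charges)) NULL
                        else if (is.character(cfg_public$charges))
                          cfg_public$charges else "<in-memory charges>"
  manifest <- list(config = cfg_public, outputs = basename(outputs),
                   log = log_lines)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(rankings = rankings, overlaps = overlaps,
                 summaries = summaries, esp = esp_out, manifest = manifest))
}
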
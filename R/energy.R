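# Aggregation of per-frame energy-term tables into relative-contribution
# summaries: kinetic vs potential fraction of the total, and bond/angle/
# dihedral shares of the bonded sum. A Urey-Bradley column (CHARMM's
# auxiliary 1,3 term) is folded into the angle contribution before shares
# are formed; an absent bond column (force fields constraining all bonds)
# yields a zero bond share with an explicit flag.

#' Summarise a per-frame energy table
#'
#' Kinetic/potential fractions use `|kinetic| + |potential|` as the per-frame
#' denominator (robust when the net total is near zero), are computed per
#' frame, then averaged. Bonded shares are `bond : angle : dihedral` fractions
#' of their per-frame sum, averaged over frames, with Urey-Bradley folded
#' into angle first.
#'
#' @param records an `energy_table` (data.frame with `kinetic`, `potential`
#'   and optionally `bond`, `angle`, `urey_bradley`, `dihedral` columns).
#' @return object of class `energy_breakdown`: `kinetic_fraction`,
#'   `potential_fraction`, `bonded_shares` (named bond/angle/dihedral),
#'   `urey_bradley_folded`, `absent_terms`, `flagged_frames`, `per_frame`
#'   (data.frame of the per-frame series).
#' @export
summarize_energy <- function(records) {
  records <- as.data.frame(records)
  names(records) <- tolower(names(records))
  for (must in c("kinetic", "potential")) {
    if (!must %in% names(records)) {
      stop("energy table schema error: missing mandatory column '", must, "'")
    }
  }
  kin <- records$kinetic
  pot <- records$potential
  denom <- abs(kin) + abs(pot)
  flagged <- denom <= 0 | (kin + pot) <= 0
  if (all(flagged)) {
    stop("every frame has non-positive total energy; fractions undefined")
  }
  ok <- denom > 0
  kin_frac <- ifelse(ok, abs(kin) / denom, NA_real_)
  pot_frac <- ifelse(ok, abs(pot) / denom, NA_real_)

  terms <- c("bond", "angle", "dihedral")
  absent <- terms[!terms %in% names(records)]
  vals <- sapply(terms, function(tm)
    if (tm %in% names(records)) records[[tm]] else rep(0, nrow(records)))
  vals <- matrix(vals, nrow = nrow(records),
                 dimnames = list(NULL, terms))
  ub_folded <- "urey_bradley" %in% names(records)
  if (ub_folded) vals[, "angle"] <- vals[, "angle"] + records$urey_bradley

  present_any <- ncol(vals[, setdiff(terms, absent), drop = FALSE]) > 0
  bsum <- rowSums(abs(vals))
  share_ok <- present_any & bsum > 0
  shares <- if (any(share_ok)) {
    colMeans(abs(vals[share_ok, , drop = FALSE]) / bsum[share_ok])
  } else {
    stats::setNames(rep(NA_real_, 3), terms)
  }

  structure(
    list(kinetic_fraction = mean(kin_frac, na.rm = TRUE),
         potential_fraction = mean(pot_frac, na.rm = TRUE),
         bonded_shares = shares,
         urey_bradley_folded = ub_folded,
         absent_terms = absent,
         flagged_frames = which(flagged),
         per_frame = data.frame(frame = seq_len(nrow(records)),
                                kinetic_fraction = kin_frac,
                                potential_fraction = pot_frac)),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy_breakdown: kinetic %.3f / potential %.3f of total\n",
              x$kinetic_fraction, x$potential_fraction))
  cat(sprintf("  bonded shares: bond %.3f, angle %.3f, dihedral %.3f%s\n",
              x$bonded_shares[["bond"]], x$bonded_shares[["angle"]],
              x$bonded_shares[["dihedral"]],
              if (x$urey_bradley_folded) " (Urey-Bradley folded into angle)"
              else ""))
  if (length(x$absent_terms)) {
    cat("  absent terms:", paste(x$absent_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export an energy breakdown as JSON plus a per-frame TSV
#' @param breakdown an `energy_breakdown`.
#' @param json_path JSON summary path (NULL to skip).
#' @param tsv_path per-frame TSV path (NULL to skip).
#' @return `breakdown`, invisibly.
#' @export
write_energy_breakdown <- function(breakdown, json_path = NULL,
                                   tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(kinetic_fraction = breakdown$kinetic_fraction,
           potential_fraction = breakdown$potential_fraction,
           bonded_shares = as.list(breakdown$bonded_shares),
           urey_bradley_folded = breakdown$urey_bradley_folded,
           absent_terms = breakdown$absent_terms,
           n_flagged_frames = length(breakdown$flagged_frames)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(breakdown$per_frame, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(breakdown)
}
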
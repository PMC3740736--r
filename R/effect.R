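# Expected versus actual supplementation effect.
#
# Expected: rank amino acids by availability minus need, where
# availability is the plasma concentration divided by the control
# protein-synthesis flux (complexes' worth of each amino acid the plasma
# could sustain) and need is the residue count per complex. The most
# negative difference is the strongest expected limitation (rank 1).
# Actual: rank amino acids by the smallest subset size at which they
# first enter a best-per-size supplement subset. The two orderings
# coincide when availability is the only mechanism, and diverge once
# catabolic or biosynthetic routes let amino acids double as fuel.

#' Amino-acid availability in complexes' worth
#'
#' `available(aa) = concentration(aa) / control_flux`: how many
#' contractile complexes the plasma supply of each amino acid could
#' build per unit time at the control synthesis flux. Dimensionless in
#' the complex count, homogeneous of degree zero under joint rescaling
#' of concentrations and flux.
#'
#' @param cond an `mf_condition`
#' @param control_flux positive control objective value
#' @param aa_set amino acids to report, default all 20
#' @return named numeric vector
#' @export
availability_counts <- function(cond, control_flux,
                                aa_set = amino_acids()) {
  stopifnot(inherits(cond, "mf_condition"))
  if (!is.numeric(control_flux) || control_flux <= 0)
    stop("control_flux must be positive")
  aa <- intersect(aa_set, names(cond$uptake_bounds))
  setNames(cond$uptake_bounds[aa] / control_flux, aa)
}

#' Expected supplementation effect
#'
#' Ranks amino acids ascending by `available - needed`; rank 1 is the
#' most limiting (largest shortfall). Exact ties are broken
#' alphabetically and flagged.
#'
#' @param needed named vector of residues per complex
#'   (see [per_complex_need()])
#' @param available named vector from [availability_counts()]; key sets
#'   must match
#' @return data.frame with `amino_acid`, `needed`, `available`,
#'   `difference`, `expected_rank`, `tie`, `essentiality`
#' @export
expected_effect <- function(needed, available) {
  if (!setequal(names(needed), names(available)))
    stop("needed and available cover different amino-acid sets")
  aa <- sort(names(needed))
  diff <- available[aa] - needed[aa]
  ord <- order(diff, aa)
  out <- data.frame(amino_acid = aa[ord],
                    needed = as.numeric(needed[aa][ord]),
                    available = as.numeric(available[aa][ord]),
                    difference = as.numeric(diff[ord]),
                    expected_rank = seq_along(aa),
                    stringsAsFactors = FALSE)
  out$tie <- duplicated(out$difference) |
    duplicated(out$difference, fromLast = TRUE)
  ess <- amino_acid_essentiality()
  out$essentiality <- unname(ess[out$amino_acid])
  out
}

#' Actual supplementation effect
#'
#' Orders amino acids by the smallest subset size at which they first
#' appear in a best-per-size subset of the sweep (alphabetical within a
#' size). Amino acids never appearing in any best subset are unranked
#' (`NA`).
#'
#' @param results an `mf_sweep` from [sweep_supplements()]
#' @param aa_set amino acids to report, default all 20
#' @return data.frame with `amino_acid`, `first_size`, `actual_rank`
#' @export
actual_effect <- function(results, aa_set = amino_acids()) {
  if (!inherits(results, "mf_sweep") || nrow(results) == 0L)
    stop("need a non-empty sweep result")
  best <- best_per_size(results)
  best <- best[best$improved, , drop = FALSE]
  first <- setNames(rep(NA_integer_, length(aa_set)), aa_set)
  for (i in seq_len(nrow(best))) {
    members <- strsplit(best$subset[i], ",", fixed = TRUE)[[1L]]
    members <- intersect(members, aa_set)
    newly <- members[is.na(first[members])]
    first[newly] <- best$size[i]
  }
  ranked <- !is.na(first)
  ord <- order(first, names(first), na.last = TRUE)
  out <- data.frame(amino_acid = names(first)[ord],
                    first_size = as.integer(first[ord]),
                    stringsAsFactors = FALSE)
  out$actual_rank <- ifelse(is.na(out$first_size), NA_integer_,
                            seq_len(nrow(out)))
  out
}

#' Compare expected and actual supplementation effects
#'
#' Joins the two rankings per amino acid and reports the rank shift and
#' a Spearman-footrule-style agreement statistic: the sum of
#' `|expected_rank - actual_rank|` over amino acids ranked in both
#' (smaller is closer agreement; zero means identical order).
#'
#' @param expected from [expected_effect()]
#' @param actual from [actual_effect()]
#' @return an `mf_effect_comparison`: data.frame with per-amino-acid
#'   ranks and `rank_shift` (`expected_rank - actual_rank`; positive
#'   means a stronger actual than expected effect), with attribute
#'   `footrule`
#' @export
compare_expected_actual <- function(expected, actual) {
  out <- merge(expected[, c("amino_acid", "difference", "expected_rank",
                            "essentiality")],
               actual[, c("amino_acid", "first_size", "actual_rank")],
               by = "amino_acid", all = TRUE)
  out$rank_shift <- out$expected_rank - out$actual_rank
  both <- !is.na(out$expected_rank) & !is.na(out$actual_rank)
  # re-rank the expected side within the co-ranked subset so the footrule
  # compares permutations of the same length
  sub <- out[both, , drop = FALSE]
  foot <- if (nrow(sub) > 0L)
    sum(abs(rank(sub$expected_rank) - rank(sub$actual_rank)))
  else NA_real_
  out <- out[order(out$expected_rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "footrule") <- foot
  class(out) <- c("mf_effect_comparison", "data.frame")
  out
}

#' Export an effect table as TSV
#'
#' The header comments state the availability convention (plasma
#' concentration used numerically, divided by the control flux) and the
#' actual-effect ordering rule (first appearance in best-per-size
#' subsets).
#'
#' @param comparison an `mf_effect_comparison`
#' @param path output file
#' @return the path, invisibly
#' @export
export_effect_tsv <- function(comparison, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# availability = plasma concentration (mmol/L) / control flux",
    "# actual rank = first appearance in best-per-size supplement subsets",
    sprintf("# footrule rank-agreement statistic: %s",
            format(attr(comparison, "footrule")))), con)
  write.table(as.data.frame(comparison), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
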
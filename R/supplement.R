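# In-silico supplementation: relax amino-acid uptake bounds and sweep
# all 1..k combinations for the best protein-synthesis objective.

#' Simulate supplementation of a set of amino acids
#'
#' Returns a copy of the model in which the uptake upper bound of every
#' subset member is raised to `cap`, the conventional "unlimited" flux
#' (99999). All other bounds are untouched; the input model is not
#' modified. Supplementing is idempotent and commutes across subsets.
#'
#' @param model an `mf_model` (typically after [apply_condition()])
#' @param subset character vector of amino-acid names (must be among the
#'   canonical 20)
#' @param cap relaxed upper bound, default 99999
#' @param exchange_prefix uptake reaction prefix, default `"EX_"`
#' @return the relaxed model
#' @export
supplement <- function(model, subset, cap = 99999,
                       exchange_prefix = "EX_") {
  bad <- setdiff(subset, amino_acids())
  if (length(bad))
    stop("not amino acids: ", paste(bad, collapse = ", "))
  for (aa in subset) {
    rid <- paste0(exchange_prefix, aa)
    if (!(rid %in% model$reactions$id))
      stop("no uptake exchange reaction for amino acid '", aa, "'")
    model <- set_bounds(model, rid, upper = cap)
  }
  model
}

#' Exhaustive supplementation sweep
#'
#' Applies the condition, solves the control, then re-solves the model
#' for every subset of 1..`k_max` amino acids with relaxed uptake
#' bounds. A subset counts as improving when its optimum exceeds the
#' control by more than `tol`.
#'
#' With `prune = TRUE` the objective under relaxing *all* candidate
#' amino acids at once is computed first; it is a proven upper bound for
#' every subset (bound enlargement can only help a maximization), so if
#' it does not beat the control every subset is recorded at the control
#' value without re-solving. Pruning never changes best-per-size
#' results.
#'
#' @param model an `mf_model` with the demand objective set
#' @param cond an `mf_condition`
#' @param k_max largest subset size, default 7 (combinatorial growth
#'   makes larger sweeps expensive)
#' @param prune skip provably non-improving subsets
#' @param aa_set candidate amino acids; by default every canonical amino
#'   acid that has an uptake exchange reaction in the model
#' @param cap relaxed bound, default 99999
#' @param tol improvement threshold, default 1e-9
#' @return an `mf_sweep`: data.frame with columns `size`, `subset`
#'   (comma-joined, alphabetical), `objective`, `improved`; attributes
#'   `control` (objective value), `condition`, `k_max`
#' @export
sweep_supplements <- function(model, cond, k_max = 7L, prune = FALSE,
                              aa_set = NULL, cap = 99999,
                              tol = 1e-9) {
  if (k_max < 1L) stop("k_max must be at least 1")
  if (is.null(aa_set))
    aa_set <- intersect(amino_acids(),
                        sub("^EX_", "", grep("^EX_", model$reactions$id,
                                             value = TRUE)))
  if (length(aa_set) == 0L) stop("no amino-acid uptake exchanges in model")
  bounded <- apply_condition(model, cond)
  control <- solve_fba(bounded)
  if (control$status != "optimal")
    stop("control condition is ", control$status,
         ": check uptake bounds and demand stoichiometry")
  c0 <- control$objective_value
  aa_set <- sort(aa_set)

  skip_all <- FALSE
  if (prune) {
    full <- solve_fba(supplement(bounded, aa_set, cap = cap))
    if (full$status == "optimal" && full$objective_value <= c0 + tol)
      skip_all <- TRUE  # nothing can improve: every optimum equals control
  }

  rows <- list()
  for (k in seq_len(k_max)) {
    if (k > length(aa_set)) break
    subsets <- combn(aa_set, k, simplify = FALSE)
    for (sub in subsets) {
      if (skip_all) {
        obj <- c0
      } else {
        sol <- solve_fba(supplement(bounded, sub, cap = cap))
        if (sol$status != "optimal")
          stop("supplemented model became ", sol$status, " for subset ",
               paste(sub, collapse = ","))
        obj <- sol$objective_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, subset = paste(sub, collapse = ","),
        objective = obj, improved = obj > c0 + tol,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "control") <- c0
  attr(out, "condition") <- cond$name
  attr(out, "k_max") <- k_max
  class(out) <- c("mf_sweep", "data.frame")
  out
}

#' Best supplement subset per size
#'
#' For each subset size in a sweep, the subset with the maximal
#' objective. Ties are broken lexicographically on the alphabetical
#' subset string and flagged in the `tie` column.
#'
#' @param results an `mf_sweep` from [sweep_supplements()]
#' @param tol equality tolerance for tie detection
#' @return data.frame with `size`, `subset`, `objective`, `improved`,
#'   `tie`; attribute `control` carried over
#' @export
best_per_size <- function(results, tol = 1e-9) {
  if (!inherits(results, "mf_sweep") || nrow(results) == 0L)
    stop("need a non-empty sweep result")
  out <- lapply(split(results, results$size), function(df) {
    top <- max(df$objective)
    cand <- df[df$objective >= top - tol * (1 + abs(top)), , drop = FALSE]
    cand <- cand[order(cand$subset), , drop = FALSE]
    data.frame(size = cand$size[1L], subset = cand$subset[1L],
               objective = cand$objective[1L], improved = cand$improved[1L],
               tie = nrow(cand) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "control") <- attr(results, "control")
  attr(out, "condition") <- attr(results, "condition")
  out
}

#' Export a sweep as TSV
#'
#' @param results an `mf_sweep`
#' @param path output file
#' @return the path, invisibly
#' @export
export_sweep_tsv <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
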
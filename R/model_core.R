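#' @importFrom stats setNames runif rnorm
#' @importFrom utils combn read.delim write.table head
NULL

.compartments <- c("extracellular", "cytosol", "mitochondrion")

#' Create a metabolite
#'
#' @param id unique, non-empty identifier
#' @param name display name (defaults to `id`)
#' @param compartment one of `"extracellular"`, `"cytosol"`,
#'   `"mitochondrion"`
#' @return an object of class `mf_metabolite`
#' @export
metabolite <- function(id, name = id, compartment = "cytosol") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  compartment <- match.arg(compartment, .compartments)
  structure(list(id = id, name = name, compartment = compartment),
            class = "mf_metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative for consumed
#' metabolites, positive for produced ones. Bounds are fluxes in the
#' model's (arbitrary) concentration-per-time unit.
#'
#' @param id unique, non-empty identifier
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#' @param lower_bound,upper_bound flux bounds, `lower_bound <= upper_bound`
#' @param name display name
#' @param subsystem free-text tag (`"exchange"`, `"demand"`,
#'   `"aa-catabolism"`, ...)
#' @return an object of class `mf_reaction`
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = 99999, name = id, subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "': stoichiometry must be non-empty")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a fully named vector")
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound))
    stop("bounds must be numeric")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 subsystem = subsystem),
            class = "mf_reaction")
}

#' Assemble a stoichiometric model
#'
#' A model is an ordered collection of metabolites and reactions plus the
#' id of the objective reaction (for muscle models, the contractile
#' protein complex demand). Ordering is preserved, so the stoichiometry
#' matrix is reproducible.
#'
#' @param metabolites list of [metabolite()] objects
#' @param reactions list of [reaction()] objects
#' @param objective_id id of the objective reaction, or `NA`
#' @return an object of class `mf_model`
#' @seealso [validate_model()], [assemble_matrix()], [model_stats()]
#' @export
stoichiometric_model <- function(metabolites, reactions, objective_id = NA) {
  stopifnot(all(vapply(metabolites, inherits, TRUE, "mf_metabolite")),
            all(vapply(reactions, inherits, TRUE, "mf_reaction")))
  met <- data.frame(
    id = vapply(metabolites, `[[`, "", "id"),
    name = vapply(metabolites, `[[`, "", "name"),
    compartment = vapply(metabolites, `[[`, "", "compartment"),
    stringsAsFactors = FALSE)
  rxn <- data.frame(
    id = vapply(reactions, `[[`, "", "id"),
    name = vapply(reactions, `[[`, "", "name"),
    lower_bound = vapply(reactions, `[[`, 0, "lower_bound"),
    upper_bound = vapply(reactions, `[[`, 0, "upper_bound"),
    subsystem = vapply(reactions, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE)
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn$id
  structure(list(metabolites = met, reactions = rxn,
                 stoichiometry = stoich,
                 objective_id = as.character(objective_id)),
            class = "mf_model")
}

#' @export
print.mf_model <- function(x, ...) {
  cat("Stoichiometric model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  cat("  objective:",
      if (is.na(x$objective_id)) "<none>" else x$objective_id, "\n")
  invisible(x)
}

#' Validate a stoichiometric model
#'
#' Reports duplicate metabolite/reaction ids, stoichiometry entries that
#' reference metabolites absent from the model, inverted bounds
#' (`lower_bound > upper_bound`), orphan metabolites that appear in no
#' reaction, and an unresolvable objective id. An empty report means the
#' model is valid.
#'
#' @param model an `mf_model`
#' @return data.frame with columns `type`, `id`, `message`; zero rows iff
#'   valid
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "mf_model"))
  bad <- list()
  note <- function(type, id, message)
    bad[[length(bad) + 1L]] <<- data.frame(type = type, id = id,
                                           message = message,
                                           stringsAsFactors = FALSE)
  mids <- model$metabolites$id
  rids <- model$reactions$id
  for (d in unique(mids[duplicated(mids)]))
    note("duplicate_metabolite", d, "metabolite id occurs more than once")
  for (d in unique(rids[duplicated(rids)]))
    note("duplicate_reaction", d, "reaction id occurs more than once")
  for (d in intersect(mids, rids))
    note("id_collision", d, "id used for both a metabolite and a reaction")
  used <- character(0)
  for (rid in rids) {
    st <- model$stoichiometry[[rid]]
    dangling <- setdiff(names(st), mids)
    for (d in dangling)
      note("dangling_metabolite", rid,
           paste0("references unknown metabolite '", d, "'"))
    used <- c(used, names(st))
  }
  inv <- which(model$reactions$lower_bound > model$reactions$upper_bound)
  for (i in inv)
    note("bound_inversion", rids[i],
         sprintf("lower bound %g exceeds upper bound %g",
                 model$reactions$lower_bound[i],
                 model$reactions$upper_bound[i]))
  for (o in setdiff(mids, unique(used)))
    note("orphan_metabolite", o, "metabolite appears in no reaction")
  if (!is.na(model$objective_id) && !(model$objective_id %in% rids))
    note("missing_objective", model$objective_id,
         "objective id does not resolve to a reaction")
  if (length(bad) == 0L)
    data.frame(type = character(0), id = character(0),
               message = character(0), stringsAsFactors = FALSE)
  else
    do.call(rbind, bad)
}

#' Assemble the stoichiometry matrix
#'
#' Returns the dense matrix S (metabolite rows x reaction columns) whose
#' entry (i, j) is the signed coefficient of metabolite i in reaction j,
#' zero where the metabolite does not take part. Steady state is the
#' constraint `S %*% v == 0`.
#'
#' @param model a valid `mf_model`
#' @return numeric matrix with metabolite ids as rownames and reaction
#'   ids as colnames
#' @export
assemble_matrix <- function(model) {
  rep <- validate_model(model)
  rep <- rep[rep$type != "orphan_metabolite", , drop = FALSE]  # orphans allowed in S
  if (nrow(rep) > 0L)
    stop("model integrity error: ", rep$type[1L], " (", rep$id[1L], "): ",
         rep$message[1L])
  mids <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(rids)) {
    st <- model$stoichiometry[[rids[j]]]
    S[names(st), j] <- st
  }
  S
}

#' Model dimensions, rank and conserved pools
#'
#' The numerical rank of S is computed from its singular values; the
#' degrees of freedom reported is the conserved-pool count,
#' `n_metabolites - rank` (the dimension of the left null space: the
#' number of invariant metabolite combinations at steady state).
#'
#' @param model a valid `mf_model`
#' @param tol rank tolerance; default `max(dim(S)) * eps * max(sv)`
#' @return an `mf_model_stats` list: `n_reactions`, `n_metabolites`,
#'   `rank`, `dof`
#' @export
model_stats <- function(model, tol = NULL) {
  S <- assemble_matrix(model)
  sv <- svd(S, nu = 0, nv = 0)$d
  if (is.null(tol))
    tol <- max(dim(S)) * .Machine$double.eps * max(sv, 0)
  r <- sum(sv > tol)
  structure(list(n_reactions = ncol(S), n_metabolites = nrow(S),
                 rank = r, dof = nrow(S) - r),
            class = "mf_model_stats")
}

#' @export
print.mf_model_stats <- function(x, ...) {
  cat(sprintf(
    "%d reactions, %d metabolites; rank %d, %d conserved pools (n_metabolites - rank)\n",
    x$n_reactions, x$n_metabolites, x$rank, x$dof))
  invisible(x)
}

#' @export
`==.mf_model_stats` <- function(e1, e2) {
  all(unlist(e1) == unlist(e2))
}

#' Export the stoichiometry matrix or a validation report as TSV
#'
#' @param model an `mf_model`
#' @param path output file
#' @return the path, invisibly
#' @export
export_matrix_tsv <- function(model, path) {
  S <- assemble_matrix(model)
  df <- data.frame(metabolite = rownames(S), S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_matrix_tsv
#' @export
export_validation_tsv <- function(model, path) {
  write.table(validate_model(model), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- internal model helpers ------------------------------------------------

.rxn_index <- function(model, rid) {
  i <- match(rid, model$reactions$id)
  if (is.na(i)) stop("no reaction with id '", rid, "'")
  i
}

#' Change the flux bounds of one reaction
#'
#' @param model an `mf_model`
#' @param rid reaction id
#' @param lower,upper new bounds; `NULL` leaves a bound untouched
#' @return the modified model (the input is not changed)
#' @export
set_bounds <- function(model, rid, lower = NULL, upper = NULL) {
  i <- .rxn_index(model, rid)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  model
}

#' Append a reaction to a model
#'
#' Metabolites referenced by the reaction but absent from the model are
#' added to the stated compartment.
#'
#' @inheritParams set_bounds
#' @param rxn an [reaction()] object
#' @param compartment compartment for any newly created metabolites
#' @return the extended model
#' @export
add_reaction <- function(model, rxn, compartment = "cytosol") {
  stopifnot(inherits(rxn, "mf_reaction"))
  if (rxn$id %in% model$reactions$id)
    stop("reaction id '", rxn$id, "' already present")
  new_mets <- setdiff(names(rxn$stoichiometry), model$metabolites$id)
  if (length(new_mets))
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_mets, name = new_mets, compartment = compartment,
                 stringsAsFactors = FALSE))
  model$reactions <- rbind(model$reactions,
    data.frame(id = rxn$id, name = rxn$name,
               lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
               subsystem = rxn$subsystem, stringsAsFactors = FALSE))
  model$stoichiometry[[rxn$id]] <- rxn$stoichiometry
  model
}
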
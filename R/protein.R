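# Contractile-protein-complex construction.
#
# The synthesis objective is one unit of the sarcomeric thin/thick
# filament assembly: 7 actin : 7 myosin : 1 tropomyosin dimer :
# 1 troponin complex. Myosin expands to a fiber-type-specific heavy
# chain plus the light chain kinase and the phosphorylatable light
# chain; the tropomyosin dimer is two chains of the type-appropriate
# isoform; the troponin complex is one each of the C, I and T subunits.

.muscle_types <- c("type1", "type2a", "type2x", "type2b")

#' Amino-acid composition of a protein
#'
#' @param protein_id identifier
#' @param counts named numeric vector of residue counts; missing amino
#'   acids are filled with zero, unknown names are an error
#' @return an `mf_composition`: named integer vector over all 20 amino
#'   acids with attribute `protein_id`
#' @export
protein_composition <- function(protein_id, counts) {
  aa <- amino_acids()
  bad <- setdiff(names(counts), aa)
  if (length(bad))
    stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("residue counts must be non-negative integers")
  full <- setNames(integer(length(aa)), aa)
  full[names(counts)] <- as.integer(counts)
  if (sum(full) < 1L)
    stop("protein '", protein_id, "' has no residues")
  structure(full, protein_id = protein_id, class = "mf_composition")
}

#' Read protein compositions from TSV
#'
#' Expects a `protein_id` column plus one column per amino acid (full
#' lowercase names). Returns a named list of [protein_composition()]
#' objects.
#'
#' @param path TSV file
#' @return named list of `mf_composition`
#' @export
read_compositions_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"protein_id" %in% names(df))
    stop("composition table needs a 'protein_id' column")
  out <- lapply(seq_len(nrow(df)), function(i) {
    counts <- unlist(df[i, intersect(names(df), amino_acids())])
    protein_composition(df$protein_id[i], counts)
  })
  names(out) <- df$protein_id
  out
}

#' Count residues from FASTA sequence records
#'
#' Reads amino-acid sequences and tallies each record into a
#' composition. Non-standard residue codes (B, Z, X, U, O) are dropped
#' with a warning.
#'
#' @param path FASTA file of protein sequences
#' @return named list of `mf_composition` keyed by record id
#' @export
read_compositions_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*(\\S+).*", "\\1", lines[idx])
  ends <- c(idx[-1L] - 1L, length(lines))
  dropped <- 0L
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    seqchars <- strsplit(toupper(
      paste(lines[(idx[i] + 1L):ends[i]], collapse = "")), "")[[1L]]
    known <- seqchars %in% names(.aa_one_letter)
    dropped <- dropped + sum(!known)
    tab <- table(.aa_one_letter[seqchars[known]])
    out[[i]] <- protein_composition(ids[i], setNames(as.integer(tab),
                                                     names(tab)))
  }
  if (dropped > 0L)
    warning(dropped, " non-standard residue(s) dropped")
  names(out) <- ids
  out
}

#' The canonical contractile-complex recipe for a fiber type
#'
#' Components and multiplicities of the 7:7:1:1 assembly. The type 1 and
#' type 2x fibers share a myosin heavy chain; tropomyosin isoform 1
#' belongs to type 1 fibers and isoform 2 to the fast types; troponin
#' subunits come in a slow (1) and a fast (2) set.
#'
#' @param muscle_type `"type1"`, `"type2a"`, `"type2x"` or `"type2b"`
#' @return an `mf_recipe`: data.frame with `protein_id`, `multiplicity`,
#'   plus attribute `muscle_type`
#' @export
complex_recipe <- function(muscle_type = c("type2a", "type1", "type2x",
                                           "type2b")) {
  muscle_type <- match.arg(muscle_type)
  myhc <- switch(muscle_type,
                 type1 = "myhc_1_2x", type2x = "myhc_1_2x",
                 type2a = "myhc_2a", type2b = "myhc_2b")
  tpm <- if (muscle_type == "type1") "tpm_1" else "tpm_2"
  tnn_set <- if (muscle_type == "type1") "1" else "2"
  comp <- data.frame(
    protein_id = c("actin", myhc, "mylk", "mylp", tpm,
                   paste0(c("tnnc_", "tnni_", "tnnt_"), tnn_set)),
    multiplicity = c(7L, 7L, 7L, 7L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  structure(comp, muscle_type = muscle_type, class = c("mf_recipe",
                                                       "data.frame"))
}

#' Total amino-acid demand of one contractile complex
#'
#' Sums residue counts over the recipe components weighted by their
#' multiplicities.
#'
#' @param recipe an [complex_recipe()] (or any `mf_recipe`)
#' @param compositions named list of [protein_composition()] covering
#'   every protein in the recipe
#' @return named integer vector over the 20 amino acids
#' @export
complex_aa_demand <- function(recipe, compositions) {
  missing <- setdiff(recipe$protein_id, names(compositions))
  if (length(missing))
    stop("no composition for: ", paste(missing, collapse = ", "))
  demand <- setNames(numeric(20L), amino_acids())
  for (i in seq_len(nrow(recipe)))
    demand <- demand +
      recipe$multiplicity[i] * compositions[[recipe$protein_id[i]]]
  if (sum(demand) <= 0) stop("recipe demands no residues")
  storage.mode(demand) <- "integer"
  demand
}

#' @rdname complex_aa_demand
#' @param muscle_type fiber type passed to [complex_recipe()]
#' @export
per_complex_need <- function(muscle_type, compositions) {
  complex_aa_demand(complex_recipe(muscle_type), compositions)
}

#' Assemble the demand recipe for a fiber type
#'
#' Bundles the per-complex amino-acid demand with the peptide-bond
#' energy cost. Bonds per complex are total residues minus the number of
#' polypeptide chains (each chain has length - 1 bonds); each bond costs
#' `energy_cost_per_bond` ATP-equivalents, by default 4 (two ATP for
#' amino-acid activation plus two GTP for ribosomal elongation).
#'
#' @inheritParams complex_aa_demand
#' @param energy_cost_per_bond ATP-equivalents per peptide bond
#' @return an `mf_demand_recipe`: list with `aa_demand`, `n_chains`,
#'   `n_bonds`, `energy_cost_per_bond`, `muscle_type`
#' @export
demand_recipe <- function(recipe, compositions, energy_cost_per_bond = 4) {
  demand <- complex_aa_demand(recipe, compositions)
  n_chains <- sum(recipe$multiplicity)
  structure(list(aa_demand = demand,
                 n_chains = n_chains,
                 n_bonds = sum(demand) - n_chains,
                 energy_cost_per_bond = energy_cost_per_bond,
                 muscle_type = attr(recipe, "muscle_type")),
            class = "mf_demand_recipe")
}

#' Build the contractile-complex demand reaction
#'
#' Produces the irreversible objective reaction: consumes the
#' per-complex amino-acid demand plus the peptide-bond energy, produces
#' one unit of the complex pseudo-metabolite. The bond cost is split
#' between ATP hydrolysis (`atp + h2o -> adp + pi`, collapsed) and GTP
#' hydrolysis according to `gtp_fraction`; set `gtp_fraction = 0` for a
#' single ATP-equivalent currency (as the synthetic toy models use).
#'
#' @param demand an [demand_recipe()]
#' @param muscle_type fiber type; defaults to the recipe's
#' @param aa_suffix compartment suffix appended to amino-acid ids
#' @param gtp_fraction fraction of the bond cost paid as GTP, default 0.5
#' @param cap upper flux bound of the reaction
#' @return an `mf_reaction` with id `DM_contractile_<type>`
#' @export
build_demand_reaction <- function(demand, muscle_type = NULL,
                                  aa_suffix = "_c", gtp_fraction = 0.5,
                                  cap = 99999) {
  stopifnot(inherits(demand, "mf_demand_recipe"))
  if (is.null(muscle_type)) muscle_type <- demand$muscle_type
  aa <- demand$aa_demand[demand$aa_demand > 0]
  if (length(aa) == 0L) stop("demand has no positive amino-acid entries")
  st <- setNames(-as.numeric(aa), paste0(names(aa), aa_suffix))
  energy <- demand$energy_cost_per_bond * demand$n_bonds
  atp <- energy * (1 - gtp_fraction)
  gtp <- energy * gtp_fraction
  if (atp > 0)
    st <- c(st, atp_c = -atp, adp_c = atp)
  if (gtp > 0)
    st <- c(st, gtp_c = -gtp, gdp_c = gtp)
  if (energy > 0)
    st <- c(st, pi_c = energy)
  st[paste0("contractile_", muscle_type, "_c")] <- 1
  reaction(paste0("DM_contractile_", muscle_type), st,
           lower_bound = 0, upper_bound = cap,
           name = paste("contractile protein complex synthesis,",
                        muscle_type),
           subsystem = "demand")
}
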
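# Synthetic stoichiometric models with known analytic optima.
#
# Two tiers: a pure assembly model (amino-acid exchanges feeding a
# single demand reaction; the optimum has the closed form
# min_aa concentration/composition) and a muscle-like model that adds a
# lumped carbohydrate/lipid energy pathway, amino-acid catabolism into
# ATP, optional non-essential interconversion and secretion routes —
# the structural features the supplementation analysis assumes.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic toy model
#'
#' Unset compositions and concentrations are drawn reproducibly from
#' the seed: residue counts uniform on 1..60, concentrations log-normal
#' around 0.12 mmol/L (the order of magnitude of plasma amino-acid
#' levels), floored at 0.003. Amino acids are the first
#' `n_amino_acids` canonical names in alphabetical order unless
#' `composition` names others.
#'
#' @param n_amino_acids 2..20
#' @param composition named residue counts per complex; `NULL` = random
#' @param concentrations named plasma levels (mmol/L); `NULL` = random
#' @param essential_set subset that cannot be synthesized; default the
#'   truly essential amino acids among those present
#' @param allow_interconversion add non-essential biosynthesis routes
#'   (muscle-like models only)
#' @param energy_pathway add the lumped energy metabolism (muscle-like
#'   models only)
#' @param energy_cost_per_bond ATP per peptide bond in the demand
#'   reaction; defaults to 4 when the energy pathway is on, else 0
#' @param seed RNG seed for the random fields
#' @param glucose,palmitate,tetradecanoate default uptake bounds of the
#'   energy carriers (fasting plasma means)
#' @param atp_per_glucose,atp_per_fatty_acid,atp_per_aa lumped ATP
#'   yields of the catabolic routes
#' @param catabolizable amino acids with an ATP-yielding catabolic
#'   route; default the muscle-oxidizable set (BCAAs, lysine, serine,
#'   and the glucogenic non-essentials) among those present
#' @param n_chains polypeptide chains per complex (bonds = residues -
#'   chains); 1 for a single toy chain, 33 for the full contractile
#'   assembly
#' @return an `mf_toy_spec`
#' @export
toy_spec <- function(n_amino_acids = 20L, composition = NULL,
                     concentrations = NULL, essential_set = NULL,
                     allow_interconversion = FALSE, energy_pathway = FALSE,
                     energy_cost_per_bond = if (energy_pathway) 4 else 0,
                     seed = 1L, glucose = 5, palmitate = 0.125,
                     tetradecanoate = 0.230, atp_per_glucose = 30,
                     atp_per_fatty_acid = 100, atp_per_aa = 20,
                     catabolizable = NULL, n_chains = 1L) {
  if (n_amino_acids < 2L || n_amino_acids > 20L)
    stop("n_amino_acids must be between 2 and 20")
  aa <- if (!is.null(composition)) sort(names(composition))
        else amino_acids()[seq_len(n_amino_acids)]
  .with_seed(seed, {
    if (is.null(composition))
      composition <- setNames(sample(1:60, length(aa), replace = TRUE), aa)
    if (is.null(concentrations))
      concentrations <- setNames(
        pmax(round(exp(rnorm(length(aa), log(0.12), 0.9)), 3), 0.003), aa)
  })
  composition <- composition[aa]
  concentrations <- concentrations[aa]
  if (all(composition <= 0)) stop("composition must be positive somewhere")
  if (is.null(essential_set))
    essential_set <- intersect(
      names(which(amino_acid_essentiality() == "essential")), aa)
  if (!all(essential_set %in% aa))
    stop("essential_set must be a subset of the amino acids present")
  if (is.null(catabolizable))
    catabolizable <- intersect(
      c(bcaa(), "lysine", "serine", "alanine", "asparagine", "aspartate",
        "glutamate", "glutamine", "glycine", "proline"), aa)
  structure(list(
    aa = aa, composition = composition, concentrations = concentrations,
    essential_set = essential_set,
    allow_interconversion = allow_interconversion,
    energy_pathway = energy_pathway,
    energy_cost_per_bond = energy_cost_per_bond, seed = seed,
    glucose = glucose, palmitate = palmitate,
    tetradecanoate = tetradecanoate, atp_per_glucose = atp_per_glucose,
    atp_per_fatty_acid = atp_per_fatty_acid, atp_per_aa = atp_per_aa,
    catabolizable = catabolizable, n_chains = as.integer(n_chains)),
    class = "mf_toy_spec")
}

.toy_demand_reaction <- function(spec, cap = 99999) {
  counts <- spec$composition[spec$composition > 0]
  dr <- structure(list(aa_demand = counts, n_chains = spec$n_chains,
                       n_bonds = sum(counts) - spec$n_chains,
                       energy_cost_per_bond = spec$energy_cost_per_bond,
                       muscle_type = "toy"),
                  class = "mf_demand_recipe")
  build_demand_reaction(dr, gtp_fraction = 0, cap = cap)
}

#' Build a pure assembly model
#'
#' Amino-acid uptake exchanges (upper bound = concentration) feeding the
#' complex demand reaction and its sink; nothing else. The maximal
#' demand flux equals [closed_form_optimum()]:
#' `min_aa concentration(aa) / composition(aa)`.
#'
#' @param spec an [toy_spec()] with `energy_pathway = FALSE` and
#'   `allow_interconversion = FALSE`
#' @param cap unbounded flux cap
#' @return an `mf_model` with objective `DM_contractile_toy`
#' @export
make_assembly_model <- function(spec, cap = 99999) {
  stopifnot(inherits(spec, "mf_toy_spec"))
  if (spec$energy_pathway || spec$allow_interconversion)
    stop("assembly models have no energy pathway or interconversion")
  if (spec$energy_cost_per_bond != 0)
    stop("assembly models carry no energy cost")
  mets <- c(lapply(paste0(spec$aa, "_c"), metabolite),
            list(metabolite("contractile_toy_c",
                            "contractile complex (toy)")))
  rxns <- lapply(spec$aa, function(a)
    reaction(paste0("EX_", a), setNames(1, paste0(a, "_c")),
             0, spec$concentrations[[a]], subsystem = "exchange"))
  rxns <- c(rxns, list(
    .toy_demand_reaction(spec, cap),
    reaction("SINK_contractile", c(contractile_toy_c = -1), 0, cap,
             subsystem = "sink")))
  stoichiometric_model(mets, rxns, objective_id = "DM_contractile_toy")
}

#' Closed-form optimum of an assembly model
#'
#' `min` over amino acids with positive composition of
#' `concentration / composition`: the single most limiting building
#' block caps the whole assembly flux.
#'
#' @param spec an assembly-model [toy_spec()]
#' @return the analytic optimal objective value
#' @export
closed_form_optimum <- function(spec) {
  stopifnot(inherits(spec, "mf_toy_spec"))
  if (spec$energy_pathway || spec$allow_interconversion)
    stop("closed form holds only for pure assembly models")
  used <- spec$composition > 0
  min(spec$concentrations[used] / spec$composition[used])
}

#' Build a muscle-like toy model
#'
#' The assembly skeleton plus: lumped glycolysis/oxidation routes
#' turning glucose and the two fatty acids into ATP, catabolic routes
#' turning the oxidizable amino acids into ATP, optional biosynthesis of
#' non-essential amino acids from a glutamate hub (1 ATP each), amino
#' acid secretion routes, and a demand reaction that now pays
#' `energy_cost_per_bond` ATP per peptide bond. With generous energy the
#' optimum reduces to the assembly closed form; scarce energy pulls it
#' below, and supplementing a catabolizable amino acid can then raise
#' the optimum even when it is not the composition bottleneck (amino
#' acids as fuel).
#'
#' @param spec an [toy_spec()] with `energy_pathway = TRUE`
#' @param cap unbounded flux cap
#' @return an `mf_model` with objective `DM_contractile_toy`
#' @export
make_muscle_like_model <- function(spec, cap = 99999) {
  stopifnot(inherits(spec, "mf_toy_spec"))
  if (!spec$energy_pathway)
    stop("muscle-like models need energy_pathway = TRUE")
  if (spec$energy_cost_per_bond > 0 && spec$glucose <= 0 &&
      spec$palmitate <= 0 && spec$tetradecanoate <= 0 &&
      length(spec$catabolizable) == 0L)
    stop("infeasible spec: energy demand with no energy source")

  mets <- c(lapply(paste0(spec$aa, "_c"), metabolite),
            lapply(c("glucose_c", "palmitate_c", "tetradecanoate_c",
                     "atp_c", "adp_c", "pi_c"), metabolite),
            list(metabolite("contractile_toy_c",
                            "contractile complex (toy)")))
  rxns <- lapply(spec$aa, function(a)
    reaction(paste0("EX_", a), setNames(1, paste0(a, "_c")),
             0, spec$concentrations[[a]], subsystem = "exchange"))
  rxns <- c(rxns, lapply(spec$aa, function(a)
    reaction(paste0("SEC_", a), setNames(-1, paste0(a, "_c")),
             0, cap, subsystem = "secretion")))
  rxns <- c(rxns, list(
    reaction("EX_glucose", c(glucose_c = 1), 0, spec$glucose,
             subsystem = "exchange"),
    reaction("EX_palmitate", c(palmitate_c = 1), 0, spec$palmitate,
             subsystem = "exchange"),
    reaction("EX_tetradecanoate", c(tetradecanoate_c = 1), 0,
             spec$tetradecanoate, subsystem = "exchange"),
    reaction("GLYC_OX", c(glucose_c = -1, adp_c = -spec$atp_per_glucose,
                          pi_c = -spec$atp_per_glucose,
                          atp_c = spec$atp_per_glucose),
             0, cap, subsystem = "glycolysis"),
    reaction("FAO_palmitate",
             c(palmitate_c = -1, adp_c = -spec$atp_per_fatty_acid,
               pi_c = -spec$atp_per_fatty_acid,
               atp_c = spec$atp_per_fatty_acid),
             0, cap, subsystem = "beta-oxidation"),
    reaction("FAO_tetradecanoate",
             c(tetradecanoate_c = -1,
               adp_c = -round(0.9 * spec$atp_per_fatty_acid),
               pi_c = -round(0.9 * spec$atp_per_fatty_acid),
               atp_c = round(0.9 * spec$atp_per_fatty_acid)),
             0, cap, subsystem = "beta-oxidation")))
  for (a in spec$catabolizable) {
    y <- spec$atp_per_aa
    rxns <- c(rxns, list(
      reaction(paste0("CAT_", a),
               setNames(c(-1, -y, -y, y),
                        c(paste0(a, "_c"), "adp_c", "pi_c", "atp_c")),
               0, cap, subsystem = "aa-catabolism")))
  }
  if (spec$allow_interconversion) {
    hub <- if ("glutamate" %in% spec$aa) "glutamate"
           else setdiff(spec$aa, spec$essential_set)[1L]
    if (!is.na(hub)) {
      targets <- setdiff(setdiff(spec$aa, spec$essential_set), hub)
      for (a in targets)
        rxns <- c(rxns, list(
          reaction(paste0("SYN_", a),
                   setNames(c(-1, 1, -1, 1, 1),
                            c(paste0(hub, "_c"), paste0(a, "_c"),
                              "atp_c", "adp_c", "pi_c")),
                   0, cap, subsystem = "aa-biosynthesis")))
    }
  }
  rxns <- c(rxns, list(
    .toy_demand_reaction(spec, cap),
    reaction("SINK_contractile", c(contractile_toy_c = -1), 0, cap,
             subsystem = "sink")))
  stoichiometric_model(mets, rxns, objective_id = "DM_contractile_toy")
}

#' Emit a toy model and its condition profile to files
#'
#' Writes the SBML model and a TSV of the uptake bounds, the pair of
#' artifacts the pipeline consumes.
#'
#' @param spec an [toy_spec()]
#' @param sbml_path,condition_path output files
#' @return invisibly, a list with the two paths
#' @export
emit_toy_files <- function(spec, sbml_path, condition_path) {
  model <- if (spec$energy_pathway) make_muscle_like_model(spec)
           else make_assembly_model(spec)
  write_sbml(model, sbml_path)
  bounds <- c(spec$concentrations,
              if (spec$energy_pathway)
                c(glucose = spec$glucose, palmitate = spec$palmitate,
                  tetradecanoate = spec$tetradecanoate))
  write.table(data.frame(metabolite = names(bounds),
                         concentration = as.numeric(bounds)),
              condition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sbml = sbml_path, condition = condition_path))
}
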
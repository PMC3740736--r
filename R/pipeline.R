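# End-to-end conveniences: the packaged synthetic muscle model and the
# full supplementation analysis around it.

#' Packaged synthetic contractile-protein compositions
#'
#' Loads the composition table shipped in
#' `inst/extdata/contractile_compositions_synthetic.tsv`: residue counts
#' for actin, the three myosin heavy chains, the two myosin light
#' chains, the two tropomyosin isoforms and the two troponin subunit
#' sets. These are synthetic stand-ins drawn from average proteome
#' amino-acid frequencies at realistic chain lengths — not
#' database-verified sequences — adequate for exercising and validating
#' the pipeline, not for quantitative claims about real fiber types.
#'
#' @return named list of [protein_composition()] objects
#' @export
contractile_compositions <- function() {
  read_compositions_tsv(system.file(
    "extdata", "contractile_compositions_synthetic.tsv",
    package = "muscleflux", mustWork = TRUE))
}

#' Build the synthetic muscle model for a fiber type
#'
#' A muscle-like stoichiometric model whose demand reaction is the full
#' contractile complex (7 actin : 7 myosin : 1 tropomyosin dimer :
#' 1 troponin complex, 33 chains) for the requested fiber type, built
#' from the packaged synthetic compositions, with uptake bounds from the
#' requested plasma state. Energy metabolism is the lumped
#' glucose/fatty-acid/amino-acid ATP routes of
#' [make_muscle_like_model()].
#'
#' @param state `"fasting"` or `"post_absorptive"`
#' @param muscle_type fiber type, default `"type2a"`
#' @param energy_cost_per_bond ATP-equivalents per peptide bond,
#'   default 4
#' @param allow_interconversion add non-essential biosynthesis routes,
#'   default TRUE
#' @param compositions override the packaged composition list
#' @return list with `model` (bounds already set to the state's plasma
#'   profile), `condition`, `spec`, and `need` (per-complex residue
#'   counts)
#' @export
synthetic_muscle_model <- function(state = c("fasting", "post_absorptive"),
                                   muscle_type = "type2a",
                                   energy_cost_per_bond = 4,
                                   allow_interconversion = TRUE,
                                   compositions = NULL) {
  state <- match.arg(state)
  if (is.null(compositions)) compositions <- contractile_compositions()
  need <- per_complex_need(muscle_type, compositions)
  cond <- plasma_condition(state)
  aa_conc <- cond$uptake_bounds[amino_acids()]
  spec <- toy_spec(composition = need,
                   concentrations = aa_conc,
                   energy_pathway = TRUE,
                   allow_interconversion = allow_interconversion,
                   energy_cost_per_bond = energy_cost_per_bond,
                   glucose = cond$uptake_bounds[["glucose"]],
                   palmitate = cond$uptake_bounds[["palmitate"]],
                   tetradecanoate = cond$uptake_bounds[["tetradecanoate"]],
                   n_chains = 33L)
  model <- make_muscle_like_model(spec)
  model <- apply_condition(model, cond)
  list(model = model, condition = cond, spec = spec, need = need)
}

#' Run the expected-versus-actual supplementation analysis
#'
#' Solves the control, runs the sweep to `k_max`, computes availability,
#' expected and actual effect rankings, and joins them.
#'
#' @param setup output of [synthetic_muscle_model()] (or a compatible
#'   list with `model`, `condition`, `need`)
#' @param k_max sweep depth
#' @param prune forward to [sweep_supplements()]
#' @return list with `control` (flux solution), `sweep`, `best`
#'   (best-per-size table), `expected`, `actual`, `comparison`
#' @export
run_supplement_analysis <- function(setup, k_max = 3L, prune = FALSE) {
  control <- solve_fba(setup$model)
  if (control$status != "optimal")
    stop("control model is ", control$status)
  sw <- sweep_supplements(setup$model, setup$condition, k_max = k_max,
                          prune = prune)
  best <- best_per_size(sw)
  avail <- availability_counts(setup$condition, control$objective_value)
  expd <- expected_effect(setup$need, avail)
  act <- actual_effect(sw)
  list(control = control, sweep = sw, best = best,
       expected = expd, actual = act,
       comparison = compare_expected_actual(expd, act))
}
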
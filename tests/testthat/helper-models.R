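# Shared fixture builders. Everything is generated in code; seeds are
# pinned by the caller.

# minimal linear chain: uptake (ub 5) -> conversion -> demand
chain_model <- function(uptake_ub = 5) {
  stoichiometric_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_A", c(A = 1), 0, uptake_ub, subsystem = "exchange"),
         reaction("R1", c(A = -1, B = 1), 0, 99999),
         reaction("DM_B", c(B = -1), 0, 99999, subsystem = "demand")),
    objective_id = "DM_B")
}

# random small network with bounded fluxes; objective on the last reaction
rand_toy_model <- function(m, n, seed, rev_frac = 0.3, coef_pool = c(-2, -1, 1, 2)) {
  set.seed(seed)
  mets <- lapply(paste0("M", seq_len(m)), metabolite)
  rxns <- lapply(seq_len(n), function(j) {
    k <- sample(seq_len(min(3L, m)), 1L)
    rows <- sample(m, k)
    st <- stats::setNames(sample(coef_pool, k, replace = TRUE),
                          paste0("M", rows))
    lb <- if (stats::runif(1) < rev_frac) -stats::runif(1, 0, 10) else 0
    reaction(paste0("R", j), st, lb, stats::runif(1, 0, 10))
  })
  stoichiometric_model(mets, rxns, objective_id = paste0("R", n))
}

# assembly spec with a strictly unique bottleneck amino acid
bottleneck_spec <- function(seed, n_aa = 5L) {
  set.seed(seed)
  aa <- amino_acids()[seq_len(n_aa)]
  comp <- stats::setNames(sample(5:30, n_aa, replace = TRUE), aa)
  conc <- stats::setNames(stats::runif(n_aa, 1, 3) * comp, aa)
  pick <- sample(n_aa, 1L)
  conc[pick] <- 0.25 * comp[pick]        # strict minimum ratio 0.25
  list(spec = toy_spec(composition = comp, concentrations = conc,
                       seed = seed),
       bottleneck = aa[pick])
}
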
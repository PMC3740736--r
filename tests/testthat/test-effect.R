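test_that("availability is concentration over control flux", {
  cond <- condition("c", c(methionine = 0.025, glycine = 0,
                           leucine = 0.123))
  av <- availability_counts(cond, control_flux = 2.18e-5,
                            aa_set = c("methionine", "glycine", "leucine"))
  expect_equal(unname(av["glycine"]), 0)
  expect_equal(unname(av["methionine"]), 0.025 / 2.18e-5)  # direct division
  expect_error(availability_counts(cond, 0), "positive")
  expect_error(availability_counts(cond, -1), "positive")
})

test_that("availability is invariant under joint rescaling", {
  cond <- condition("c", c(methionine = 0.025, leucine = 0.123))
  for (c_scale in c(0.5, 10)) {
    scaled <- condition("c", cond$uptake_bounds * c_scale)
    expect_equal(
      availability_counts(scaled, 2.18e-5 * c_scale,
                          aa_set = names(cond$uptake_bounds)),
      availability_counts(cond, 2.18e-5,
                          aa_set = names(cond$uptake_bounds)))
  }
})

test_that("expected_effect ranks ascending differences with flagged ties", {
  needed <- c(alanine = 10, arginine = 2)
  avail <- c(alanine = 5, arginine = 5)      # differences -5 and +3
  ee <- expected_effect(needed, avail)
  expect_equal(ee$amino_acid, c("alanine", "arginine"))
  expect_equal(ee$expected_rank, c(1L, 2L))
  expect_equal(ee$difference, c(-5, 3))
  expect_false(any(ee$tie))

  tied <- expected_effect(c(valine = 3, serine = 3),
                          c(valine = 1, serine = 1))
  expect_equal(tied$amino_acid, c("serine", "valine"))  # alphabetical
  expect_true(all(tied$tie))

  expect_error(expected_effect(needed, c(alanine = 1, lysine = 1)),
               "different amino-acid sets")
})

test_that("actual_effect orders by first appearance in best subsets", {
  bs <- bottleneck_spec(seed = 41, n_aa = 4)
  mod <- make_assembly_model(bs$spec)
  cond <- condition("toy", bs$spec$concentrations)
  sw <- sweep_supplements(mod, cond, k_max = 2)
  act <- actual_effect(sw, aa_set = bs$spec$aa)
  expect_equal(act$amino_acid[1L], bs$bottleneck)
  expect_equal(act$actual_rank[1L], 1L)
  expect_equal(act$first_size[1L], 1L)

  # sweep where nothing improves: everything unranked
  flat <- toy_spec(n_amino_acids = 3,
                   composition = c(alanine = 1, arginine = 1,
                                   asparagine = 1),
                   concentrations = c(alanine = 2, arginine = 2,
                                      asparagine = 2),
                   seed = 1)
  swf <- sweep_supplements(make_assembly_model(flat),
                           condition("toy", flat$concentrations),
                           k_max = 2)
  actf <- actual_effect(swf, aa_set = flat$aa)
  expect_true(all(is.na(actf$actual_rank)))
})

test_that("rank comparison reports shifts and the footrule statistic", {
  ee <- data.frame(amino_acid = c("a", "b", "c"), difference = c(-3, -2, -1),
                   expected_rank = 1:3,
                   essentiality = "essential", stringsAsFactors = FALSE)
  same <- data.frame(amino_acid = c("a", "b", "c"), first_size = 1:3,
                     actual_rank = 1:3, stringsAsFactors = FALSE)
  cmp <- compare_expected_actual(ee, same)
  expect_equal(cmp$rank_shift, c(0L, 0L, 0L))
  expect_equal(attr(cmp, "footrule"), 0)

  rev3 <- data.frame(amino_acid = c("a", "b", "c"), first_size = c(3, 2, 1),
                     actual_rank = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  cmp_rev <- compare_expected_actual(ee, rev3)
  # enumeration oracle: the reversal attains the footrule maximum over S_3
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  max_foot <- max(vapply(perms, function(p) sum(abs(1:3 - p)), 0))
  expect_equal(attr(cmp_rev, "footrule"), max_foot)
  expect_equal(max_foot, 4)
})

test_that("expected and actual coincide on assembly-only models", {
  for (seed in c(6, 19, 28)) {
    bs <- bottleneck_spec(seed = seed, n_aa = 5)
    mod <- make_assembly_model(bs$spec)
    cond <- condition("toy", bs$spec$concentrations)
    ctrl <- solve_fba(apply_condition(mod, cond))
    avail <- availability_counts(cond, ctrl$objective_value,
                                 aa_set = bs$spec$aa)
    # need per complex: the composition itself
    ee <- expected_effect(bs$spec$composition, avail)
    sw <- sweep_supplements(mod, cond, k_max = 1)
    act <- actual_effect(sw, aa_set = bs$spec$aa)
    expect_equal(ee$amino_acid[1L], act$amino_acid[1L],
                 info = paste("seed", seed))
    expect_equal(act$amino_acid[1L], bs$bottleneck)
  }
})

test_that("catabolic routes make the two rankings diverge", {
  # leucine is scarce as a building block but can also be burned for
  # ATP; with energy tight, supplementing abundant catabolizable alanine
  # raises the optimum although alanine is nowhere near the expected top
  comp <- c(alanine = 1, leucine = 1, methionine = 20)
  conc <- c(alanine = 1, leucine = 0.4, methionine = 10)
  spec <- toy_spec(composition = comp, concentrations = conc,
                   energy_pathway = TRUE, energy_cost_per_bond = 10,
                   glucose = 0.001, palmitate = 0, tetradecanoate = 0,
                   catabolizable = "alanine", atp_per_aa = 20, seed = 1)
  mod <- make_muscle_like_model(spec)
  cond <- condition("toy", c(conc, glucose = 0.001, palmitate = 0,
                             tetradecanoate = 0))
  ctrl <- solve_fba(apply_condition(mod, cond))
  expect_equal(ctrl$status, "optimal")
  avail <- availability_counts(cond, ctrl$objective_value,
                               aa_set = names(comp))
  ee <- expected_effect(comp, avail)
  expect_false(ee$amino_acid[1L] == "alanine")  # not the expected top
  sup <- solve_fba(supplement(apply_condition(mod, cond), "alanine"))
  expect_gt(sup$objective_value, ctrl$objective_value + 1e-9)
})

test_that("effect TSV export keeps the declared header", {
  ee <- expected_effect(c(alanine = 2, valine = 1),
                        c(alanine = 1, valine = 5))
  act <- data.frame(amino_acid = c("alanine", "valine"),
                    first_size = c(1L, NA), actual_rank = c(1L, NA),
                    stringsAsFactors = FALSE)
  cmp <- compare_expected_actual(ee, act)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_effect_tsv(cmp, path)
  lines <- readLines(path)
  expect_true(any(grepl("availability = plasma concentration", lines)))
  expect_true(any(grepl("footrule", lines)))
})
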
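l2_fixture <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="toy">
  <listOfCompartments>
   <compartment id="cytosol"/><compartment id="extracellular"/>
  </listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="extracellular"/>
   <species id="B" compartment="cytosol"/>
   <species id="C" compartment="cytosol"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="T1" reversible="false">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="7.5"/>
      <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="T2" reversible="true">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="C"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="-3"/>
      <parameter id="UPPER_BOUND" value="99999"/>
      <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
  path
}

l3_fbc_fixture <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="toy3" fbc:strict="true">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="ub10" value="10" constant="true"/>
   <parameter id="big" value="99999" constant="true"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="X" compartment="c" constant="false"/>
   <species id="Y" compartment="c" constant="false"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="up" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfProducts><speciesReference species="X" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="conv" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="big">
    <listOfReactants><speciesReference species="X" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="Y" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="dm" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="big">
    <listOfReactants><speciesReference species="Y" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj1">
   <fbc:objective fbc:id="obj1" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="dm" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>', path)
  path
}

test_that("a Level 2 file with kineticLaw bounds reads correctly", {
  path <- withr::local_tempfile(fileext = ".xml")
  mod <- read_sbml(l2_fixture(path))
  expect_equal(nrow(mod$reactions), 2L)
  expect_equal(nrow(mod$metabolites), 3L)
  expect_equal(mod$metabolites$compartment,
               c("extracellular", "cytosol", "cytosol"))
  expect_equal(mod$stoichiometry[["T1"]], c(A = -1, B = 2))
  expect_equal(mod$reactions$upper_bound, c(7.5, 99999))
  expect_equal(mod$reactions$lower_bound, c(0, -3))
  expect_equal(mod$objective_id, "T2")  # OBJECTIVE_COEFFICIENT = 1
})

test_that("a Level 3 fbc file reads bounds and objective", {
  path <- withr::local_tempfile(fileext = ".xml")
  mod <- read_sbml(l3_fbc_fixture(path))
  expect_equal(nrow(mod$reactions), 3L)
  expect_equal(mod$reactions$upper_bound[mod$reactions$id == "up"], 10)
  expect_equal(mod$objective_id, "dm")
  sol <- solve_fba(mod)
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})

test_that("write_sbml then read_sbml is the identity on structure", {
  for (mod in list(chain_model(),
                   make_muscle_like_model(toy_spec(n_amino_acids = 6,
                                                   energy_pathway = TRUE,
                                                   seed = 2)))) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(mod, path)
    back <- read_sbml(path)
    expect_true(model_stats(back) == model_stats(mod))
    expect_equal(assemble_matrix(back), assemble_matrix(mod))
    expect_equal(back$reactions$lower_bound, mod$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, mod$reactions$upper_bound)
    expect_equal(back$objective_id, mod$objective_id)
    expect_equal(back$reactions$subsystem, mod$reactions$subsystem)
    expect_equal(solve_fba(back)$objective_value,
                 solve_fba(mod)$objective_value, tolerance = 1e-9)
  }
})

test_that("unicode names survive a round-trip", {
  mod <- stoichiometric_model(
    list(metabolite("A", name = "α-ketoglutarate"),
         metabolite("B", name = "acetyl~CoA <2>")),
    list(reaction("R1", c(A = -1, B = 1), 0, 5,
                  name = "Δ-isomerase \"fast\"")),
    "R1")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mod, path)
  back <- read_sbml(path)
  expect_equal(back$metabolites$name, mod$metabolites$name)
  expect_equal(back$reactions$name, mod$reactions$name)
})

test_that("species without a compartment warns and lands in cytosol", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model><listOfSpecies><species id="S1"/></listOfSpecies>
 <listOfReactions><reaction id="R1" reversible="false">
  <listOfProducts><speciesReference species="S1"/></listOfProducts>
 </reaction></listOfReactions></model></sbml>', path)
  expect_warning(mod <- read_sbml(path), "compartment")
  expect_equal(mod$metabolites$compartment, "cytosol")
  # no explicit bounds: irreversible flag maps to (0, cap)
  expect_equal(mod$reactions$lower_bound, 0)
  expect_equal(mod$reactions$upper_bound, 99999)
})

test_that("malformed XML is a parse error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", path)
  expect_error(read_sbml(path))
})
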
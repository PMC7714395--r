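test_that("minimal JSON documents parse into validated models", {
  doc <- '{
    "metabolites": [{"id": "glc_e", "name": "glucose", "compartment": "e"}],
    "reactions": [{"id": "EX_glc", "stoichiometry": {"glc_e": -1},
                   "lower_bound": -10, "upper_bound": 1000,
                   "is_exchange": true}],
    "objective": "EX_glc"
  }'
  m <- read_model(doc, "json")
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$reactions), 1)
  expect_true(m$reactions$is_exchange[1])
  expect_equal(m$reactions$lower_bound[1], -10)
})

test_that("JSON serialization is canonical and round-trips losslessly", {
  toy <- make_toy_model(include_heterologous = TRUE)
  expect_equal(nrow(toy$reactions), 9)
  txt <- write_model(toy)
  expect_identical(write_model(toy), txt) # byte-identical determinism
  back <- read_model(txt, "json")
  expect_identical(write_model(back), txt)
  expect_setequal(back$reactions$id, toy$reactions$id)
  mets <- sort(toy$metabolites$id)
  rxns <- sort(toy$reactions$id)
  expect_equal(stoichiometric_matrix(back)[mets, rxns],
               stoichiometric_matrix(toy)[mets, rxns])
})

test_that("model invariants are enforced with element-naming errors", {
  mets <- tibble::tibble(id = c("a", "b"), name = c("a", "b"),
                         compartment = "c")
  ok <- tibble::tibble(id = "r1", stoichiometry = list(c(a = -1, b = 1)),
                       lower_bound = 0, upper_bound = 10, is_exchange = FALSE)
  expect_error(metabolic_model(mets, dplyr::mutate(ok, lower_bound = 20), "r1"),
               "lower_bound > upper_bound")
  expect_error(metabolic_model(mets, dplyr::mutate(ok, stoichiometry =
                                                     list(c(zz = 1))), "r1"),
               "unknown metabolite 'zz'")
  expect_error(metabolic_model(mets, dplyr::mutate(ok, is_exchange = TRUE),
                               "r1"),
               "exactly one metabolite")
  expect_error(metabolic_model(mets, ok, "nope"), "objective")
  expect_error(metabolic_model(mets, dplyr::bind_rows(ok, ok), "r1"),
               "duplicate reaction")
  expect_error(read_model("{not json", "json"), "malformed")
})

test_that("the SBML subset reader recovers species, reactions and bounds", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
  <sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
    <model id="mini">
      <listOfParameters>
        <parameter id="lb_m10" value="-10" constant="true"/>
        <parameter id="ub_1000" value="1000" constant="true"/>
      </listOfParameters>
      <listOfSpecies>
        <species id="A" name="met A" compartment="c"/>
        <species id="B" name="met B" compartment="c"/>
      </listOfSpecies>
      <listOfReactions>
        <reaction id="EX_A" reversible="true" lowerFluxBound="lb_m10" upperFluxBound="ub_1000">
          <listOfReactants>
            <speciesReference species="A" stoichiometry="1"/>
          </listOfReactants>
        </reaction>
        <reaction id="A_to_B" reversible="false">
          <listOfReactants>
            <speciesReference species="A"/>
          </listOfReactants>
          <listOfProducts>
            <speciesReference species="B" stoichiometry="2"/>
          </listOfProducts>
        </reaction>
      </listOfReactions>
    </model>
  </sbml>'
  m <- read_model(sbml, "sbml")
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 2)
  ex <- dplyr::filter(m$reactions, id == "EX_A")
  expect_equal(ex$lower_bound, -10)
  expect_true(ex$is_exchange)
  ab <- dplyr::filter(m$reactions, id == "A_to_B")
  expect_equal(ab$stoichiometry[[1]][["B"]], 2)
  expect_equal(ab$lower_bound, 0) # irreversible default
})

test_that("set_carbon_source configures one exclusive organic source", {
  toy <- make_toy_model()
  m <- set_carbon_source(toy, "EX_glyc", 10)
  i <- match("EX_glyc", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -10)
  expect_equal(m$reactions$upper_bound[i], Inf)
  # original untouched
  expect_equal(toy$reactions$upper_bound[match("EX_glyc", toy$reactions$id)],
               1000)
  expect_error(set_carbon_source(toy, "T5_rpi", 10), "not an exchange")
  expect_error(set_carbon_source(toy, "EX_nope", 10), "unknown reaction")
})

test_that("configuring each of nine sources yields nine exclusive models", {
  sources <- c("EX_glc", "EX_fru", "EX_glcn", "EX_rib", "EX_succ", "EX_xyl",
               "EX_glyc_r", "EX_ac", "EX_glyc")
  mets <- tibble::tibble(id = paste0(sources, "_m"),
                         name = sources, compartment = "e")
  rxns <- tibble::tibble(
    id = sources,
    stoichiometry = purrr::map(paste0(sources, "_m"),
                               ~ stats::setNames(-1, .x)),
    lower_bound = -5, upper_bound = 1000, is_exchange = TRUE
  )
  model <- metabolic_model(mets, rxns, sources[1])
  configured <- purrr::map(sources, ~ set_carbon_source(model, .x, 10))
  open_source <- purrr::map_chr(configured, function(m) {
    m$reactions$id[m$reactions$is_exchange & m$reactions$lower_bound < 0]
  })
  expect_equal(open_source, sources) # exactly one open uptake each
  expect_equal(length(unique(purrr::map_chr(configured, write_model))), 9)
  # applying a second source closes the first
  twice <- set_carbon_source(configured[[9]], "EX_glc", 10)
  expect_equal(twice$reactions$lower_bound[match("EX_glyc", twice$reactions$id)],
               0)
})

test_that("apply_knockouts zeroes bounds without touching the input", {
  toy <- make_toy_model()
  expect_identical(apply_knockouts(toy, character(0)), toy)
  ko <- apply_knockouts(toy, "T5_rpi")
  i <- match("T5_rpi", ko$reactions$id)
  expect_equal(ko$reactions$lower_bound[i], 0)
  expect_equal(ko$reactions$upper_bound[i], 0)
  expect_equal(toy$reactions$upper_bound[i], 1000)
  expect_error(apply_knockouts(toy, "nope"), "unknown reaction")
})
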
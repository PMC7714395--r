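het <- toy_heterologous_spec()

test_that("the detour is added with the right stoichiometry, idempotently", {
  toy <- make_toy_model()
  m <- add_heterologous(toy, het)
  expect_setequal(setdiff(m$reactions$id, toy$reactions$id),
                  c("T6_prk", "T7_rubisco"))
  rub <- m$reactions$stoichiometry[[match("T7_rubisco", m$reactions$id)]]
  expect_equal(rub[["g3p"]], 2) # two 3PG-equivalents per carboxylation
  expect_equal(rub[["co2"]], -1)
  m2 <- add_heterologous(m, het)
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_identical(write_model(m2), write_model(m))
  # clashing id with different stoichiometry is refused
  clash <- heterologous_spec(ru5p_id = "ru5p", rubp_id = "rubp",
                             co2_id = "co2", target_metabolite_id = "ri5p")
  expect_error(add_heterologous(m, clash), "different stoichiometry")
  bad <- heterologous_spec(ru5p_id = "nope", rubp_id = "rubp",
                           co2_id = "co2", target_metabolite_id = "g3p")
  expect_error(add_heterologous(toy, bad), "lacks metabolite")
})

test_that("rubisco dependence requires the right knockout", {
  toy <- make_toy_model()
  wt <- rubisco_dependence_test(toy, character(0), het)
  expect_false(wt$dependent) # wild type grows at 3.75 without the detour
  expect_equal(wt$growth_without, 3.75, tolerance = 1e-8)
  drpi <- rubisco_dependence_test(toy, "T5_rpi", het)
  expect_lt(drpi$growth_without, 1e-6)
  expect_equal(drpi$growth_with, 5, tolerance = 1e-8)
  expect_true(drpi$dependent)
  # severing the sole Ri5P source cannot be rescued by the detour
  dead <- rubisco_dependence_test(toy, "T4_ppp", het)
  expect_lt(dead$growth_with, 1e-6)
  expect_false(dead$dependent)
})

test_that("coupling slope matches the hand LP and scales with demand", {
  fit <- coupling_slope(toy_rescued(), het)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(nrow(fit$grid), 5)
  expect_true(all(diff(fit$grid$biomass) > 0))
  # grid points lie on the fitted line (exactly linear here)
  expect_true(all(fit$grid$min_rubisco >=
                    fit$slope * fit$grid$biomass + fit$intercept - 1e-5))
  expect_equal(tidy(fit)$estimate, c(fit$intercept, fit$slope))
  # doubling the biomass Ri5P coefficient doubles the rubisco requirement
  fit2 <- coupling_slope(toy_rescued(biomass_ri5p = 2), het)
  expect_equal(fit2$slope, 4, tolerance = 1e-6)
  # no growth -> no slope
  expect_error(coupling_slope(apply_knockouts(make_toy_model(), "T5_rpi"),
                              het),
               "does not grow")
})

test_that("the knockout scan is complete, minimal and deterministic", {
  toy <- make_toy_model()
  scan <- scan_knockouts(toy, het, sources = "EX_glyc",
                         candidate_rxns = TOY_CANDIDATES, max_size = 2)
  oracle <- brute_force_dependent_subsets(toy, het, "EX_glyc",
                                          TOY_CANDIDATES, 2)
  expect_setequal(unique(scan$deleted_ids), oracle)
  expect_equal(unique(scan$deleted_ids), "T5_rpi") # only the isomerase couples
  expect_gt(scan$slope[1], 0) # dependence implies positive coupling
  expect_identical(scan,
                   scan_knockouts(toy, het, sources = "EX_glyc",
                                  candidate_rxns = TOY_CANDIDATES,
                                  max_size = 2))
  # no qualifying single among the non-isomerase candidates
  none <- scan_knockouts(toy, het, sources = "EX_glyc",
                         candidate_rxns = c("T3_g3p_f6p", "T4_ppp"),
                         max_size = 1)
  expect_equal(nrow(none), 0)
  expect_error(scan_knockouts(toy, het, sources = "EX_glyc",
                              candidate_rxns = character(0)),
               "empty candidate")
  expect_error(scan_knockouts(toy, het, sources = "EX_glyc",
                              candidate_rxns = c("EX_glyc")),
               "exclude exchanges")
})

test_that("the rubisco 3PG share matches the hand LP in both accountings", {
  resc <- toy_rescued()
  frac_mol <- predicted_rubisco_3pg_fraction(resc, het)
  # gross 3PG production 30 (10 glycolytic + 20 rubisco molecules)
  expect_equal(frac_mol$point, 200 / 3, tolerance = 1e-6)
  expect_equal(frac_mol$lo, frac_mol$point, tolerance = 1e-6)
  expect_equal(frac_mol$hi, frac_mol$point, tolerance = 1e-6)
  frac_ev <- predicted_rubisco_3pg_fraction(resc, het, accounting = "events")
  # 10 carboxylation events vs 10 glycolytic units
  expect_equal(frac_ev$point, 50, tolerance = 1e-6)
  expect_equal(frac_ev$lo, 50, tolerance = 1e-6)
  expect_equal(frac_ev$hi, 50, tolerance = 1e-6)
})

test_that("the 3PG share is a bounded, monotone function of rubisco flux", {
  wt_het <- make_toy_model(include_heterologous = TRUE)
  # rubisco silenced: share is 0, not an error
  silenced <- wt_het
  i <- match("T7_rubisco", silenced$reactions$id)
  silenced$reactions$upper_bound[i] <- 0
  expect_equal(predicted_rubisco_3pg_fraction(silenced, het)$point, 0)
  # a prk that burns one G3P (ATP proxy) makes the detour uncompetitive with
  # the isomerase; forcing rubisco flux then strictly raises its 3PG share
  costly <- wt_het
  jp <- match("T6_prk", costly$reactions$id)
  costly$reactions$stoichiometry[[jp]] <- c(ru5p = -1, g3p = -1, rubp = 1)
  j <- match("T7_rubisco", costly$reactions$id)
  shares <- vapply(c(0, 2, 4), function(lb_rub) {
    m <- costly
    m$reactions$lower_bound[j] <- lb_rub
    predicted_rubisco_3pg_fraction(m, het)$point
  }, numeric(1))
  expect_equal(shares[1], 0, tolerance = 1e-6) # optimum avoids the detour
  expect_true(all(diff(shares) > 1e-6))
  expect_true(all(shares >= 0 & shares <= 100))
})
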
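test_that("a single uptake bottleneck caps the objective", {
  st <- function(...) list(c(...))
  mets <- tibble::tibble(id = c("A_ext", "A", "B"), name = id,
                         compartment = "c")
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_A", stoichiometry = st(A_ext = -1),
                   lower_bound = -10, upper_bound = 0, is_exchange = TRUE),
    tibble::tibble(id = "upt", stoichiometry = st(A_ext = -1, A = 1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
    tibble::tibble(id = "conv", stoichiometry = st(A = -1, B = 1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
    tibble::tibble(id = "bio", stoichiometry = st(B = -1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE)
  )
  m <- metabolic_model(mets, rxns, "bio")
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(glance(sol)$objective_value, 10, tolerance = 1e-9)
  expect_named(tidy(sol), c("reaction", "flux"))
})

test_that("toy network optima match the hand-derived LP values", {
  expect_equal(fba(make_toy_model())$objective_value, 3.75, tolerance = 1e-8)
  drpi <- fba(apply_knockouts(make_toy_model(), "T5_rpi"))
  expect_equal(drpi$status, "optimal")
  expect_lt(drpi$objective_value, 1e-6) # Ru5P dead end: no growth
  resc <- fba(toy_rescued())
  expect_equal(resc$objective_value, 5, tolerance = 1e-8)
  expect_equal(resc$fluxes[["T7_rubisco"]], 10, tolerance = 1e-8)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  toy <- make_toy_model(include_heterologous = TRUE)
  set.seed(42)
  for (rep_i in 1:10) {
    m <- toy
    scale <- stats::runif(nrow(m$reactions), 0.5, 2)
    m$reactions$upper_bound <- ifelse(
      is.finite(m$reactions$upper_bound),
      m$reactions$upper_bound * scale, m$reactions$upper_bound)
    sol <- fba(m)
    expect_equal(sol$status, "optimal")
    v <- sol$fluxes[m$reactions$id]
    expect_lt(max(abs(stoichiometric_matrix(m) %*% v)), 1e-6)
    expect_true(all(v >= m$reactions$lower_bound - 1e-9))
    expect_true(all(v <= m$reactions$upper_bound + 1e-9))
  }
})

test_that("widening any bound never decreases the optimum", {
  base <- toy_rescued()
  f0 <- fba(base)$objective_value
  set.seed(7)
  for (rep_i in 1:12) {
    m <- base
    j <- sample.int(nrow(m$reactions), 1)
    if (stats::runif(1) < 0.5) {
      m$reactions$upper_bound[j] <- m$reactions$upper_bound[j] * 2 + 1
    } else {
      m$reactions$lower_bound[j] <- m$reactions$lower_bound[j] -
        abs(m$reactions$lower_bound[j]) - 1
    }
    expect_gte(fba(m)$objective_value, f0 - 1e-7)
  }
})

test_that("infeasible and degenerate problems are reported, never zeroed", {
  st <- function(...) list(c(...))
  mets <- tibble::tibble(id = "X", name = "X", compartment = "c")
  rxns <- tibble::tibble(id = "make_X", stoichiometry = st(X = 1),
                         lower_bound = 1, upper_bound = 10,
                         is_exchange = FALSE)
  m <- metabolic_model(mets, rxns, "make_X")
  expect_equal(fba(m)$status, "infeasible") # X has no sink but flux >= 1
  expect_true(is.na(fba(m)$objective_value))
  expect_error(flux_variability(m, "make_X"), "infeasible")
})

test_that("FVA brackets the FBA flux and pins fully coupled reactions", {
  resc <- toy_rescued()
  sol <- fba(resc)
  fva <- flux_variability(resc, resc$reactions$id, fraction_of_optimum = 1)
  for (k in seq_len(nrow(fva))) {
    flux <- sol$fluxes[[fva$reaction[k]]]
    expect_gte(flux, fva$min_flux[k] - 1e-6)
    expect_lte(flux, fva$max_flux[k] + 1e-6)
  }
  # the objective's own variability at fraction 1 is the optimum
  obj_fva <- flux_variability(resc, "T9_biomass", 1)
  expect_equal(obj_fva$min_flux, 5, tolerance = 1e-6)
  expect_equal(obj_fva$max_flux, 5, tolerance = 1e-6)
  # rubisco is fully coupled: (10, 10)
  rub <- flux_variability(resc, "T7_rubisco", 1)
  expect_equal(rub$min_flux, 10, tolerance = 1e-6)
  expect_equal(rub$max_flux, 10, tolerance = 1e-6)
  # absent reaction is an error, not a zero
  expect_error(flux_variability(make_toy_model(), "T7_rubisco"),
               "unknown reaction")
})

test_that("the simplex agrees with exhaustive grid search on tiny models", {
  # grid step chosen so each optimum is representable (uptake 3 splits
  # half-integer across the branches)
  for (case in list(c(2, 1), c(3, 0.5), c(4, 1))) {
    m <- mini_branched_model(uptake = case[1])
    expect_equal(fba(m)$objective_value, grid_lp_oracle(m, step = case[2]),
                 tolerance = 1e-9)
  }
  # asymmetric branch capacity
  m <- mini_branched_model(uptake = 4)
  m$reactions$upper_bound[match("A_to_B", m$reactions$id)] <- 1
  expect_equal(fba(m)$objective_value, grid_lp_oracle(m, step = 1),
               tolerance = 1e-9)
})
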
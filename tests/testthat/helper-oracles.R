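# Independent oracles and small fixtures, all built in code.

# Exhaustive grid-search LP oracle for tiny models: enumerate fluxes on an
# integer-step grid over the boxed bounds, keep mass-balanced points, return
# the best objective value. Independent of the simplex path used by fba().
grid_lp_oracle <- function(model, step = 1) {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  grids <- lapply(seq_along(lb), function(i) seq(lb[i], ub[i], by = step))
  combos <- as.matrix(expand.grid(grids))
  obj_i <- match(model$objective, model$reactions$id)
  resid <- abs(S %*% t(combos))
  feasible <- apply(resid, 2, max) < 1e-9
  if (!any(feasible)) return(NA_real_)
  max(combos[feasible, obj_i])
}

# small branched network with integer optima for the grid oracle:
# EX_A (uptake <= 4); A -> B; A -> C; B + C -> biomass
mini_branched_model <- function(uptake = 4, ub = 4) {
  st <- function(...) list(c(...))
  mets <- tibble::tibble(id = c("A", "B", "C"),
                         name = c("A", "B", "C"),
                         compartment = "c")
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_A", stoichiometry = st(A = -1),
                   lower_bound = -uptake, upper_bound = 0, is_exchange = TRUE),
    tibble::tibble(id = "A_to_B", stoichiometry = st(A = -1, B = 1),
                   lower_bound = 0, upper_bound = ub, is_exchange = FALSE),
    tibble::tibble(id = "A_to_C", stoichiometry = st(A = -1, C = 1),
                   lower_bound = 0, upper_bound = ub, is_exchange = FALSE),
    tibble::tibble(id = "bio", stoichiometry = st(B = -1, C = -1),
                   lower_bound = 0, upper_bound = ub, is_exchange = FALSE)
  )
  metabolic_model(mets, rxns, "bio")
}

# Brute-force knockout screen: re-runs the dependence test over every subset,
# independent of scan_knockouts()'s bookkeeping.
brute_force_dependent_subsets <- function(model, het, sources, candidates,
                                          max_size, max_uptake = 10) {
  subsets <- unlist(lapply(seq_len(max_size), function(k) {
    utils::combn(sort(candidates), k, simplify = FALSE)
  }), recursive = FALSE)
  keep <- vapply(subsets, function(ko) {
    any(vapply(sources, function(src) {
      rubisco_dependence_test(model, ko, het, source = src,
                              max_uptake = max_uptake)$dependent
    }, logical(1)))
  }, logical(1))
  vapply(subsets[keep], paste, character(1), collapse = ";")
}

# Analytic serine isotopologue distribution for iid per-position 12C
# probabilities (b, b, p_cbx): fraction of molecules with i heavy carbons.
serine_distribution <- function(b, p_cbx) {
  p12 <- c(b, b, p_cbx)
  f <- c(1)
  for (p in p12) f <- convolve(f, rev(c(p, 1 - p)), type = "open")
  # f[i+1] = P(i heavy carbons)
  f
}

# Analytic M+2 MRM pair (carboxyl 13C / 12C integrals, arbitrary scale)
serine_mrm_pair <- function(b, p_cbx, scale = 1e5) {
  a <- (1 - p_cbx) * 2 * b * (1 - b)      # carboxyl 13C, one other 12C
  bb <- p_cbx * (1 - b)^2                 # carboxyl 12C, others 13C
  c(peak_61_1 = scale * a, peak_62_1 = scale * bb)
}

# Long-form isotopologue + MRM tables from analytic (noise-free) fractions
analytic_labeling_tables <- function(x_true, b = 0.02, c_co2 = 0.989,
                                     d = 0.5, n_replicates = 2) {
  p_exp <- b + x_true * d * (c_co2 - b)
  arms <- list(experiment = p_exp, control = b)
  iso <- purrr::map_dfr(names(arms), function(arm) {
    frac <- serine_distribution(b, arms[[arm]])
    purrr::map_dfr(seq_len(n_replicates), function(i) {
      tibble::tibble(compound = "serine", n_carbons = 3L,
                     replicate = paste0(arm, i), role = arm,
                     m_plus = 0:3, fraction = frac)
    })
  })
  mrm <- purrr::map_dfr(names(arms), function(arm) {
    pk <- serine_mrm_pair(b, arms[[arm]])
    tibble::tibble(replicate = paste0(arm, seq_len(n_replicates)),
                   role = arm,
                   peak_61_1 = pk[["peak_61_1"]],
                   peak_62_1 = pk[["peak_62_1"]])
  })
  list(iso = iso, mrm = mrm)
}

toy_rescued <- function(...) {
  apply_knockouts(make_toy_model(include_heterologous = TRUE, ...), "T5_rpi")
}

TOY_CANDIDATES <- c("T3_g3p_f6p", "T4_ppp", "T5_rpi")
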
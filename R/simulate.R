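# Seeded generators for every input the pipeline consumes: a toy
# rubisco-coupled network, labeling tables with known ground truth, and
# replicate growth curves. Each generator is a pure function of its
# parameters and seed.

#' Toy rubisco-coupled metabolic network
#'
#' A deterministic 9-reaction, carbon-balanced caricature of the pentose
#' phosphate route on glycerol:
#' \itemize{
#'   \item `EX_glyc`: glycerol exchange (uptake bound `uptake`);
#'   \item `T2_glyc_g3p`: Glyc -> G3P;
#'   \item `T3_g3p_f6p`: 2 G3P -> F6P;
#'   \item `T4_ppp`: 2 F6P + G3P -> 2 Ru5P + Ri5P (lumped non-oxidative
#'     pentose phosphate reaction; 15 carbons on both sides);
#'   \item `T5_rpi`: Ru5P -> Ri5P (ribose-phosphate isomerase);
#'   \item `T6_prk` / `T7_rubisco` (when `include_heterologous`): the detour
#'     Ru5P -> RuBP, RuBP + CO2 -> 2 G3P;
#'   \item `EX_co2`: free CO2 exchange;
#'   \item `T9_biomass`: `biomass_g3p` G3P + `biomass_ri5p` Ri5P -> biomass
#'     (the objective).
#' }
#' Deleting `T5_rpi` makes Ru5P a dead end that only the prk + rubisco detour
#' can drain, exactly the growth-coupling mechanism the screen looks for.
#' Energy cofactors are deliberately absent. At the defaults the hand-derived
#' LP optima are: wild type 3.75; delta-rpi without the detour 0; delta-rpi
#' with the detour 5.0 with rubisco flux pinned at 10.
#'
#' @param uptake glycerol uptake bound (mmol/gDW/h).
#' @param biomass_g3p,biomass_ri5p biomass stoichiometric demands.
#' @param include_heterologous add the prk and rubisco reactions?
#' @return A `metabolic_model`.
#' @export
make_toy_model <- function(uptake = 10, biomass_g3p = 1, biomass_ri5p = 1,
                           include_heterologous = FALSE) {
  stopifnot(uptake > 0, biomass_g3p > 0, biomass_ri5p > 0)
  mets <- tibble::tibble(
    id = c("glyc_e", "g3p", "f6p", "ru5p", "ri5p", "co2"),
    name = c("glycerol (external)", "glyceraldehyde/3PG pool",
             "fructose-6-phosphate", "ribulose-5-phosphate",
             "ribose-5-phosphate", "carbon dioxide"),
    compartment = c("e", "c", "c", "c", "c", "c")
  )
  st <- function(...) list(c(...))
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_glyc", stoichiometry = st(glyc_e = -1),
                   lower_bound = -uptake, upper_bound = 1000,
                   is_exchange = TRUE),
    tibble::tibble(id = "T2_glyc_g3p", stoichiometry = st(glyc_e = -1, g3p = 1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
    tibble::tibble(id = "T3_g3p_f6p", stoichiometry = st(g3p = -2, f6p = 1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
    tibble::tibble(id = "T4_ppp",
                   stoichiometry = st(f6p = -2, g3p = -1, ru5p = 2, ri5p = 1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
    tibble::tibble(id = "T5_rpi", stoichiometry = st(ru5p = -1, ri5p = 1),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
    tibble::tibble(id = "EX_co2", stoichiometry = st(co2 = -1),
                   lower_bound = -1000, upper_bound = 1000,
                   is_exchange = TRUE),
    tibble::tibble(id = "T9_biomass",
                   stoichiometry = st(g3p = -biomass_g3p,
                                      ri5p = -biomass_ri5p),
                   lower_bound = 0, upper_bound = 1000, is_exchange = FALSE)
  )
  model <- metabolic_model(mets, rxns, "T9_biomass")
  if (include_heterologous) {
    model <- add_heterologous(model, toy_heterologous_spec())
  }
  model
}

#' Heterologous spec for the toy network's metabolite ids
#'
#' @return A [heterologous_spec()] wiring prk and rubisco into
#'   [make_toy_model()]'s Ru5P, CO2 and G3P pools.
#' @export
toy_heterologous_spec <- function() {
  heterologous_spec(ru5p_id = "ru5p", rubp_id = "rubp", co2_id = "co2",
                    target_metabolite_id = "g3p")
}

#' Simulate serine labeling data with known ground truth
#'
#' Forward model of the labeling experiment: cultures grow on highly
#' 13C-enriched glycerol, so glycolytic serine carbons are 12C only with the
#' small background probability `b = (1 - purity) * (1 - nat_13c)` (the
#' unlabeled impurity, itself carrying natural-abundance 13C). In the
#' experiment arm the carboxyl carbon is 12C with probability
#' `b + x_true * d * (c_co2 - b)`; the control arm has no rubisco
#' contribution. Per replicate, `depth` serine molecules are drawn
#' multinomially over the eight per-position label configurations;
#' isotopologue fractions aggregate the configurations, and the MRM pair is
#' the carboxyl-13C/-12C split *within the M+2 subpopulation*, as the
#' instrument measures it.
#'
#' @param x_true true fraction of 3PG production due to rubisco.
#' @param purity 13C atom purity of the glycerol substrate.
#' @param c_co2 12C fraction of intracellular CO2.
#' @param d pool dilution (fraction of rubisco-derived 3PG carrying the CO2
#'   carbon).
#' @param n_replicates biological replicates per arm.
#' @param depth serine molecules (multinomial counts) per replicate.
#' @param seed integer RNG seed.
#' @param nat_13c natural 13C abundance applied to the unlabeled impurity.
#' @return A list with `iso` (long isotopologue tibble: `compound`,
#'   `n_carbons`, `replicate`, `role`, `m_plus`, `fraction`) and `mrm`
#'   (tibble `replicate`, `role`, `peak_61_1`, `peak_62_1`), plus the
#'   generating parameters in `params`.
#' @export
simulate_labeling <- function(x_true, purity = 0.99, c_co2 = 0.989, d = 0.5,
                              n_replicates = 4, depth = 1e5, seed = 1,
                              nat_13c = 0.011) {
  stopifnot(x_true >= 0, x_true <= 1, purity > 0, purity <= 1,
            c_co2 > 0, c_co2 <= 1, d > 0, d <= 1, n_replicates >= 1,
            depth >= 1)
  b <- (1 - purity) * (1 - nat_13c)
  p_cbx <- c(experiment = b + x_true * d * (c_co2 - b), control = b)
  rows <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(names(p_cbx), function(role) {
      purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
        .simulate_serine_replicate(role, rep_i, b, p_cbx[[role]], depth)
      })
    })
  })
  iso <- dplyr::select(rows, "compound", "n_carbons", "replicate", "role",
                       "m_plus", "fraction")
  mrm <- rows |>
    dplyr::distinct(.data$replicate, .data$role, .data$peak_61_1,
                    .data$peak_62_1)
  list(iso = iso, mrm = mrm,
       params = list(x_true = x_true, purity = purity, c_co2 = c_co2, d = d,
                     b = b, n_replicates = n_replicates, depth = depth,
                     seed = as.integer(seed), nat_13c = nat_13c))
}

# one replicate: counts over the 2^3 label configurations of serine's three
# carbons (positions 1-2 glycolytic background, position 3 the carboxyl)
.simulate_serine_replicate <- function(role, rep_i, b, p_cbx, depth) {
  configs <- expand.grid(c1 = 0:1, c2 = 0:1, cbx = 0:1) # 1 = 12C
  prob <- ifelse(configs$c1 == 1, b, 1 - b) *
    ifelse(configs$c2 == 1, b, 1 - b) *
    ifelse(configs$cbx == 1, p_cbx, 1 - p_cbx)
  counts <- as.numeric(stats::rmultinom(1, size = depth, prob = prob))
  n12 <- configs$c1 + configs$c2 + configs$cbx
  m_plus <- 3 - n12  # heavy-carbon count
  iso_counts <- vapply(0:3, function(i) sum(counts[m_plus == i]), numeric(1))
  # M+2 = exactly one 12C carbon; split by whether it sits on the carboxyl
  m2 <- m_plus == 2
  peak_b <- sum(counts[m2 & configs$cbx == 1]) # carboxyl 12C -> 62.1 channel
  peak_a <- sum(counts[m2 & configs$cbx == 0]) # carboxyl 13C -> 61.1 channel
  tibble::tibble(
    compound = "serine", n_carbons = 3L,
    replicate = paste0(substr(role, 1, 3), rep_i),
    role = role, m_plus = 0:3, fraction = iso_counts / depth,
    peak_61_1 = peak_a, peak_62_1 = peak_b
  )
}

#' Simulate replicate growth curves with a configurable endpoint effect
#'
#' Control replicates follow a logistic trajectory saturating at `od_control`;
#' experiment replicates add `effect` scaled by a logistic ramp normalized to
#' 1 at `t_eval`, so with zero noise the arm difference at `t_eval` is
#' exactly `effect`. Gaussian measurement noise is truncated at 0.
#'
#' @param effect OD offset between arms at `t_eval`.
#' @param noise_sd OD measurement noise standard deviation.
#' @param n_replicates replicates per arm.
#' @param times sampling grid (hours).
#' @param t_eval evaluation time (hours), within `times`.
#' @param od_control control plateau OD.
#' @param od_start inoculation OD.
#' @param growth_rate logistic rate (1/h).
#' @param t_mid logistic midpoint (hours).
#' @param seed integer RNG seed.
#' @return A growth tibble: `arm`, `replicate`, `time_hr`, `od600`.
#' @export
simulate_growth_curves <- function(effect = 0.6, noise_sd = 0.02,
                                   n_replicates = 3,
                                   times = seq(0, 100, by = 2), t_eval = 80,
                                   od_control = 0.12, od_start = 0.005,
                                   growth_rate = 0.15, t_mid = 40, seed = 1) {
  stopifnot(effect >= 0, noise_sd >= 0, n_replicates >= 1,
            length(times) >= 2, t_eval >= min(times), t_eval <= max(times))
  logistic <- function(t) 1 / (1 + exp(-growth_rate * (t - t_mid)))
  base_ctrl <- od_start + (od_control - od_start) * logistic(times)
  ramp <- logistic(times) / logistic(t_eval)
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(c("control", "experiment"), function(arm) {
      mean_curve <- base_ctrl + if (arm == "experiment") effect * ramp else 0
      purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
        noise <- stats::rnorm(length(times), sd = noise_sd)
        tibble::tibble(
          arm = arm,
          replicate = paste0(substr(arm, 1, 3), rep_i),
          time_hr = times,
          od600 = pmax(mean_curve + noise, 0)
        )
      })
    })
  })
}
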
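# OptSlope-style screen: knockouts whose growth requires the heterologous
# rubisco + phosphoribulokinase detour, and how tightly rubisco flux is
# coupled to biomass production.

#' Describe the heterologous rubisco/prk detour
#'
#' The detour converts ribulose-5-phosphate into rubisco's substrate
#' (prk: Ru5P -> RuBP) and then carboxylates it (rubisco: RuBP + CO2 ->
#' 2 x 3PG-equivalent). Rubisco must produce exactly two units of the target
#' metabolite per carboxylation; that factor of two is what the labeling
#' mixture model's pool-dilution parameter refers back to.
#'
#' @param ru5p_id,rubp_id,co2_id,target_metabolite_id metabolite ids in the
#'   host model for Ru5P, RuBP, CO2 and the 3PG pool.
#' @param prk_id,rubisco_id reaction ids to create (or find) in the model.
#' @return An object of class `heterologous_spec`.
#' @export
heterologous_spec <- function(ru5p_id, rubp_id, co2_id, target_metabolite_id,
                              prk_id = "T6_prk", rubisco_id = "T7_rubisco") {
  structure(
    list(ru5p_id = ru5p_id, rubp_id = rubp_id, co2_id = co2_id,
         target_metabolite_id = target_metabolite_id,
         prk_id = prk_id, rubisco_id = rubisco_id),
    class = "heterologous_spec"
  )
}

#' Add the rubisco/prk detour reactions to a model
#'
#' Adds `prk` (Ru5P -> RuBP) and `rubisco` (RuBP + CO2 -> 2 target) as
#' irreversible reactions, creating the RuBP metabolite if absent. Idempotent:
#' re-adding the same spec leaves the model unchanged; a clashing reaction id
#' with different stoichiometry is an error. ATP consumption by prk is not
#' modelled in cofactor-free toy networks; supply a model that includes the
#' ATP-coupled stoichiometry when cofactors matter.
#'
#' @param model a `metabolic_model` containing the Ru5P, CO2 and target
#'   metabolites named in `spec`.
#' @param spec a [heterologous_spec()].
#' @return A new `metabolic_model` with the two reactions present.
#' @export
add_heterologous <- function(model, spec) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(spec, "heterologous_spec"))
  needed <- c(spec$ru5p_id, spec$co2_id, spec$target_metabolite_id)
  missing <- setdiff(needed, model$metabolites$id)
  if (length(missing)) {
    stop("model lacks metabolite(s): ", paste(missing, collapse = ", "))
  }
  if (!spec$rubp_id %in% model$metabolites$id) {
    model$metabolites <- dplyr::bind_rows(
      model$metabolites,
      tibble::tibble(id = spec$rubp_id, name = "ribulose-1,5-bisphosphate",
                     compartment = "c"))
  }
  prk_st <- stats::setNames(c(-1, 1), c(spec$ru5p_id, spec$rubp_id))
  rub_st <- stats::setNames(c(-1, -1, 2),
                            c(spec$rubp_id, spec$co2_id,
                              spec$target_metabolite_id))
  model <- .add_reaction(model, spec$prk_id, prk_st)
  model <- .add_reaction(model, spec$rubisco_id, rub_st)
  validate_model(model)
}

.add_reaction <- function(model, id, stoich, lower = 0, upper = 1000) {
  existing <- match(id, model$reactions$id)
  if (!is.na(existing)) {
    old <- model$reactions$stoichiometry[[existing]]
    same <- length(old) == length(stoich) &&
      setequal(names(old), names(stoich)) &&
      all(abs(old[names(stoich)] - stoich) < 1e-12)
    if (!same) {
      stop("reaction id '", id, "' already exists with different stoichiometry")
    }
    return(model)
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = id, stoichiometry = list(stoich),
                   lower_bound = lower, upper_bound = upper,
                   is_exchange = FALSE))
  model
}

#' Does a knockout set make growth rubisco-dependent?
#'
#' A deletion set is rubisco-dependent on a carbon source when the knocked-out
#' model cannot grow without the detour (objective < 1e-6) but grows once prk
#' and rubisco are added (objective >= 1e-6).
#'
#' @param model a `metabolic_model` *without* the heterologous reactions.
#' @param ko character vector of reaction ids to delete (may be empty).
#' @param het a [heterologous_spec()].
#' @param source optional exchange reaction id; when given, the model is
#'   configured for that sole carbon source via [set_carbon_source()].
#' @param max_uptake uptake bound used with `source`.
#' @return A one-row tibble: `growth_without`, `growth_with`, `dependent`.
#' @export
rubisco_dependence_test <- function(model, ko, het, source = NULL,
                                    max_uptake = 10) {
  if (!is.null(source)) {
    model <- set_carbon_source(model, source, max_uptake)
  }
  without <- fba(apply_knockouts(model, ko))
  with_het <- fba(apply_knockouts(add_heterologous(model, het), ko))
  g0 <- if (without$status == "optimal") without$objective_value else 0
  g1 <- if (with_het$status == "optimal") with_het$objective_value else 0
  tibble::tibble(
    growth_without = g0,
    growth_with = g1,
    dependent = g0 < .ZERO_GROWTH && g1 >= .ZERO_GROWTH
  )
}

#' Coupling between rubisco flux and biomass production
#'
#' For a rubisco-dependent design, fixes biomass at `n_grid` evenly spaced
#' values in `(0, mu_max]`, minimizes the rubisco flux at each, and fits
#' slope and intercept by least squares. A positive slope means every unit of
#' biomass *requires* rubisco flux -- the coupling that makes a knockout
#' strain a rubisco selection platform. The grid is kept for audit so other
#' functionals of the coupling curve can be recomputed.
#'
#' @param model a `metabolic_model` already carrying the knockouts and the
#'   heterologous reactions.
#' @param het a [heterologous_spec()] (names the rubisco reaction).
#' @param n_grid number of biomass grid points (>= 3).
#' @return An object of class `coupling_fit` with fields `slope`, `intercept`
#'   and `grid` (tibble `biomass`, `min_rubisco`). `tidy()` returns the
#'   coefficient table, `glance()` a one-row summary, `autoplot()` the curve.
#' @export
coupling_slope <- function(model, het, n_grid = 5) {
  stopifnot(n_grid >= 3)
  base <- fba(model)
  if (base$status != "optimal" || base$objective_value < .ZERO_GROWTH) {
    stop("model does not grow; coupling slope undefined")
  }
  mu <- base$objective_value * seq_len(n_grid) / n_grid
  min_rub <- vapply(mu, function(m) {
    .optimize_at_biomass(model, het$rubisco_id, m)$value
  }, numeric(1))
  fit <- stats::lm(min_rub ~ mu)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         grid = tibble::tibble(biomass = mu, min_rubisco = min_rub),
         rubisco_id = het$rubisco_id),
    class = "coupling_fit"
  )
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat("<coupling_fit> min ", x$rubisco_id, " = ",
      format(x$slope, digits = 4), " * biomass + ",
      format(x$intercept, digits = 4), "  (", nrow(x$grid),
      " grid points)\n", sep = "")
  invisible(x)
}

#' @rdname coupling_slope
#' @param x a `coupling_fit`.
#' @param ... unused.
#' @export
tidy.coupling_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname coupling_slope
#' @export
glance.coupling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_grid = nrow(x$grid),
                 biomass_max = max(x$grid$biomass))
}

#' @rdname coupling_slope
#' @param object a `coupling_fit`.
#' @export
autoplot.coupling_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$biomass, y = .data$min_rubisco)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "biomass flux (1/h)",
                  y = paste("minimum", object$rubisco_id, "flux"),
                  title = "Rubisco flux / biomass coupling") +
    ggplot2::theme_minimal()
}

#' Screen knockout sets for rubisco-coupled growth
#'
#' Tests every subset of `candidate_rxns` of size up to `max_size` on every
#' carbon source, keeps those that are rubisco-dependent on at least one
#' source (see [rubisco_dependence_test()]), and reports the coupling slope
#' and intercept per retained candidate and source. The enumeration is
#' exhaustive and the output deterministically sorted by (deletion size,
#' lexicographic ids, source), so repeated runs are identical.
#'
#' @param model host `metabolic_model` without heterologous reactions.
#' @param het a [heterologous_spec()].
#' @param sources character vector of exchange reaction ids.
#' @param candidate_rxns reactions eligible for deletion; must exclude
#'   exchanges and the objective. Defaults to all non-exchange, non-objective,
#'   non-heterologous reactions.
#' @param max_size 1 or 2.
#' @param max_uptake uptake bound applied per source.
#' @param n_grid grid size for [coupling_slope()].
#' @return A tibble with columns `deleted_ids` (ids joined by `";"`),
#'   `n_deleted`, `source`, `growth_without`, `growth_with`, `slope`,
#'   `intercept`. Zero rows when nothing qualifies.
#' @export
scan_knockouts <- function(model, het, sources, candidate_rxns = NULL,
                           max_size = 2, max_uptake = 10, n_grid = 5) {
  stopifnot(max_size %in% c(1, 2), length(sources) >= 1)
  validate_model(model)
  if (is.null(candidate_rxns)) {
    rxn <- model$reactions
    candidate_rxns <- rxn$id[!rxn$is_exchange &
                               rxn$id != model$objective &
                               !rxn$id %in% c(het$prk_id, het$rubisco_id)]
  }
  if (length(candidate_rxns) == 0) stop("empty candidate reaction list")
  bad <- candidate_rxns[candidate_rxns %in%
                          c(model$reactions$id[model$reactions$is_exchange],
                            model$objective)]
  if (length(bad)) {
    stop("candidate reactions must exclude exchanges and the objective: ",
         paste(bad, collapse = ", "))
  }
  subsets <- purrr::map(seq_len(max_size), function(k) {
    utils::combn(sort(candidate_rxns), k, simplify = FALSE)
  })
  subsets <- purrr::flatten(subsets)
  rows <- purrr::map_dfr(subsets, function(ko) {
    per_source <- purrr::map_dfr(sources, function(src) {
      dep <- rubisco_dependence_test(model, ko, het, source = src,
                                     max_uptake = max_uptake)
      dplyr::mutate(dep, source = src)
    })
    if (!any(per_source$dependent)) return(tibble::tibble())
    per_source <- dplyr::filter(per_source, .data$dependent)
    slopes <- purrr::map_dfr(per_source$source, function(src) {
      m <- set_carbon_source(model, src, max_uptake)
      m <- apply_knockouts(add_heterologous(m, het), ko)
      fit <- coupling_slope(m, het, n_grid = n_grid)
      tibble::tibble(source = src, slope = fit$slope,
                     intercept = fit$intercept)
    })
    per_source |>
      dplyr::left_join(slopes, by = "source") |>
      dplyr::transmute(
        deleted_ids = paste(ko, collapse = ";"),
        n_deleted = length(ko),
        source = .data$source,
        growth_without = .data$growth_without,
        growth_with = .data$growth_with,
        slope = .data$slope,
        intercept = .data$intercept
      )
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(deleted_ids = character(), n_deleted = integer(),
                          source = character(), growth_without = numeric(),
                          growth_with = numeric(), slope = numeric(),
                          intercept = numeric()))
  }
  dplyr::arrange(rows, .data$n_deleted, .data$deleted_ids, .data$source)
}

#' FBA-predicted fraction of 3PG production due to rubisco
#'
#' At the FBA optimum, computes rubisco's share of the gross production flux
#' into the target (3PG) metabolite, counting only positive contributions.
#' Two accountings are offered. `"molecules"` (default) counts both product
#' molecules of each carboxylation (numerator `2 v_rubisco`), the convention
#' consistent with the labeling mixture model in which the pool-dilution
#' parameter `d` separately tracks which molecule carries the CO2-derived
#' carboxyl carbon. `"events"` counts one unit per carboxylation event in
#' both numerator and denominator. The range comes from re-evaluating the
#' share on the flux distributions at the FVA extremes of the rubisco flux.
#'
#' @param model a `metabolic_model` carrying knockouts and the detour.
#' @param het a [heterologous_spec()].
#' @param at_fraction_of_optimum biomass fraction for the FVA range.
#' @param accounting `"molecules"` or `"events"`.
#' @return A one-row tibble: `point`, `lo`, `hi` (percent), `accounting`.
#' @export
predicted_rubisco_3pg_fraction <- function(model, het,
                                           at_fraction_of_optimum = 1,
                                           accounting = c("molecules",
                                                          "events")) {
  accounting <- match.arg(accounting)
  sol <- fba(model)
  if (sol$status != "optimal" || sol$objective_value < .ZERO_GROWTH) {
    stop("model does not grow; 3PG fraction undefined")
  }
  pct_of <- function(fluxes) {
    .rubisco_share(model, het, fluxes, accounting)
  }
  point <- pct_of(sol$fluxes)
  # flux vectors at the FVA extremes of the rubisco flux
  p <- .lp_parts(model)
  obj_row <- as.numeric(p$ids == model$objective)
  A <- matrix(-obj_row, nrow = 1)
  target_obj <- at_fraction_of_optimum * sol$objective_value
  rhs <- -(target_obj - 1e-9 * max(1, abs(target_obj)))
  i <- .rxn_index(model, het$rubisco_id)
  target <- as.numeric(seq_along(p$ids) == i)
  extreme <- function(maximize) {
    ans <- .solve_flux_lp(target, p$S, p$lb, p$ub, A = A, rhs = rhs,
                          maximize = maximize)
    if (ans$status != "optimal") {
      stop("FVA infeasible at fraction ", at_fraction_of_optimum)
    }
    pct_of(stats::setNames(ans$v, p$ids))
  }
  range_pct <- sort(c(extreme(FALSE), extreme(TRUE)))
  tibble::tibble(point = point, lo = range_pct[1], hi = range_pct[2],
                 accounting = accounting)
}

.rubisco_share <- function(model, het, fluxes, accounting) {
  target <- het$target_metabolite_id
  v_rub <- fluxes[[het$rubisco_id]]
  production <- 0
  rub_production <- 0
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[j]]
    if (!target %in% names(s)) next
    contrib <- s[[target]] * fluxes[[model$reactions$id[j]]]
    if (contrib <= 0) next
    if (model$reactions$id[j] == het$rubisco_id) {
      rub_production <- contrib  # = 2 v_rubisco by the spec invariant
    } else {
      production <- production + contrib
    }
  }
  if (accounting == "events") rub_production <- v_rub
  total <- production + rub_production
  if (total <= .ZERO_GROWTH) {
    stop("no production flux into '", target, "'; fraction undefined")
  }
  100 * rub_production / total
}
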
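# Linear programming backend -------------------------------------------------
#
# All flux optimizations go through .solve_flux_lp(), which encodes the flux
# problem in standard form for the in-package simplex (R/lp.R). Variables are
# shifted (x = v - lb) so the solver sees a non-negative box, infinite bounds
# are capped at .FLUX_CAP (well above any flux a bounded toy or core model can
# carry), and every reported optimum is verified against mass balance and
# bounds before it is returned. A single solver configuration is used
# throughout; alternate optima are a matter for flux_variability(), never for
# a particular returned vertex.

.FLUX_CAP <- 1e4
.MASS_BALANCE_TOL <- 1e-6
.BOUND_TOL <- 1e-9
.ZERO_GROWTH <- 1e-6

# maximize/minimize obj'v subject to S v = 0, lb <= v <= ub, A v <= rhs
.solve_flux_lp <- function(obj, S, lb, ub, A = NULL, rhs = NULL,
                           maximize = TRUE) {
  n <- length(obj)
  lb_c <- pmax(lb, -.FLUX_CAP)
  ub_c <- pmin(ub, .FLUX_CAP)
  box <- ub_c - lb_c
  m <- nrow(S)
  k <- if (is.null(A)) 0L else nrow(A)
  # z = (x, s_box, s_ineq) >= 0:
  #   S x = -S lb ; x + s_box = box ; A x + s_ineq = rhs - A lb
  Amat <- rbind(
    cbind(unname(S), matrix(0, m, n + k)),
    cbind(diag(n), diag(n), matrix(0, n, k))
  )
  bvec <- c(as.numeric(-S %*% lb_c), box)
  if (k > 0) {
    Amat <- rbind(Amat, cbind(A, matrix(0, k, n), diag(k)))
    bvec <- c(bvec, rhs - as.numeric(A %*% lb_c))
  }
  cost <- c(if (maximize) -obj else obj, rep(0, n + k))
  ans <- .simplex_core(cost, Amat, bvec)
  if (ans$status != "optimal") {
    return(list(status = "infeasible", objective_value = NA_real_,
                v = rep(NA_real_, n)))
  }
  v <- ans$z[seq_len(n)] + lb_c
  resid <- max(abs(S %*% v))
  if (resid > .MASS_BALANCE_TOL ||
      any(v < lb_c - 1e-7) || any(v > ub_c + 1e-7)) {
    return(list(status = "infeasible", objective_value = NA_real_,
                v = rep(NA_real_, n)))
  }
  # clean tiny violations so downstream invariants hold exactly
  v <- pmin(pmax(v, lb_c), ub_c)
  value <- sum(obj * v)
  status <- "optimal"
  # an optimum pinned at the cap of an infinite bound is an unbounded direction
  at_cap <- abs(v) >= 0.999 * .FLUX_CAP
  inf_bound <- !is.finite(lb) | !is.finite(ub)
  if (any(at_cap & inf_bound) && abs(value) >= 0.999 * .FLUX_CAP) {
    status <- "unbounded"
  }
  list(status = status, objective_value = value, v = v)
}

.lp_parts <- function(model) {
  list(S = stoichiometric_matrix(model),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

#' Flux balance analysis
#'
#' Maximizes the biomass objective flux subject to steady-state mass balance
#' `S v = 0` and the model's flux bounds. Infeasible or unbounded problems are
#' reported through `status`, never as silent zeros. Optima satisfy
#' `max |S v| < 1e-6` and the bounds to within 1e-9; objective values below
#' 1e-6 count as "no growth" for the screens built on top of this.
#'
#' @param model a `metabolic_model`.
#' @return An object of class `fba_solution`: fields `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, `fluxes` (named
#'   numeric), `objective` (reaction id). Use [generics::tidy()] for a tibble
#'   of fluxes and [generics::glance()] for a one-row summary.
#' @examples
#' toy <- make_toy_model()
#' sol <- fba(toy)
#' sol$objective_value # 3.75 at glycerol uptake 10
#' @export
fba <- function(model) {
  validate_model(model)
  p <- .lp_parts(model)
  obj <- as.numeric(p$ids == model$objective)
  ans <- .solve_flux_lp(obj, p$S, p$lb, p$ub, maximize = TRUE)
  structure(
    list(status = ans$status,
         objective_value = if (ans$status == "optimal") ans$objective_value else NA_real_,
         fluxes = stats::setNames(ans$v, p$ids),
         objective = model$objective),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective (", x$objective, ") = ",
        format(x$objective_value, digits = 6), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname fba
#' @param x an `fba_solution`.
#' @param ... unused.
#' @export
tidy.fba_solution <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @rdname fba
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 n_reactions = length(x$fluxes))
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux while the
#' biomass objective is constrained to at least `fraction_of_optimum` times
#' the FBA optimum. The FBA flux always lies in the returned interval at
#' fraction 1.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id one or more reaction ids.
#' @param fraction_of_optimum number in `[0, 1]`.
#' @return A tibble with columns `reaction`, `min_flux`, `max_flux`.
#' @export
flux_variability <- function(model, reaction_id, fraction_of_optimum = 1) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  validate_model(model)
  idx <- .rxn_index(model, reaction_id)
  base <- fba(model)
  if (base$status != "optimal") {
    stop("FBA is ", base$status, "; flux variability undefined")
  }
  p <- .lp_parts(model)
  obj_row <- as.numeric(p$ids == model$objective)
  A <- matrix(-obj_row, nrow = 1)
  target_obj <- fraction_of_optimum * base$objective_value
  rhs <- -(target_obj - 1e-9 * max(1, abs(target_obj)))
  one_dir <- function(i, maximize) {
    target <- as.numeric(seq_along(p$ids) == i)
    ans <- .solve_flux_lp(target, p$S, p$lb, p$ub, A = A, rhs = rhs,
                          maximize = maximize)
    if (ans$status == "infeasible") {
      stop("flux variability infeasible at fraction_of_optimum = ",
           fraction_of_optimum)
    }
    ans$objective_value
  }
  tibble::tibble(
    reaction = model$reactions$id[idx],
    min_flux = vapply(idx, one_dir, numeric(1), maximize = FALSE),
    max_flux = vapply(idx, one_dir, numeric(1), maximize = TRUE)
  )
}

# minimize (or maximize) one reaction's flux with the biomass flux pinned
.optimize_at_biomass <- function(model, reaction_id, biomass_value,
                                 maximize = FALSE) {
  p <- .lp_parts(model)
  i <- .rxn_index(model, reaction_id)
  lb <- p$lb
  ub <- p$ub
  j <- match(model$objective, p$ids)
  # tiny backoff so a biomass value carrying LP round-off (e.g. the FBA
  # optimum itself) still intersects the feasible set
  lb[j] <- biomass_value - 1e-9 * max(1, abs(biomass_value))
  ub[j] <- biomass_value
  target <- as.numeric(seq_along(p$ids) == i)
  ans <- .solve_flux_lp(target, p$S, lb, ub, maximize = maximize)
  if (ans$status != "optimal") {
    stop("infeasible at biomass = ", format(biomass_value))
  }
  list(value = ans$objective_value,
       fluxes = stats::setNames(ans$v, p$ids))
}
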
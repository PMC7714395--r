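# Rubisco kinetics under competitive O2 inhibition. CO2 and O2 compete for
# the same enamine intermediate, so each gas acts as a competitive inhibitor
# of the other: elevated CO2 raises carboxylation and suppresses oxygenation
# without changing either v_max. Concentrations are in uM throughout;
# dissolved-gas/Henry-law conversions are up to the caller.

#' Rubisco kinetic constants
#'
#' No default values are supplied: the constants differ several-fold across
#' rubisco forms, so they are required inputs. A representative Form IA-like
#' example set used in this package's documentation is
#' `rubisco_kinetics(kcat_c = 10, K_c = 150, kcat_o = 1, K_o = 200)`.
#'
#' @param kcat_c carboxylation turnover number (1/s).
#' @param K_c CO2 half-saturation constant (uM).
#' @param kcat_o oxygenation turnover number (1/s).
#' @param K_o O2 half-saturation constant (uM).
#' @return An object of class `rubisco_kinetics`.
#' @export
rubisco_kinetics <- function(kcat_c, K_c, kcat_o, K_o) {
  vals <- c(kcat_c = kcat_c, K_c = K_c, kcat_o = kcat_o, K_o = K_o)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all kinetic constants must be strictly positive and finite")
  }
  structure(as.list(vals), class = "rubisco_kinetics")
}

#' @export
print.rubisco_kinetics <- function(x, ...) {
  cat("<rubisco_kinetics> kcat_C = ", x$kcat_c, "/s, K_C = ", x$K_c,
      " uM, kcat_O = ", x$kcat_o, "/s, K_O = ", x$K_o, " uM, S_C/O = ",
      format(specificity_ratio(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Specificity ratio S_C/O
#'
#' The ratio of catalytic efficiencies `(kcat_C/K_C) / (kcat_O/K_O)`; by the
#' competing-substrates rate laws, `v_C / v_O = S_C/O * [CO2]/[O2]` exactly.
#'
#' @param k a [rubisco_kinetics()].
#' @return Dimensionless specificity ratio.
#' @export
specificity_ratio <- function(k) {
  (k$kcat_c / k$K_c) / (k$kcat_o / k$K_o)
}

.check_conc <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals) & !is.infinite(vals)) || any(vals < 0)) {
    stop("gas concentrations must be non-negative")
  }
}

#' Per-active-site carboxylation rate
#'
#' `v_C = kcat_C [CO2] / ([CO2] + K_C (1 + [O2]/K_O))` -- Michaelis-Menten
#' with O2 as a competitive inhibitor. Vectorized over concentrations.
#'
#' @param k a [rubisco_kinetics()].
#' @param co2,o2 concentrations (uM).
#' @return Rate(s) in 1/s, in `[0, kcat_C)`.
#' @export
carboxylation_rate <- function(k, co2, o2) {
  .check_conc(co2, o2)
  k$kcat_c * co2 / (co2 + k$K_c * (1 + o2 / k$K_o))
}

#' Per-active-site oxygenation rate
#'
#' `v_O = kcat_O [O2] / ([O2] + K_O (1 + [CO2]/K_C))`: the same form with the
#' roles of the two gases exchanged, so raising CO2 suppresses oxygenation.
#'
#' @inheritParams carboxylation_rate
#' @return Rate(s) in 1/s, in `[0, kcat_O)`.
#' @export
oxygenation_rate <- function(k, co2, o2) {
  .check_conc(co2, o2)
  k$kcat_o * o2 / (o2 + k$K_o * (1 + co2 / k$K_c))
}

#' Carboxylation/oxygenation rates over a CO2 grid
#'
#' One row per CO2 grid point at a fixed O2 concentration; the 270 uM default
#' corresponds to air-equilibrated water.
#'
#' @param k a [rubisco_kinetics()].
#' @param co2_grid ascending CO2 concentrations (uM), non-empty.
#' @param o2 O2 concentration (uM).
#' @return A tibble of class `rate_table`: `co2_uM`, `o2_uM`, `v_c`, `v_o`.
#' @export
rate_curve_table <- function(k, co2_grid, o2 = 270) {
  if (length(co2_grid) == 0) stop("co2_grid must be non-empty")
  if (is.unsorted(co2_grid, strictly = FALSE)) {
    stop("co2_grid must be ascending")
  }
  .check_conc(co2_grid, o2)
  out <- tibble::tibble(
    co2_uM = as.numeric(co2_grid),
    o2_uM = o2,
    v_c = carboxylation_rate(k, co2_grid, o2),
    v_o = oxygenation_rate(k, co2_grid, o2)
  )
  class(out) <- c("rate_table", class(out))
  out
}

#' Plot carboxylation and oxygenation rate curves
#'
#' @param object a `rate_table` from [rate_curve_table()].
#' @param ... unused.
#' @return A ggplot: rates vs CO2 on a log axis.
#' @export
autoplot.rate_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("v_c", "v_o"),
                              names_to = "reaction", values_to = "rate")
  long$reaction <- dplyr::recode(long$reaction,
                                 v_c = "carboxylation", v_o = "oxygenation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$co2_uM, y = .data$rate,
                                     colour = .data$reaction)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(carboxylation = "#2e7d32",
                                            oxygenation = "grey40")) +
    ggplot2::labs(x = expression("[CO"[2] * "] (uM)"),
                  y = "rate per active site (1/s)", colour = NULL) +
    ggplot2::theme_minimal()
}
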
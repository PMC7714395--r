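# 13C label arithmetic and the rubisco flux-fraction estimator.
#
# Cultures are grown on 99% 13C glycerol, so 12CO2 from ambient air is the
# dominant source of 12C. 3PG made by lower glycolysis inherits the
# substrate's (almost fully 13C) carbon; 3PG made by rubisco carries a
# CO2-derived -- mostly 12C -- carbon at its carboxyl position in half of the
# product molecules (one of the two 3PG per carboxylation). Serine is made
# from 3PG carbon-for-carbon, so excess 12C on serine, and specifically on
# its carboxyl carbon, reports the rubisco share of 3PG synthesis.

#' Total 13C fraction of an isotopologue distribution
#'
#' The weighted average of the isotopologue fractions:
#' `f13C = sum_i f_i * i / N`, where `f_i` is the fraction of molecules
#' carrying `i` heavy carbons out of `N`.
#'
#' @param fractions numeric vector `(f_0, ..., f_N)`; must be non-negative
#'   and sum to 1 within 1e-6.
#' @return The 13C atom fraction, in `[0, 1]`.
#' @export
total_13c_fraction <- function(fractions) {
  .check_distribution(fractions)
  n <- length(fractions) - 1L
  sum(fractions * (0:n)) / n
}

#' Total 12C fraction of an isotopologue distribution
#'
#' The complement `f12C = 1 - f13C`.
#'
#' @inheritParams total_13c_fraction
#' @return The 12C atom fraction, in `[0, 1]`.
#' @export
total_12c_fraction <- function(fractions) {
  1 - total_13c_fraction(fractions)
}

.check_distribution <- function(fractions) {
  if (length(fractions) < 2) {
    stop("need fractions for at least 1 carbon (length N + 1 >= 2)")
  }
  if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9)) {
    stop("isotopologue fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("isotopologue fractions must sum to 1 (got ",
         format(sum(fractions)), ")")
  }
  invisible(fractions)
}

#' Per-compound label fractions from a long isotopologue table
#'
#' Computes `f13C` and `f12C` for every compound/replicate/role combination
#' of a long-form isotopologue table (the on-disk CSV dialect).
#'
#' @param iso data frame with columns `compound`, `n_carbons`, `replicate`,
#'   `role`, `m_plus`, `fraction`.
#' @return A tibble with one row per compound x role x replicate and columns
#'   `f13c`, `f12c`.
#' @export
label_fractions <- function(iso) {
  req <- c("compound", "n_carbons", "replicate", "role", "m_plus", "fraction")
  if (!all(req %in% names(iso))) {
    stop("isotopologue table needs columns: ", paste(req, collapse = ", "))
  }
  iso |>
    dplyr::group_by(.data$compound, .data$role, .data$replicate) |>
    dplyr::arrange(.data$m_plus, .by_group = TRUE) |>
    dplyr::summarise(
      f13c = total_13c_fraction(.data$fraction),
      .groups = "drop"
    ) |>
    dplyr::mutate(f12c = 1 - .data$f13c)
}

#' Carboxyl-carbon 13C fraction from an MRM fragment pair
#'
#' The serine M+2 parent ion is fragmented into two daughter channels whose
#' undetected fragment contains the carboxyl carbon: channel A (61.1 m/z,
#' carboxyl 13C) and channel B (62.1 m/z, carboxyl 12C). The carboxyl 13C
#' fraction among M+2 ions is the integral ratio `A / (A + B)`, invariant
#' under joint rescaling of the two integrals.
#'
#' @param peak_a integral of the carboxyl-13C channel (61.1 m/z).
#' @param peak_b integral of the carboxyl-12C channel (62.1 m/z).
#' @return Fraction(s) in `[0, 1]`; vectorized.
#' @export
mrm_carboxyl_13c <- function(peak_a, peak_b) {
  if (any(peak_a < 0) || any(peak_b < 0)) stop("peak integrals must be >= 0")
  tot <- peak_a + peak_b
  if (any(tot == 0)) stop("peak integrals must not both be zero")
  peak_a / tot
}

# Invert the M+2-conditional carboxyl 12C fraction u to the marginal carboxyl
# 12C probability p. With iid non-carboxyl 12C probability b per position and
# N = 3 serine carbons, conditioning on exactly one 12C (the M+2 ions) gives
#   u = p (1-b)^2 / (p (1-b)^2 + 2 b (1-b) (1-p))
# whose inversion is the odds relation p/(1-p) = 2 b u / ((1-b)(1-u)).
# The control (p = b) always lands at u = 1/3, so the control MRM channel
# carries no information about b itself.
.mrm_conditional_to_marginal <- function(u, b) {
  if (any(u >= 1)) stop("conditional carboxyl 12C fraction must be < 1")
  odds <- 2 * b * u / ((1 - b) * (1 - u))
  odds / (1 + odds)
}

#' Estimate the rubisco-derived fraction of 3PG synthesis
#'
#' Fits the two-source mixture model for serine labeling. Glycolytic 3PG has
#' per-carbon 12C probability `b`, measured from the rubisco-independent
#' control; rubisco-derived 3PG additionally carries a CO2-derived carbon
#' (12C with probability `c_co2`) at the carboxyl position in a fraction `d`
#' of its molecules. Writing `x` for the fraction of 3PG production due to
#' rubisco:
#' \itemize{
#'   \item `total_serine` mode: the excess is diluted over serine's three
#'     carbons, `f12C_exp = b + x d (c - b) / 3`, so
#'     `x = 3 (f12C_exp - b) / (d (c - b))`.
#'   \item `carboxyl_mrm` mode: the marginal carboxyl 12C fraction obeys
#'     `f12C_cbx = b + x d (c - b)`, so `x = (f12C_cbx - b) / (d (c - b))`.
#'     Because MRM measures the carboxyl state *within the M+2 population*,
#'     the measured conditional fraction is first inverted to the marginal
#'     (see the paper-facing vignette); `b` comes from the control's total
#'     serine 12C, since the control's conditional fraction is 1/3 for any b.
#' }
#' Estimates are clipped to `[0, 1]` with an explicit flag -- never silently.
#'
#' @param iso long isotopologue table (see [label_fractions()]) containing a
#'   serine entry for every replicate of both roles (`"experiment"`,
#'   `"control"`).
#' @param mrm optional MRM table with columns `replicate`, `role`,
#'   `peak_61_1`, `peak_62_1`; required for `mode = "carboxyl_mrm"`.
#' @param mode `"carboxyl_mrm"` or `"total_serine"`.
#' @param c_co2 12C fraction of intracellular CO2 (0.989 for ambient air).
#' @param d pool dilution: fraction of rubisco-derived 3PG molecules carrying
#'   the CO2 carbon (1/2: one of the two products per carboxylation).
#' @param compound compound used for the estimate (serine).
#' @return An object of class `flux_fraction_estimate`: `per_replicate`
#'   tibble (`replicate`, `x_raw`, `x`, `clipped`), `mean`, `min`, `b`,
#'   and the mixture inputs echoed for audit. `tidy()` returns the
#'   per-replicate table, `glance()` a one-row summary.
#' @export
estimate_rubisco_fraction <- function(iso, mrm = NULL,
                                      mode = c("carboxyl_mrm", "total_serine"),
                                      c_co2 = 0.989, d = 0.5,
                                      compound = "serine") {
  mode <- match.arg(mode)
  stopifnot(c_co2 > 0, c_co2 <= 1, d > 0, d <= 1)
  lf <- label_fractions(iso) |> dplyr::filter(.data$compound == !!compound)
  if (nrow(lf) == 0) stop("no '", compound, "' rows in the isotopologue table")
  ctrl <- dplyr::filter(lf, .data$role == "control")
  exp_ <- dplyr::filter(lf, .data$role == "experiment")
  if (nrow(ctrl) == 0 || nrow(exp_) == 0) {
    stop("need both 'experiment' and 'control' replicates for '",
         compound, "'")
  }
  b <- mean(ctrl$f12c)
  if (c_co2 <= b) {
    stop("no isotopic contrast: CO2 12C fraction c (", format(c_co2),
         ") must exceed the background b (", format(b), ")")
  }
  if (mode == "total_serine") {
    per <- tibble::tibble(
      replicate = exp_$replicate,
      x_raw = 3 * (exp_$f12c - b) / (d * (c_co2 - b))
    )
  } else {
    if (is.null(mrm)) stop("mode 'carboxyl_mrm' requires an MRM table")
    req <- c("replicate", "role", "peak_61_1", "peak_62_1")
    if (!all(req %in% names(mrm))) {
      stop("MRM table needs columns: ", paste(req, collapse = ", "))
    }
    mexp <- dplyr::filter(mrm, .data$role == "experiment")
    if (nrow(mexp) == 0) stop("MRM table has no experiment replicates")
    u <- 1 - mrm_carboxyl_13c(mexp$peak_61_1, mexp$peak_62_1)
    p <- .mrm_conditional_to_marginal(u, b)
    per <- tibble::tibble(
      replicate = mexp$replicate,
      x_raw = (p - b) / (d * (c_co2 - b))
    )
  }
  per$x <- pmin(pmax(per$x_raw, 0), 1)
  # flag genuine truncation, not float round-off at the boundaries
  per$clipped <- per$x_raw < -1e-9 | per$x_raw > 1 + 1e-9
  structure(
    list(per_replicate = per, mean = mean(per$x), min = min(per$x),
         mode = mode, b = b, c_co2 = c_co2, d = d, compound = compound,
         any_clipped = any(per$clipped)),
    class = "flux_fraction_estimate"
  )
}

#' @export
print.flux_fraction_estimate <- function(x, ...) {
  cat("<flux_fraction_estimate> mode: ", x$mode, ", ",
      nrow(x$per_replicate), " replicates\n", sep = "")
  cat("  mean x = ", format(x$mean, digits = 4),
      ", min x = ", format(x$min, digits = 4),
      ", background b = ", format(x$b, digits = 4), sep = "")
  if (x$any_clipped) cat("  [some estimates clipped to [0, 1]]")
  cat("\n")
  invisible(x)
}

#' @rdname estimate_rubisco_fraction
#' @param x a `flux_fraction_estimate`.
#' @param ... unused.
#' @export
tidy.flux_fraction_estimate <- function(x, ...) {
  x$per_replicate
}

#' @rdname estimate_rubisco_fraction
#' @export
glance.flux_fraction_estimate <- function(x, ...) {
  tibble::tibble(mean = x$mean, min = x$min,
                 n_replicates = nrow(x$per_replicate), mode = x$mode,
                 b = x$b, c_co2 = x$c_co2, d = x$d,
                 any_clipped = x$any_clipped)
}

#' Compare a labeling estimate with the FBA prediction
#'
#' @param est a [estimate_rubisco_fraction()] result (fractions in `[0, 1]`).
#' @param pred a one-row data frame with `point`, `lo`, `hi` in percent, as
#'   returned by [predicted_rubisco_3pg_fraction()].
#' @return A one-row tibble: `estimate_mean`, `prediction_point`,
#'   `prediction_lo`, `prediction_hi` (all percent), `inside_range`, `gap`
#'   (absolute distance, percentage points, from the estimate mean to the
#'   prediction interval; 0 when inside).
#' @export
compare_to_fba <- function(est, pred) {
  stopifnot(inherits(est, "flux_fraction_estimate"))
  mean_pct <- 100 * est$mean
  lo <- pred$lo[1]
  hi <- pred$hi[1]
  inside <- mean_pct >= lo && mean_pct <= hi
  gap <- if (inside) 0 else min(abs(mean_pct - lo), abs(mean_pct - hi))
  tibble::tibble(
    estimate_mean = mean_pct,
    prediction_point = pred$point[1],
    prediction_lo = lo, prediction_hi = hi,
    inside_range = inside, gap = gap
  )
}
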
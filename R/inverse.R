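# Inverse estimation of phi and theta from measurements, prediction error
# metrics, and the validation suites against the published reference tables.

#' Fit a molecule's osmotic coefficient from a measured pressure
#'
#' `phi = pi_exp / (RT * C)`: the ratio of the measured osmotic pressure to
#' the ideal van 't Hoff prediction at the same concentration. This is the
#' osmometric route to phi, quantifying how far the solution deviates from
#' ideality at that concentration.
#'
#' @param pressure_measured Measured osmotic pressure in the context's unit,
#'   >= 0.
#' @param conc Molar concentration in mol/L, > 0.
#' @param context A [thermo_context()].
#' @return The osmotic coefficient (numeric scalar).
#' @examples
#' ctx <- thermo_context(295.15, "bar", gas_constant = 24.54 / 295.15)
#' fit_osmotic_coefficient(4.77, 0.200, ctx)   # ~0.972
#' @export
fit_osmotic_coefficient <- function(pressure_measured, conc, context) {
  stopifnot(is.numeric(pressure_measured), length(pressure_measured) == 1L,
            is.numeric(conc), length(conc) == 1L,
            inherits(context, "osmo_context"))
  if (!is.finite(conc) || conc <= 0) stop("concentration must be > 0 to fit phi")
  if (!is.finite(pressure_measured) || pressure_measured < 0) {
    stop("measured pressure must be >= 0")
  }
  pressure_measured / (context$rt * conc)
}

#' Fit the osmosis-system coefficient from an osmometer reading
#'
#' `theta = corrected osmolar activity / C_TSP`. Both arguments must be on
#' the same concentration scale (both mOsm/L or both osmol/L); theta is their
#' dimensionless ratio.
#'
#' @param activity Corrected osmolar activity (measured effective
#'   osmolarity), >= 0.
#' @param ctsp Total-solute-particle concentration on the same scale, > 0.
#' @return A [system_coefficient()] with source `"fitted_from_activity"`.
#' @examples
#' fit_theta_from_activity(282.0, 299.8)   # theta ~0.9406 (plasma)
#' @export
fit_theta_from_activity <- function(activity, ctsp) {
  stopifnot(is.numeric(activity), length(activity) == 1L,
            is.numeric(ctsp), length(ctsp) == 1L)
  if (!is.finite(ctsp) || ctsp <= 0) stop("C_TSP must be > 0 to fit theta")
  if (!is.finite(activity) || activity < 0) stop("activity must be >= 0")
  system_coefficient(activity / ctsp, source = "fitted_from_activity")
}

#' Fit the osmosis-system coefficient from a measured pressure
#'
#' Solves `pi = theta * C_TSP * RT` for theta. Round-trips through
#' [extended_pressure()] to within floating tolerance.
#'
#' @param pressure_measured Measured osmotic pressure in the context's unit.
#' @param ctsp Total-solute-particle concentration in osmol/L, > 0.
#' @param context A [thermo_context()].
#' @return A [system_coefficient()] with source `"fitted_from_pressure"`.
#' @export
fit_theta_from_pressure <- function(pressure_measured, ctsp, context) {
  stopifnot(is.numeric(pressure_measured), length(pressure_measured) == 1L,
            is.numeric(ctsp), length(ctsp) == 1L,
            inherits(context, "osmo_context"))
  if (!is.finite(ctsp) || ctsp <= 0) stop("C_TSP must be > 0 to fit theta")
  system_coefficient(pressure_measured / (context$rt * ctsp),
                     source = "fitted_from_pressure")
}

#' Absolute and relative prediction error
#'
#' `absolute = pi_pred - pi_corr`; `relative = 100 * absolute / pi_pred`
#' (percent of the prediction). Positive values mean the ideal prediction
#' overshoots the corrected pressure.
#'
#' @param pressure_predicted Predicted pressure; must be > 0 for the relative
#'   error.
#' @param pressure_corrected Corrected (activity-based or measured) pressure.
#' @return A list with elements `absolute` and `relative`.
#' @export
prediction_errors <- function(pressure_predicted, pressure_corrected) {
  stopifnot(is.numeric(pressure_predicted), is.numeric(pressure_corrected))
  if (any(!is.finite(pressure_predicted)) || any(pressure_predicted <= 0)) {
    stop("predicted pressure must be > 0 for a relative error")
  }
  abs_err <- pressure_predicted - pressure_corrected
  list(absolute = abs_err, relative = 100 * abs_err / pressure_predicted)
}

new_validation_report <- function(table, cells) {
  pass <- all(cells$matched[!cells$flagged])
  structure(list(table = table, cells = cells, pass = pass),
            class = "osmo_validation")
}

#' @export
print.osmo_validation <- function(x, ...) {
  cat(sprintf("<osmo_validation> %s: %s (%d/%d cells matched, %d flagged)\n",
              x$table, if (x$pass) "PASS" else "FAIL",
              sum(x$cells$matched), nrow(x$cells), sum(x$cells$flagged)))
  invisible(x)
}

validation_cells <- function(table, row, column, expected, computed, rule) {
  flagged <- mapply(function(r, col) {
    kd <- .known_discrepancies[[table]]
    any(kd$row == r & kd$column == col)
  }, row, column, USE.NAMES = FALSE)
  data.frame(
    row = row, column = column,
    expected = expected, computed = computed,
    rounding = rule,
    matched = abs(expected - computed) < 1e-9,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Validate the unified law against the sucrose osmometry table
#'
#' Recomputes, for every row of [sucrose_osmometry()], the ideal prediction
#' `pi_pred = RT * C` (RT = 24.54 L·bar/mol, 3 dp), the signed error
#' `pi_exp - pi_pred` (3 dp), the osmotic coefficient
#' `phi = pi_exp / (RT * C)` (3 dp) and the effective osmotic concentration
#' `OC0 = sigma * phi * C` with sigma = 1 (4 dp, formed from the rounded
#' phi), and compares each against the published cell. Two cells of the most
#' dilute row carry extra precision not derivable from the printed inputs;
#' they are flagged as known discrepancies and excluded from the pass flag
#' rather than silently matched.
#'
#' @return An `osmo_validation` report: `$cells` holds one row per compared
#'   cell (expected, computed, rounding rule, match and flag status),
#'   `$pass` is `TRUE` iff every non-flagged cell matches.
#' @export
validate_sucrose_table <- function() {
  ref <- sucrose_osmometry()
  k <- reference_constants()
  ctx <- thermo_context(k$t_sucrose_K, "bar",
                        gas_constant = k$rt_sucrose_bar / k$t_sucrose_K)
  sigma <- 1  # membrane impermeable to sucrose

  rows <- character(); cols <- character()
  expected <- numeric(); computed <- numeric(); rule <- character()
  for (i in seq_len(nrow(ref))) {
    cc <- ref$conc[i]
    lab <- sprintf("%.3f", cc)
    pi_pred <- round(osmotic_pressure(cc, ctx)$value, 3)
    err <- round(ref$pi_exp[i] - pi_pred, 3)
    phi <- round(fit_osmotic_coefficient(ref$pi_exp[i], cc, ctx), 3)
    oc0 <- round(sigma * phi * cc, 4)

    rows <- c(rows, rep(lab, 4))
    cols <- c(cols, c("pi_pred", "error", "phi", "oc0"))
    expected <- c(expected, ref$pi_pred[i], ref$error[i], ref$phi[i], ref$oc0[i])
    computed <- c(computed, pi_pred, err, phi, oc0)
    rule <- c(rule, c("3dp", "3dp", "3dp", "4dp"))
  }
  new_validation_report("sucrose",
                        validation_cells("sucrose", rows, cols,
                                         expected, computed, rule))
}

#' Validate the extended law against the body-fluid table
#'
#' Recomputes, for each compartment of [body_fluids()], the system
#' coefficient `theta = activity / C_TSP` (4 dp), the predicted pressure
#' `pi_pred = C_TSP * RT` and corrected pressure `pi_corr = activity * RT`
#' (RT = 19.3421 mmHg/mOsm, nearest integer), the absolute error formed from
#' the rounded integers, and the relative error (2 dp), and compares each
#' against the published cell. Four intracellular cells disagree with
#' recomputation by one unit of rounding; they are flagged as known
#' discrepancies and excluded from the pass flag.
#'
#' @return An `osmo_validation` report (see [validate_sucrose_table()]).
#' @export
validate_body_fluids <- function() {
  ref <- body_fluids()
  k <- reference_constants()
  # context with RT equal to the printed per-mOsm factor, scaled to osmol/L
  ctx <- thermo_context(k$t_body_K, "mmHg",
                        gas_constant = k$rt_body_mmHg_per_mosm * 1000 / k$t_body_K)

  rows <- character(); cols <- character()
  expected <- numeric(); computed <- numeric(); rule <- character()
  for (i in seq_len(nrow(ref))) {
    lab <- ref$fluid[i]
    ctsp_osm <- ref$ctsp[i] / 1000      # mOsm/L -> osmol/L
    act_osm <- ref$activity[i] / 1000
    theta <- round(fit_theta_from_activity(ref$activity[i], ref$ctsp[i])$theta, 4)
    pi_pred <- round(osmotic_pressure(ctsp_osm, ctx)$value)
    pi_corr <- round(osmotic_pressure(act_osm, ctx)$value)
    errs <- prediction_errors(pi_pred, pi_corr)
    abs_err <- errs$absolute
    rel_err <- round(errs$relative, 2)

    rows <- c(rows, rep(lab, 5))
    cols <- c(cols, c("theta", "pi_pred", "pi_corr", "abs_error", "rel_error"))
    expected <- c(expected, ref$theta[i], ref$pi_pred[i], ref$pi_corr[i],
                  ref$abs_error[i], ref$rel_error[i])
    computed <- c(computed, theta, pi_pred, pi_corr, abs_err, rel_err)
    rule <- c(rule, c("4dp", "int", "int", "int-diff", "2dp"))
  }
  new_validation_report("body_fluids",
                        validation_cells("body_fluids", rows, cols,
                                         expected, computed, rule))
}
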
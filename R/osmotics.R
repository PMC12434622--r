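# OC0 (both sigma-application methods), osmotic pressure, the extended
# theta-form pressure, electroneutrality applicability, and unit conversion.

#' Initial osmotic concentration, molecule-based (method 1)
#'
#' `OC0 = sum_j g_j sigma_j phi_j C_j`: the membrane-dependent, osmotically
#' effective fraction of the total solute particles, applying the reflection
#' coefficient per molecule and folding in each molecule's osmotic
#' coefficient. This is the preferred method when non-ideality matters, since
#' phi is defined per molecule, not per dissociated ion. Equals
#' [ctsp_nonideal()] under an ideal membrane.
#'
#' @param sol A [solution()].
#' @param mem A [membrane()].
#' @return Concentration in osmol/L.
#' @export
oc0_molecule_based <- function(sol, mem) {
  stopifnot(inherits(sol, "osmo_solution"), inherits(mem, "osmo_membrane"))
  if (length(sol$solutes) == 0L) return(0)
  total <- 0
  for (k in seq_along(sol$solutes)) {
    s <- sol$solutes[[k]]
    sig <- sigma_for_molecule(mem, s$name)
    total <- total + s$g * sig * resolve_phi(s, sol$conc[k]) * sol$conc[k]
  }
  total
}

#' Initial osmotic concentration, particle-based (method 2)
#'
#' `OC0 = sum_i sigma_i C_i` over the solution's particle view, applying the
#' reflection coefficient per particle species. Carries no osmotic-coefficient
#' factor: this form assumes an ideal solution. Equivalent to method 1
#' whenever all phi = 1 and, within each molecule, every constituent species
#' shares the molecule's sigma.
#'
#' @inheritParams oc0_molecule_based
#' @return Concentration in osmol/L.
#' @export
oc0_particle_based <- function(sol, mem) {
  stopifnot(inherits(sol, "osmo_solution"), inherits(mem, "osmo_membrane"))
  pv <- particle_view(sol)
  if (nrow(pv) == 0L) return(0)
  sig <- vapply(pv$species, sigma_for_species, numeric(1), membrane = mem)
  sum(sig * pv$conc)
}

new_pressure_result <- function(value, oc0, context) {
  structure(list(value = value, unit = context$pressure_unit,
                 oc0 = oc0, context = context),
            class = "osmo_pressure")
}

#' @export
print.osmo_pressure <- function(x, ...) {
  cat(sprintf("<osmo_pressure> %.6g %s  (OC = %.6g osmol/L, T = %.2f K)\n",
              x$value, x$unit, x$oc0, x$context$temperature))
  invisible(x)
}

#' Osmotic pressure from an osmotic concentration
#'
#' The unified law `pi = RT * OC0`: pressure in the context's unit from a
#' nonnegative osmotic concentration.
#'
#' @param oc0 Osmotic concentration in osmol/L, >= 0.
#' @param context A [thermo_context()].
#' @return An `osmo_pressure` object with fields `value`, `unit`, `oc0`,
#'   `context`.
#' @examples
#' osmotic_pressure(0.2550, thermo_context(295.15, "bar"))
#' @export
osmotic_pressure <- function(oc0, context) {
  stopifnot(is.numeric(oc0), length(oc0) == 1L, inherits(context, "osmo_context"))
  if (!is.finite(oc0) || oc0 < 0) stop("osmotic concentration must be >= 0")
  new_pressure_result(context$rt * oc0, oc0, context)
}

#' Osmosis-system coefficient
#'
#' theta is a system-level empirical coefficient in the extended law
#' `pi = theta * C_TSP * RT`; `theta * C_TSP` generalises OC0 and absorbs
#' non-ideal behaviour that per-solute coefficients cannot represent. theta
#' cannot be derived from first principles: it is fitted from a measured
#' pressure ([fit_theta_from_pressure()]) or from an osmometer reading
#' ([fit_theta_from_activity()]); theta = 1 recovers the ideal law.
#'
#' @param theta Positive dimensionless coefficient.
#' @param source One of `"assumed"`, `"fitted_from_pressure"`,
#'   `"fitted_from_activity"`.
#' @return An object of class `osmo_theta`.
#' @export
system_coefficient <- function(theta,
                               source = c("assumed", "fitted_from_pressure",
                                          "fitted_from_activity")) {
  source <- match.arg(source)
  stopifnot(is.numeric(theta), length(theta) == 1L)
  if (!is.finite(theta) || theta <= 0) {
    stop("theta must be a finite positive number")
  }
  structure(list(theta = as.numeric(theta), source = source),
            class = "osmo_theta")
}

#' @export
print.osmo_theta <- function(x, ...) {
  cat(sprintf("<osmo_theta> theta = %.6g (%s)\n", x$theta, x$source))
  invisible(x)
}

#' Extended-form osmotic pressure
#'
#' `pi = theta * C_TSP * RT`. With theta = 1 this reproduces
#' [osmotic_pressure()] on the same concentration exactly.
#'
#' @param ctsp Total-solute-particle concentration in osmol/L, >= 0.
#' @param theta A [system_coefficient()] or a positive number.
#' @param context A [thermo_context()].
#' @return An `osmo_pressure` object; its `oc0` field holds the effective
#'   concentration `theta * ctsp`.
#' @export
extended_pressure <- function(ctsp, theta, context) {
  stopifnot(is.numeric(ctsp), length(ctsp) == 1L, inherits(context, "osmo_context"))
  if (!is.finite(ctsp) || ctsp < 0) stop("ctsp must be >= 0")
  if (is.numeric(theta)) theta <- system_coefficient(theta)
  stopifnot(inherits(theta, "osmo_theta"))
  eff <- theta$theta * ctsp
  new_pressure_result(context$rt * eff, eff, context)
}

#' Electroneutrality applicability check
#'
#' The per-species reflection-coefficient formulas apply only when the
#' membrane is exclusively impermeable to all cations or to all anions:
#' otherwise permeant counter-ions diffuse to keep both compartments
#' electrically neutral and the printed forms lose validity. This check
#' returns a verdict, not an error: `"PASS"` when every at-all-permeant
#' (sigma < 1) charged species shares one charge sign (or none exists),
#' `"WARN"` naming an offending cation/anion pair otherwise.
#'
#' @inheritParams oc0_molecule_based
#' @return An object of class `osmo_verdict` with fields `verdict`
#'   (`"PASS"`/`"WARN"`), `detail`, and `offending` (character vector of
#'   species names, empty on pass).
#' @export
electroneutrality_check <- function(sol, mem) {
  stopifnot(inherits(sol, "osmo_solution"), inherits(mem, "osmo_membrane"))
  pv <- particle_view(sol)
  charged <- pv[pv$charge != 0L, , drop = FALSE]
  if (nrow(charged)) {
    sig <- vapply(charged$species, sigma_for_species, numeric(1), membrane = mem)
    permeant <- charged[sig < 1, , drop = FALSE]
  } else {
    permeant <- charged
  }
  if (nrow(permeant) == 0L ||
      all(permeant$charge > 0L) || all(permeant$charge < 0L)) {
    return(structure(list(verdict = "PASS",
                          detail = "permeant charged species confined to one sign (or none)",
                          offending = character()),
                     class = "osmo_verdict"))
  }
  cat_name <- permeant$species[permeant$charge > 0L][1]
  an_name <- permeant$species[permeant$charge < 0L][1]
  structure(list(
    verdict = "WARN",
    detail = sprintf(
      "membrane permeant to both cation '%s' and anion '%s'; per-species sigma forms may not apply",
      cat_name, an_name),
    offending = c(cat_name, an_name)),
    class = "osmo_verdict")
}

#' @export
print.osmo_verdict <- function(x, ...) {
  cat(sprintf("<osmo_verdict> %s: %s\n", x$verdict, x$detail))
  invisible(x)
}

# Pressure-unit conversion factors: units per bar
.per_bar <- c(bar = 1, mmHg = 750.062, atm = 0.986923)

#' Convert a pressure between units
#'
#' Exact factor conversion among bar, mmHg and atm
#' (1 bar = 750.062 mmHg = 0.986923 atm).
#'
#' @param value Pressure value (vectorised).
#' @param from,to Unit names from `"bar"`, `"mmHg"`, `"atm"`.
#' @return Converted pressure.
#' @examples
#' convert_pressure(1, "bar", "mmHg")   # 750.062
#' @export
convert_pressure <- function(value, from, to) {
  stopifnot(is.numeric(value))
  if (!from %in% names(.per_bar)) stop(sprintf("unknown pressure unit '%s'", from))
  if (!to %in% names(.per_bar)) stop(sprintf("unknown pressure unit '%s'", to))
  value / .per_bar[[from]] * .per_bar[[to]]
}
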
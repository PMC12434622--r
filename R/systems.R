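# Simple, composite and complex osmosis systems: mirrored deconstruction,
# pressure gradients, and the osmosis/diffusion split of complex systems.

#' Simple osmosis system (solution | membrane | water)
#'
#' One solution compartment facing pure water across a selectively permeable
#' membrane — the arrangement in which the initial osmotic concentration OC0
#' is defined. The second compartment is implicitly pure water.
#'
#' @param sol A [solution()].
#' @param mem A [membrane()]; ideal by default.
#' @param context A [thermo_context()].
#' @return An object of class `osmo_simple_system`.
#' @export
simple_system <- function(sol, mem = membrane(), context = thermo_context()) {
  stopifnot(inherits(sol, "osmo_solution"), inherits(mem, "osmo_membrane"),
            inherits(context, "osmo_context"))
  structure(list(solution = sol, membrane = mem, context = context),
            class = "osmo_simple_system")
}

#' Composite osmosis system (solution 1 | membrane | solution 2)
#'
#' Two solution compartments sharing one membrane and one thermodynamic
#' context. Osmosis in a composite system is a competition for water between
#' the two compartments' osmotic concentrations; see [composite_gradient()].
#'
#' @param sol1,sol2 [solution()]s for compartments 1 and 2.
#' @param mem Shared [membrane()].
#' @param context Shared [thermo_context()].
#' @return An object of class `osmo_composite_system`.
#' @export
composite_system <- function(sol1, sol2, mem = membrane(),
                             context = thermo_context()) {
  stopifnot(inherits(sol1, "osmo_solution"), inherits(sol2, "osmo_solution"),
            inherits(mem, "osmo_membrane"), inherits(context, "osmo_context"))
  structure(list(solution_1 = sol1, solution_2 = sol2,
                 membrane = mem, context = context),
            class = "osmo_composite_system")
}

#' Deconstruct a composite system into two mirrored simple systems
#'
#' S1-m-S2 splits into S1-m-H2O and H2O-m-S2: each compartment faces pure
#' water across the shared membrane. The signed difference of the two simple
#' systems' pressures reassembles the composite's gradient (see
#' [composite_gradient()]); swapping the compartments swaps the pair.
#'
#' @param sys An [composite_system()].
#' @return A list with elements `s1` and `s2`, each an
#'   `osmo_simple_system` sharing the composite's membrane and context.
#' @export
deconstruct_composite <- function(sys) {
  stopifnot(inherits(sys, "osmo_composite_system"))
  list(s1 = simple_system(sys$solution_1, sys$membrane, sys$context),
       s2 = simple_system(sys$solution_2, sys$membrane, sys$context))
}

new_gradient_result <- function(delta_pi, oc0_1, oc0_2, context) {
  direction <- if (delta_pi > 0) "solution_1"
               else if (delta_pi < 0) "solution_2"
               else "none"
  structure(list(delta_pi = delta_pi, unit = context$pressure_unit,
                 direction = direction, oc0_1 = oc0_1, oc0_2 = oc0_2,
                 context = context),
            class = "osmo_gradient")
}

#' @export
print.osmo_gradient <- function(x, ...) {
  cat(sprintf("<osmo_gradient> delta_pi = %.6g %s (water flows toward %s)\n",
              x$delta_pi, x$unit, x$direction))
  cat(sprintf("  OC_1 = %.6g, OC_2 = %.6g osmol/L\n", x$oc0_1, x$oc0_2))
  invisible(x)
}

#' Osmotic pressure gradient of a composite system
#'
#' `delta_pi = RT * (OC0(S1) - OC0(S2))`, the sum of the two mirrored simple
#' systems' van 't Hoff equations with opposite orientations. The sign
#' convention is fixed: positive delta_pi means net water movement toward
#' compartment 1 (the compartment with the larger OC0).
#'
#' @param sys A [composite_system()].
#' @param method `"molecule"` for [oc0_molecule_based()] (default, carries
#'   phi) or `"particle"` for [oc0_particle_based()].
#' @return An `osmo_gradient` with fields `delta_pi`, `unit`, `direction`
#'   (`"solution_1"`, `"solution_2"` or `"none"`), `oc0_1`, `oc0_2`.
#' @export
composite_gradient <- function(sys, method = c("molecule", "particle")) {
  stopifnot(inherits(sys, "osmo_composite_system"))
  method <- match.arg(method)
  oc_fun <- if (method == "molecule") oc0_molecule_based else oc0_particle_based
  oc1 <- oc_fun(sys$solution_1, sys$membrane)
  oc2 <- oc_fun(sys$solution_2, sys$membrane)
  new_gradient_result(sys$context$rt * (oc1 - oc2), oc1, oc2, sys$context)
}

#' Extended-form pressure gradient of a composite system
#'
#' `delta_pi = theta * (C_TSP(S1) - C_TSP(S2)) * RT`, with a single
#' system-level coefficient applied to both compartments (the caller asserts
#' this is appropriate). C_TSP here is the ideal `sum g_j C_j`: theta is
#' defined to absorb the non-ideality that per-solute phi would otherwise
#' carry. theta = 1 gives the ideal-law gradient.
#'
#' @param sys A [composite_system()].
#' @param theta A [system_coefficient()] or positive number.
#' @return An `osmo_gradient`; `oc0_1`/`oc0_2` hold the effective
#'   concentrations `theta * C_TSP`.
#' @export
extended_gradient <- function(sys, theta) {
  stopifnot(inherits(sys, "osmo_composite_system"))
  if (is.numeric(theta)) theta <- system_coefficient(theta)
  stopifnot(inherits(theta, "osmo_theta"))
  e1 <- theta$theta * ctsp_ideal(sys$solution_1)
  e2 <- theta$theta * ctsp_ideal(sys$solution_2)
  new_gradient_result(sys$context$rt * (e1 - e2), e1, e2, sys$context)
}

#' Split a complex system into osmosis and diffusion subsystems
#'
#' A system whose membrane passes some solutes non-negligibly is not a simple
#' osmosis system: it decomposes into a simple osmosis subsystem of the
#' impermeant solutes and a diffusion subsystem of the permeant ones (e.g. an
#' inulin + urea solution against a membrane tight to inulin but leaky to
#' urea). Classification is per molecule: a molecule with
#' `sigma_j >= sigma_cutoff` joins the osmosis subsystem, otherwise the
#' diffusion subsystem. The partition is exhaustive and disjoint. The
#' diffusion subsystem is represented, not simulated: no flux model is
#' attached.
#'
#' @param sol A [solution()].
#' @param mem A [membrane()].
#' @param sigma_cutoff Threshold in (0, 1] above which a molecule counts as
#'   impermeant; defaults to 0.95.
#' @param context A [thermo_context()] for the osmosis subsystem.
#' @return An object of class `osmo_split` with fields `osmosis_subsystem`
#'   (an `osmo_simple_system` of the retained molecules), `diffusion_subsystem`
#'   (`data.frame` of molecule, conc, sigma for the permeant ones), and
#'   `cutoff_used`.
#' @export
split_complex <- function(sol, mem, sigma_cutoff = 0.95,
                          context = thermo_context()) {
  stopifnot(inherits(sol, "osmo_solution"), inherits(mem, "osmo_membrane"))
  if (!is.numeric(sigma_cutoff) || length(sigma_cutoff) != 1L ||
      !is.finite(sigma_cutoff) || sigma_cutoff <= 0 || sigma_cutoff > 1) {
    stop("sigma_cutoff must lie in (0, 1]")
  }
  nm <- vapply(sol$solutes, `[[`, character(1), "name")
  sig <- vapply(nm, sigma_for_molecule, numeric(1), membrane = mem)
  keep <- sig >= sigma_cutoff
  osmosis_sol <- solution(sol$solutes[keep], sol$conc[keep])
  diffusion <- data.frame(molecule = nm[!keep], conc = sol$conc[!keep],
                          sigma = unname(sig[!keep]), stringsAsFactors = FALSE)
  structure(list(
    osmosis_subsystem = simple_system(osmosis_sol, mem, context),
    diffusion_subsystem = diffusion,
    cutoff_used = sigma_cutoff),
    class = "osmo_split")
}

#' @export
print.osmo_split <- function(x, ...) {
  n_os <- length(x$osmosis_subsystem$solution$solutes)
  cat(sprintf("<osmo_split> cutoff %.3g: %d impermeant molecule(s), %d permeant\n",
              x$cutoff_used, n_os, nrow(x$diffusion_subsystem)))
  invisible(x)
}
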
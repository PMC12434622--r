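# Domain types for solutes, solutions, membranes and thermodynamic context,
# plus the total-solute-particle (C_TSP) calculus.

#' Define a particle species
#'
#' A particle species is one kind of osmotically counted particle: an
#' undissociated molecule (charge 0) or a dissociated ion. Species are the
#' carriers of per-particle reflection coefficients and of the charge used by
#' the electroneutrality applicability check.
#'
#' @param name Species identifier, e.g. `"Na+"`. Must be a single non-empty
#'   string, unique within any one solution's particle view.
#' @param charge Signed integer charge in elementary-charge units; 0 for
#'   non-electrolytes.
#' @param count How many particles of this species one solute molecule
#'   releases on complete dissociation (used inside [solute()] stoichiometry).
#' @return An object of class `osmo_species`.
#' @examples
#' species("Na+", charge = 1)
#' species("SO4--", charge = -2)
#' @export
species <- function(name, charge = 0, count = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  charge <- as.integer(charge)
  count <- as.integer(count)
  if (is.na(charge)) stop("charge must be an integer")
  if (is.na(count) || count < 1L) stop("count must be an integer >= 1")
  structure(list(name = name, charge = charge, count = count),
            class = "osmo_species")
}

#' Define a solute molecule
#'
#' A solute molecule carries its dissociation number `g` (particles produced
#' per molecule under complete dissociation: glucose 1, NaCl 2, CaCl2 3), its
#' particle stoichiometry, and an osmotic-coefficient specification `phi`.
#'
#' `phi` corrects for solution non-ideality and is specific to the molecule
#' type. It is either a single constant, or a two-column table
#' (`conc` in mol/L, strictly increasing; `phi` > 0) that is interpolated
#' piecewise-linearly at the molecule's working concentration by
#' [resolve_phi()]. Concentrations outside the table range are an error (no
#' silent extrapolation).
#'
#' If `stoichiometry` is omitted, a molecule with `g = 1` dissolves as a
#' single neutral species bearing the molecule's own name; a molecule with
#' `g > 1` is represented by a single neutral placeholder species (same name,
#' count `g`). Supply explicit [species()] entries to model real ions.
#'
#' @param name Molecule identifier, unique within a solution.
#' @param g Dissociation number, integer >= 1.
#' @param phi Either a positive constant or a `data.frame` with columns
#'   `conc` and `phi`.
#' @param stoichiometry Optional list of [species()] objects whose counts sum
#'   to `g`.
#' @return An object of class `osmo_solute`.
#' @examples
#' glucose <- solute("glucose")
#' nacl <- solute("NaCl", g = 2,
#'                stoichiometry = list(species("Na+", 1), species("Cl-", -1)))
#' sucrose <- solute("sucrose", phi = data.frame(conc = c(0.1, 0.3),
#'                                               phi = c(0.933, 0.850)))
#' @export
solute <- function(name, g = 1L, phi = 1, stoichiometry = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop("dissociation number g must be an integer >= 1")

  if (is.null(stoichiometry)) {
    stoichiometry <- list(species(name, charge = 0L, count = g))
  }
  if (!is.list(stoichiometry) ||
      !all(vapply(stoichiometry, inherits, logical(1), "osmo_species"))) {
    stop("stoichiometry must be a list of species() objects")
  }
  counts <- vapply(stoichiometry, `[[`, integer(1), "count")
  if (sum(counts) != g) {
    stop(sprintf("stoichiometry counts sum to %d but g = %d for '%s'",
                 sum(counts), g, name))
  }
  sp_names <- vapply(stoichiometry, `[[`, character(1), "name")
  if (anyDuplicated(sp_names)) stop("duplicate species in stoichiometry")
  if (g == 1L && !identical(sp_names, name)) {
    stop("a non-dissociable molecule (g = 1) must have a single species ",
         "identical to the molecule itself")
  }

  phi <- validate_phi_spec(phi, name)
  structure(list(name = name, g = g, phi = phi, stoichiometry = stoichiometry),
            class = "osmo_solute")
}

validate_phi_spec <- function(phi, name) {
  if (is.numeric(phi) && length(phi) == 1L) {
    if (!is.finite(phi) || phi <= 0) {
      stop(sprintf("constant phi for '%s' must be a finite positive number", name))
    }
    return(phi)
  }
  if (is.data.frame(phi)) {
    if (!all(c("conc", "phi") %in% names(phi)) || nrow(phi) < 1L) {
      stop("phi table must have columns 'conc' and 'phi' and at least one row")
    }
    if (any(!is.finite(phi$conc)) || any(!is.finite(phi$phi))) {
      stop("phi table values must be finite")
    }
    if (is.unsorted(phi$conc, strictly = TRUE)) {
      stop("phi table concentrations must be strictly increasing")
    }
    if (any(phi$phi <= 0)) stop("phi table values must be positive")
    return(phi[, c("conc", "phi")])
  }
  stop(sprintf("phi for '%s' must be a positive constant or a (conc, phi) table", name))
}

#' Define a solution composition
#'
#' A solution is a list of solute molecules with their molar concentrations
#' (mol/L). An empty call, `solution()`, represents pure water.
#'
#' @param solutes List of [solute()] objects.
#' @param conc Numeric vector of concentrations in mol/L, one per solute,
#'   each >= 0.
#' @return An object of class `osmo_solution`.
#' @examples
#' sol <- solution(
#'   solutes = list(
#'     solute("glucose"),
#'     solute("NaCl", g = 2,
#'            stoichiometry = list(species("Na+", 1), species("Cl-", -1)))
#'   ),
#'   conc = c(0.005, 0.140)
#' )
#' @export
solution <- function(solutes = list(), conc = numeric()) {
  if (inherits(solutes, "osmo_solute")) solutes <- list(solutes)
  stopifnot(is.list(solutes), is.numeric(conc))
  if (length(solutes) != length(conc)) {
    stop("solutes and conc must have the same length")
  }
  if (!all(vapply(solutes, inherits, logical(1), "osmo_solute"))) {
    stop("solutes must be a list of solute() objects")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0")
  }
  nm <- vapply(solutes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate molecule name '%s' in solution", nm[duplicated(nm)][1]))
  }
  structure(list(solutes = solutes, conc = as.numeric(conc)),
            class = "osmo_solution")
}

#' @export
print.osmo_solution <- function(x, ...) {
  if (length(x$solutes) == 0L) {
    cat("<osmo_solution> pure water\n")
    return(invisible(x))
  }
  cat("<osmo_solution>", length(x$solutes), "solute(s)\n")
  for (k in seq_along(x$solutes)) {
    s <- x$solutes[[k]]
    cat(sprintf("  %-12s %.6g mol/L  (g = %d)\n", s$name, x$conc[k], s$g))
  }
  invisible(x)
}

#' Define a membrane by its reflection coefficients
#'
#' A membrane's permeability to a particle species or a whole molecule is its
#' reflection coefficient sigma in \[0, 1\]: 1 means impermeant, 0 freely
#' permeant. Coefficients can be given per particle species (used by the
#' particle-based osmotic concentration) and/or per molecule (used by the
#' molecule-based one); anything unlisted falls back to `default_sigma`.
#' `membrane()` with no arguments is an ideal membrane, permeable to water
#' only.
#'
#' @param default_sigma Fallback sigma in \[0, 1\] for unlisted entries.
#' @param sigma_molecule Named numeric vector, molecule name -> sigma.
#' @param sigma_species Named numeric vector, species name -> sigma.
#' @return An object of class `osmo_membrane`.
#' @examples
#' membrane()                                     # ideal
#' membrane(sigma_molecule = c(urea = 0.05))      # leaky to urea
#' @export
membrane <- function(default_sigma = 1, sigma_molecule = numeric(),
                     sigma_species = numeric()) {
  check_sigma <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
      stop(what, " must be a named numeric vector")
    }
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(what, " values must lie in [0, 1]")
    }
    x
  }
  stopifnot(is.numeric(default_sigma), length(default_sigma) == 1L)
  if (!is.finite(default_sigma) || default_sigma < 0 || default_sigma > 1) {
    stop("default_sigma must lie in [0, 1]")
  }
  structure(list(default_sigma = as.numeric(default_sigma),
                 sigma_molecule = check_sigma(sigma_molecule, "sigma_molecule"),
                 sigma_species = check_sigma(sigma_species, "sigma_species")),
            class = "osmo_membrane")
}

sigma_for_molecule <- function(membrane, name) {
  if (name %in% names(membrane$sigma_molecule)) {
    unname(membrane$sigma_molecule[[name]])
  } else {
    membrane$default_sigma
  }
}

sigma_for_species <- function(membrane, name) {
  if (name %in% names(membrane$sigma_species)) {
    unname(membrane$sigma_species[[name]])
  } else {
    membrane$default_sigma
  }
}

# Gas constant per pressure unit, L·unit·mol^-1·K^-1
.gas_constants <- c(bar = 0.0831446, mmHg = 62.3637, atm = 0.0820574)

#' Thermodynamic context: temperature and gas constant
#'
#' Bundles the absolute temperature and the gas constant expressed in the
#' active pressure unit, supplying the RT factor used by every pressure
#' computation. The constructor selects R to match `pressure_unit`
#' (0.0831446 L·bar/mol/K, 62.3637 L·mmHg/mol/K, 0.0820574 L·atm/mol/K)
#' unless `gas_constant` is given explicitly — useful to reproduce published
#' tables that used a rounded RT.
#'
#' @param temperature Absolute temperature in kelvin, > 0.
#' @param pressure_unit One of `"bar"`, `"mmHg"`, `"atm"`.
#' @param gas_constant Optional override for R, in L·(pressure_unit)/mol/K.
#' @return An object of class `osmo_context` with fields `temperature`,
#'   `pressure_unit`, `gas_constant` and the precomputed product `rt`.
#' @examples
#' thermo_context(310.15, "mmHg")   # body temperature, mmHg
#' @export
thermo_context <- function(temperature = 298.15,
                           pressure_unit = c("bar", "mmHg", "atm"),
                           gas_constant = NULL) {
  pressure_unit <- match.arg(pressure_unit)
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a positive number of kelvin")
  }
  if (is.null(gas_constant)) {
    gas_constant <- unname(.gas_constants[[pressure_unit]])
  } else {
    stopifnot(is.numeric(gas_constant), length(gas_constant) == 1L)
    if (!is.finite(gas_constant) || gas_constant <= 0) {
      stop("gas_constant must be positive")
    }
  }
  structure(list(temperature = as.numeric(temperature),
                 pressure_unit = pressure_unit,
                 gas_constant = as.numeric(gas_constant),
                 rt = as.numeric(gas_constant * temperature)),
            class = "osmo_context")
}

#' Expand a solution into its particle view
#'
#' Sums, for each particle species, the contributions of every molecule that
#' releases it: `C_i = sum_j count_ij * C_j`. The total over all species
#' equals the ideal total-solute-particle concentration [ctsp_ideal()].
#'
#' @param sol A [solution()].
#' @return A `data.frame` with columns `species`, `charge`, `conc` (mol/L),
#'   one row per species; zero rows for pure water.
#' @examples
#' nacl <- solute("NaCl", g = 2,
#'                stoichiometry = list(species("Na+", 1), species("Cl-", -1)))
#' particle_view(solution(list(nacl), 0.1))
#' @export
particle_view <- function(sol) {
  stopifnot(inherits(sol, "osmo_solution"))
  out <- list(species = character(), charge = integer(), conc = numeric())
  idx <- integer()
  seen <- character()
  for (k in seq_along(sol$solutes)) {
    s <- sol$solutes[[k]]
    for (sp in s$stoichiometry) {
      contrib <- sp$count * sol$conc[k]
      j <- match(sp$name, seen)
      if (is.na(j)) {
        seen <- c(seen, sp$name)
        out$species <- c(out$species, sp$name)
        out$charge <- c(out$charge, sp$charge)
        out$conc <- c(out$conc, contrib)
      } else {
        if (out$charge[j] != sp$charge) {
          stop(sprintf("species '%s' declared with conflicting charges", sp$name))
        }
        out$conc[j] <- out$conc[j] + contrib
      }
    }
  }
  data.frame(species = out$species, charge = out$charge, conc = out$conc,
             stringsAsFactors = FALSE)
}

#' Ideal total-solute-particle concentration
#'
#' `C_TSP = sum_j g_j C_j`, the molar concentration of total solute particles
#' under complete dissociation and ideal behaviour — an intrinsic solution
#' property (what conventional osmolarity measures in mOsm/L, here in
#' osmol/L).
#'
#' @param sol A [solution()].
#' @return Concentration in osmol/L (numeric scalar; 0 for pure water).
#' @export
ctsp_ideal <- function(sol) {
  stopifnot(inherits(sol, "osmo_solution"))
  if (length(sol$solutes) == 0L) return(0)
  g <- vapply(sol$solutes, `[[`, integer(1), "g")
  sum(g * sol$conc)
}

#' Resolve a molecule's osmotic coefficient at a concentration
#'
#' A constant specification returns its value; a tabular specification is
#' interpolated linearly between the bracketing rows. Concentrations outside
#' the table range signal an error rather than extrapolating.
#'
#' @param mol A [solute()].
#' @param conc Concentration in mol/L, >= 0.
#' @return The osmotic coefficient (numeric scalar).
#' @examples
#' sucrose <- solute("sucrose", phi = data.frame(conc = c(0.1, 0.3),
#'                                               phi = c(0.933, 0.850)))
#' resolve_phi(sucrose, 0.2)   # 0.8915
#' @export
resolve_phi <- function(mol, conc) {
  stopifnot(inherits(mol, "osmo_solute"), is.numeric(conc), length(conc) == 1L)
  if (!is.finite(conc) || conc < 0) stop("concentration must be finite and >= 0")
  spec <- mol$phi
  if (is.numeric(spec)) return(spec)
  if (nrow(spec) == 1L) {
    if (conc != spec$conc[1]) {
      stop(sprintf("phi for '%s' is tabulated only at %g mol/L (asked for %g)",
                   mol$name, spec$conc[1], conc))
    }
    return(spec$phi[1])
  }
  if (conc < min(spec$conc) || conc > max(spec$conc)) {
    stop(sprintf(
      "concentration %g mol/L outside the phi table range [%g, %g] for '%s'",
      conc, min(spec$conc), max(spec$conc), mol$name))
  }
  stats::approx(spec$conc, spec$phi, xout = conc, method = "linear")$y
}

#' Non-ideal total-solute-particle concentration
#'
#' `C_TSP = sum_j g_j phi_j(C_j) C_j`, with each molecule's osmotic
#' coefficient resolved at its own concentration via [resolve_phi()]. Reduces
#' to [ctsp_ideal()] when every phi equals 1.
#'
#' @param sol A [solution()].
#' @return Concentration in osmol/L (numeric scalar).
#' @export
ctsp_nonideal <- function(sol) {
  stopifnot(inherits(sol, "osmo_solution"))
  if (length(sol$solutes) == 0L) return(0)
  total <- 0
  for (k in seq_along(sol$solutes)) {
    s <- sol$solutes[[k]]
    total <- total + s$g * resolve_phi(s, sol$conc[k]) * sol$conc[k]
  }
  total
}
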
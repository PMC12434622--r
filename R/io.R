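# File readers/writers: CSV solute tables, JSON system specifications,
# and report serialisation.

num_or <- function(x, default = NA_real_) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x))) {
    return(default)
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("not a number: '%s'", x))
  v
}

#' Read a solute table (CSV) into a solution and membrane
#'
#' The file is comma-separated with the required header
#' `molecule,conc_mM,g,phi,sigma`. Each molecule row gives the concentration
#' in mM (converted to mol/L internally), the dissociation number `g`, an
#' optional constant osmotic coefficient `phi` (blank means 1) and an
#' optional molecule-level reflection coefficient `sigma` (blank means the
#' membrane default). A molecule row may be followed by per-species rows
#' whose first field starts with `+`: `+name,charge,count,sigma_i` — these
#' define the molecule's ion stoichiometry and optional per-species sigma.
#'
#' ```
#' molecule,conc_mM,g,phi,sigma
#' NaCl,140,2,0.93,
#' +Na+,1,1,
#' +Cl-,-1,1,
#' glucose,5,1,,
#' ```
#'
#' @param path Path to the CSV file.
#' @param default_sigma Membrane default reflection coefficient for entries
#'   without an explicit sigma.
#' @return A list with elements `solution` (an [solution()]) and `membrane`
#'   (a [membrane()] assembled from the sigma columns).
#' @export
read_solute_table <- function(path, default_sigma = 1) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         strip.white = TRUE, blank.lines.skip = TRUE)
  required <- c("molecule", "conc_mm", "g", "phi", "sigma")
  if (ncol(raw) < 5L ||
      !identical(tolower(names(raw))[seq_along(required)], required)) {
    stop("malformed header: expected 'molecule,conc_mM,g,phi,sigma'")
  }
  names(raw) <- tolower(names(raw))

  solutes <- list(); conc <- numeric()
  sigma_molecule <- numeric(); sigma_species <- numeric()
  cur <- NULL  # accumulator for the molecule row being assembled

  flush_cur <- function(cur) {
    if (is.null(cur)) return(NULL)
    stoich <- if (length(cur$species)) cur$species else NULL
    solute(cur$name, g = cur$g, phi = cur$phi, stoichiometry = stoich)
  }

  for (i in seq_len(nrow(raw))) {
    rowno <- i + 1L  # header is line 1
    first <- raw$molecule[i]
    if (startsWith(first, "+")) {
      if (is.null(cur)) {
        stop(sprintf("row %d: species row '%s' has no preceding molecule row",
                     rowno, first))
      }
      sp_name <- sub("^\\+", "", first)
      charge <- tryCatch(num_or(raw$conc_mm[i], 0),
                         error = function(e) stop(sprintf("row %d: %s", rowno,
                                                          conditionMessage(e))))
      count <- tryCatch(num_or(raw$g[i], 1),
                        error = function(e) stop(sprintf("row %d: %s", rowno,
                                                         conditionMessage(e))))
      sig_i <- tryCatch(num_or(raw$phi[i]),
                        error = function(e) stop(sprintf("row %d: %s", rowno,
                                                         conditionMessage(e))))
      if (!is.na(sig_i)) {
        if (sig_i < 0 || sig_i > 1) {
          stop(sprintf("row %d: sigma_i = %g outside [0, 1]", rowno, sig_i))
        }
        sigma_species[sp_name] <- sig_i
      }
      cur$species <- c(cur$species, list(species(sp_name, charge, count)))
    } else {
      s <- tryCatch(flush_cur(cur), error = function(e)
        stop(sprintf("row %d (molecule '%s'): %s", cur$rowno, cur$name,
                     conditionMessage(e))))
      if (!is.null(s)) { solutes <- c(solutes, list(s)); conc <- c(conc, cur$conc) }

      wrap <- function(expr) tryCatch(expr, error = function(e)
        stop(sprintf("row %d: %s", rowno, conditionMessage(e))))
      c_mM <- wrap(num_or(raw$conc_mm[i]))
      if (is.na(c_mM)) stop(sprintf("row %d: missing concentration", rowno))
      if (c_mM < 0) stop(sprintf("row %d: negative concentration %g", rowno, c_mM))
      g <- wrap(num_or(raw$g[i], 1))
      if (g < 1 || g != round(g)) {
        stop(sprintf("row %d: g must be an integer >= 1, got %g", rowno, g))
      }
      phi <- wrap(num_or(raw$phi[i], 1))
      sig <- wrap(num_or(raw$sigma[i]))
      if (!is.na(sig)) {
        if (sig < 0 || sig > 1) {
          stop(sprintf("row %d: sigma = %g outside [0, 1]", rowno, sig))
        }
        sigma_molecule[first] <- sig
      }
      cur <- list(name = first, conc = c_mM / 1000, g = as.integer(g),
                  phi = phi, species = list(), rowno = rowno)
    }
  }
  s <- tryCatch(flush_cur(cur), error = function(e)
    stop(sprintf("row %d (molecule '%s'): %s", cur$rowno, cur$name,
                 conditionMessage(e))))
  if (!is.null(s)) { solutes <- c(solutes, list(s)); conc <- c(conc, cur$conc) }

  list(solution = solution(solutes, conc),
       membrane = membrane(default_sigma = default_sigma,
                           sigma_molecule = sigma_molecule,
                           sigma_species = sigma_species))
}

solute_from_spec <- function(entry) {
  stoich <- NULL
  if (!is.null(entry$species)) {
    stoich <- lapply(entry$species, function(sp) {
      species(sp$name,
              charge = if (is.null(sp$charge)) 0 else sp$charge,
              count = if (is.null(sp$count)) 1 else sp$count)
    })
  }
  phi <- if (is.null(entry$phi)) 1 else entry$phi
  if (is.list(phi)) {
    phi <- data.frame(conc = unlist(phi$conc), phi = unlist(phi$phi))
  }
  solute(entry$name,
         g = if (is.null(entry$g)) 1L else entry$g,
         phi = phi, stoichiometry = stoich)
}

compartment_from_spec <- function(comp) {
  if (is.null(comp) || is.null(comp$solutes) || length(comp$solutes) == 0L) {
    return(solution())
  }
  solutes <- lapply(comp$solutes, solute_from_spec)
  conc <- vapply(comp$solutes, function(e) {
    if (is.null(e$conc_mM)) stop(sprintf("solute '%s' lacks conc_mM", e$name))
    e$conc_mM / 1000
  }, numeric(1))
  solution(solutes, conc)
}

#' Read a JSON system specification
#'
#' The document describes a simple or composite osmosis system:
#'
#' ```json
#' {
#'   "type": "composite",
#'   "compartment1": {"solutes": [
#'     {"name": "NaCl", "conc_mM": 140, "g": 2, "phi": 0.93,
#'      "species": [{"name": "Na+", "charge": 1, "count": 1},
#'                  {"name": "Cl-", "charge": -1, "count": 1}]}]},
#'   "compartment2": {"solutes": []},
#'   "membrane": {"default_sigma": 1,
#'                "sigma_by_molecule": {"urea": 0.05},
#'                "sigma_by_species": {}},
#'   "temperature_K": 310.15,
#'   "pressure_unit": "mmHg"
#' }
#' ```
#'
#' `type` may be omitted: a spec without `compartment2` is a simple system
#' (the water compartment is implicit). `phi` may be a number or an object
#' `{"conc": [...], "phi": [...]}` for a concentration-indexed coefficient.
#' Concentrations are mM at this boundary and converted to mol/L internally.
#'
#' @param path Path to the JSON file.
#' @return An [simple_system()] or [composite_system()].
#' @export
read_system_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  unit <- if (is.null(spec$pressure_unit)) "bar" else spec$pressure_unit
  if (!unit %in% c("bar", "mmHg", "atm")) {
    stop(sprintf("unknown pressure unit '%s'", unit))
  }
  ctx <- thermo_context(
    temperature = if (is.null(spec$temperature_K)) 298.15 else spec$temperature_K,
    pressure_unit = unit)

  m <- spec$membrane
  mem <- membrane(
    default_sigma = if (is.null(m$default_sigma)) 1 else m$default_sigma,
    sigma_molecule = unlist(m$sigma_by_molecule %||% list()),
    sigma_species = unlist(m$sigma_by_species %||% list()))

  type <- spec$type %||% if (is.null(spec$compartment2)) "simple" else "composite"
  if (type == "simple") {
    simple_system(compartment_from_spec(spec$compartment1), mem, ctx)
  } else if (type == "composite") {
    composite_system(compartment_from_spec(spec$compartment1),
                     compartment_from_spec(spec$compartment2), mem, ctx)
  } else {
    stop(sprintf("unknown system type '%s'", type))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

solution_to_spec <- function(sol) {
  list(solutes = lapply(seq_along(sol$solutes), function(k) {
    s <- sol$solutes[[k]]
    out <- list(name = s$name, conc_mM = sol$conc[k] * 1000, g = s$g)
    out$phi <- if (is.data.frame(s$phi)) {
      list(conc = s$phi$conc, phi = s$phi$phi)
    } else s$phi
    out$species <- lapply(s$stoichiometry, function(sp) {
      list(name = sp$name, charge = sp$charge, count = sp$count)
    })
    out
  }))
}

#' Write a system back to its JSON specification
#'
#' Inverse of [read_system_spec()]: re-reading the written document yields an
#' equivalent system (same compositions, membrane and context).
#'
#' @param sys An `osmo_simple_system` or `osmo_composite_system`.
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_system_spec <- function(sys, path = NULL) {
  mem <- sys$membrane
  spec <- list(
    type = if (inherits(sys, "osmo_simple_system")) "simple" else "composite",
    compartment1 = solution_to_spec(
      if (inherits(sys, "osmo_simple_system")) sys$solution else sys$solution_1),
    membrane = list(default_sigma = mem$default_sigma,
                    sigma_by_molecule = as.list(mem$sigma_molecule),
                    sigma_by_species = as.list(mem$sigma_species)),
    temperature_K = sys$context$temperature,
    pressure_unit = sys$context$pressure_unit)
  if (inherits(sys, "osmo_composite_system")) {
    spec$compartment2 <- solution_to_spec(sys$solution_2)
  }
  txt <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
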
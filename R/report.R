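# Structured computation reports and their deterministic serialisation.

#' Full computation report for an osmosis system
#'
#' For a simple system: ideal and non-ideal C_TSP, OC0 under the chosen
#' sigma-application method, the osmotic pressure, and the electroneutrality
#' applicability verdict. For a composite system: the same per compartment
#' plus the pressure gradient and flow direction.
#'
#' @param sys An `osmo_simple_system` or `osmo_composite_system`.
#' @param method `"molecule"` (default) or `"particle"`; see
#'   [oc0_molecule_based()] and [oc0_particle_based()].
#' @return An object of class `osmo_report` (a named list of quantities).
#' @export
system_report <- function(sys, method = c("molecule", "particle")) {
  method <- match.arg(method)
  oc_fun <- if (method == "molecule") oc0_molecule_based else oc0_particle_based
  one <- function(sol, mem, ctx) {
    oc0 <- oc_fun(sol, mem)
    list(ctsp_ideal = ctsp_ideal(sol),
         ctsp_nonideal = ctsp_nonideal(sol),
         oc0 = oc0,
         pi = osmotic_pressure(oc0, ctx)$value,
         verdict = electroneutrality_check(sol, mem))
  }
  if (inherits(sys, "osmo_simple_system")) {
    rep <- list(type = "simple", method = method,
                unit = sys$context$pressure_unit,
                compartment_1 = one(sys$solution, sys$membrane, sys$context))
  } else if (inherits(sys, "osmo_composite_system")) {
    rep <- list(type = "composite", method = method,
                unit = sys$context$pressure_unit,
                compartment_1 = one(sys$solution_1, sys$membrane, sys$context),
                compartment_2 = one(sys$solution_2, sys$membrane, sys$context),
                gradient = composite_gradient(sys, method))
  } else {
    stop("sys must be a simple or composite osmosis system")
  }
  structure(rep, class = "osmo_report")
}

#' @export
print.osmo_report <- function(x, ...) {
  cat(write_report(x, format = "text"), sep = "\n")
  invisible(x)
}

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Serialise a result as text, delimited or JSON
#'
#' Deterministic serialisation of computation results: the same input always
#' yields byte-identical output. Numeric fields are written at full
#' precision.
#'
#' @param x An `osmo_report`, `osmo_gradient`, `osmo_validation` or
#'   `osmo_split` object.
#' @param format `"text"` (human-readable), `"csv"` (delimited) or `"json"`.
#' @param path Optional file to write to.
#' @return A character vector of lines (invisibly when `path` is given).
#' @export
write_report <- function(x, format = c("text", "csv", "json"), path = NULL) {
  format <- match.arg(format)
  lines <- switch(class(x)[1],
    osmo_report = render_report(x, format),
    osmo_gradient = render_gradient(x, format),
    osmo_validation = render_validation(x, format),
    osmo_split = render_split(x, format),
    stop(sprintf("no report renderer for class '%s'", class(x)[1])))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

report_rows <- function(x) {
  comps <- grep("^compartment_", names(x), value = TRUE)
  rows <- do.call(rbind, lapply(comps, function(cn) {
    cmp <- x[[cn]]
    data.frame(compartment = cn,
               quantity = c("ctsp_ideal", "ctsp_nonideal", "oc0", "pi", "verdict"),
               value = c(fmt_num(cmp$ctsp_ideal), fmt_num(cmp$ctsp_nonideal),
                         fmt_num(cmp$oc0), fmt_num(cmp$pi), cmp$verdict$verdict),
               unit = c("osmol/L", "osmol/L", "osmol/L", x$unit, ""),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(x$gradient)) {
    g <- x$gradient
    rows <- rbind(rows, data.frame(
      compartment = "system",
      quantity = c("delta_pi", "direction"),
      value = c(fmt_num(g$delta_pi), g$direction),
      unit = c(x$unit, ""),
      stringsAsFactors = FALSE))
  }
  rows
}

df_to_csv <- function(df) {
  header <- paste(names(df), collapse = ",")
  body <- apply(df, 1L, function(r) paste(r, collapse = ","))
  c(header, unname(body))
}

render_report <- function(x, format) {
  rows <- report_rows(x)
  if (format == "csv") return(df_to_csv(rows))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(x), auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE,
                                         force = TRUE)))
  }
  c(sprintf("%s osmosis system (%s method, unit %s)", x$type, x$method, x$unit),
    sprintf("  %-14s %-14s %-22s %s", rows$compartment, rows$quantity,
            rows$value, rows$unit))
}

render_gradient <- function(x, format) {
  rows <- data.frame(
    quantity = c("oc0_1", "oc0_2", "delta_pi", "direction"),
    value = c(fmt_num(x$oc0_1), fmt_num(x$oc0_2), fmt_num(x$delta_pi),
              x$direction),
    unit = c("osmol/L", "osmol/L", x$unit, ""),
    stringsAsFactors = FALSE)
  if (format == "csv") return(df_to_csv(rows))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(x)[c("delta_pi", "unit",
                                                      "direction", "oc0_1",
                                                      "oc0_2")],
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  }
  sprintf("  %-10s %-22s %s", rows$quantity, rows$value, rows$unit)
}

render_validation <- function(x, format) {
  cells <- x$cells
  cells$expected <- fmt_num(cells$expected)
  cells$computed <- fmt_num(cells$computed)
  cells$matched <- ifelse(x$cells$matched, "yes", "no")
  cells$flagged <- ifelse(x$cells$flagged, "known-discrepancy", "")
  if (format == "csv") return(df_to_csv(cells))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(list(table = x$table, pass = x$pass,
                                              cells = x$cells),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  }
  c(sprintf("validation of %s table: %s", x$table,
            if (x$pass) "PASS" else "FAIL"),
    sprintf("  %-14s %-10s %-12s %-12s %-4s %s",
            c("row", cells$row), c("column", cells$column),
            c("expected", cells$expected), c("computed", cells$computed),
            c("ok", cells$matched), c("note", cells$flagged)))
}

render_split <- function(x, format) {
  os_sol <- x$osmosis_subsystem$solution
  os_mem <- x$osmosis_subsystem$membrane
  os_nm <- vapply(os_sol$solutes, `[[`, character(1), "name")
  rows <- data.frame(
    subsystem = c(rep("osmosis", length(os_nm)),
                  rep("diffusion", nrow(x$diffusion_subsystem))),
    molecule = c(os_nm, x$diffusion_subsystem$molecule),
    conc = fmt_num(c(os_sol$conc, x$diffusion_subsystem$conc)),
    stringsAsFactors = FALSE)
  oc0 <- oc0_molecule_based(os_sol, os_mem)
  pi <- osmotic_pressure(oc0, x$osmosis_subsystem$context)
  summary_rows <- c(
    sprintf("sigma cutoff: %s", fmt_num(x$cutoff_used)),
    sprintf("osmosis subsystem OC0: %s osmol/L", fmt_num(oc0)),
    sprintf("osmosis subsystem pi: %s %s", fmt_num(pi$value), pi$unit))
  if (format == "csv") return(df_to_csv(rows))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(cutoff = x$cutoff_used, oc0 = oc0, pi = pi$value, unit = pi$unit,
           partition = rows), auto_unbox = TRUE, digits = NA, pretty = TRUE)))
  }
  c(summary_rows,
    sprintf("  %-10s %-14s %s", c("subsystem", rows$subsystem),
            c("molecule", rows$molecule), c("conc mol/L", rows$conc)))
}
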
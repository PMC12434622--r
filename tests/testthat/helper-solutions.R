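# Shared constructors for test solutions and random-system generators.

nacl_solute <- function(phi = 1) {
  solute("NaCl", g = 2, phi = phi,
         stoichiometry = list(species("Na+", 1), species("Cl-", -1)))
}

mgso4_solute <- function(phi = 1) {
  solute("MgSO4", g = 2, phi = phi,
         stoichiometry = list(species("Mg++", 2), species("SO4--", -2)))
}

physiological_mix <- function() {
  solution(list(solute("glucose"), nacl_solute(), mgso4_solute()),
           c(0.005, 0.140, 0.001))
}

# Random solution of 1..4 molecules with random g (explicit neutral-ion
# stoichiometry so molecule- and particle-level sigmas can be aligned).
random_solution <- function(max_molecules = 4L, phi_one = TRUE, prefix = "mol") {
  n <- sample.int(max_molecules, 1L)
  solutes <- lapply(seq_len(n), function(k) {
    g <- sample.int(3L, 1L)
    nm <- sprintf("%s%d", prefix, k)
    stoich <- if (g == 1L) NULL else {
      lapply(seq_len(g), function(j) species(sprintf("%s_p%d", nm, j), 0, 1))
    }
    phi <- if (phi_one) 1 else stats::runif(1, 0.7, 1)
    solute(nm, g = g, phi = phi, stoichiometry = stoich)
  })
  solution(solutes, stats::runif(n, 0, 0.5))
}

# Membrane whose per-molecule sigma is copied onto each constituent species,
# so the two OC0 methods agree when phi = 1.
aligned_membrane <- function(sol, sigma = NULL) {
  nm <- vapply(sol$solutes, `[[`, character(1), "name")
  if (is.null(sigma)) sigma <- stats::runif(length(nm))
  sig_mol <- stats::setNames(sigma, nm)
  sig_sp <- numeric()
  for (k in seq_along(sol$solutes)) {
    for (sp in sol$solutes[[k]]$stoichiometry) {
      sig_sp[sp$name] <- sigma[k]
    }
  }
  membrane(default_sigma = 1, sigma_molecule = sig_mol, sigma_species = sig_sp)
}
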
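# OC0 under both sigma-application methods, pressures, applicability
# verdicts and unit conversion.

test_that("molecule-based OC0 applies g * sigma * phi * C per molecule", {
  suc <- solution(list(solute("sucrose", phi = 0.850)), 0.300)
  expect_equal(oc0_molecule_based(suc, membrane()), 0.2550)

  fully_permeable <- membrane(default_sigma = 0)
  expect_equal(oc0_molecule_based(physiological_mix(), fully_permeable), 0)

  sol <- solution(list(solute("glucose"), nacl_solute()), c(0.005, 0.140))
  mem <- membrane(sigma_molecule = c(glucose = 1, NaCl = 0.5))
  expect_equal(oc0_molecule_based(sol, mem), 0.145)
})

test_that("particle-based OC0 applies sigma_i * C_i with no phi factor", {
  nacl <- solution(list(nacl_solute()), 0.100)
  expect_equal(oc0_particle_based(nacl, membrane()), 0.200)
  expect_equal(oc0_particle_based(
    nacl, membrane(sigma_species = c("Na+" = 0.2, "Cl-" = 1))), 0.120)
  expect_equal(oc0_particle_based(solution(), membrane()), 0)
  # phi deliberately ignored on the particle route
  nonideal <- solution(list(nacl_solute(phi = 0.93)), 0.100)
  expect_equal(oc0_particle_based(nonideal, membrane()), 0.200)
})

test_that("osmotic pressure is RT * OC0 in the context's unit", {
  ctx <- thermo_context(295.15, "bar", gas_constant = 24.54 / 295.15)
  p <- osmotic_pressure(0.106, ctx)
  expect_equal(round(p$value, 3), 2.601)
  expect_identical(p$unit, "bar")

  expect_equal(osmotic_pressure(0, ctx)$value, 0)
  expect_error(osmotic_pressure(-0.1, ctx), ">= 0")

  # body-temperature prediction from a mOsm-scale concentration
  ctx_mmHg <- thermo_context(310.15, "mmHg", gas_constant = 62.3637)
  expect_equal(round(osmotic_pressure(300.8 / 1000, ctx_mmHg)$value), 5818)
})

test_that("extended pressure theta * C_TSP * RT and identity at theta = 1", {
  ctx <- thermo_context(310.15, "mmHg", gas_constant = 19.3421 * 1000 / 310.15)
  expect_equal(round(extended_pressure(282.0 / 1000, 1, ctx)$value), 5454)
  expect_equal(round(extended_pressure(299.8 / 1000,
                                       system_coefficient(0.9406), ctx)$value),
               5454)
  expect_equal(extended_pressure(0.25, 1, ctx)$value,
               osmotic_pressure(0.25, ctx)$value)
  expect_error(extended_pressure(0.25, -1, ctx), "positive")
  expect_error(system_coefficient(0), "positive")
})

test_that("electroneutrality verdict warns only on mixed-sign permeant ions", {
  mix <- physiological_mix()
  # permeable to Cl- and Mg++ but impermeable to Na+ and SO4--
  leaky_both <- membrane(sigma_species = c("Cl-" = 0.3, "Mg++" = 0.3,
                                           "Na+" = 1, "SO4--" = 1,
                                           glucose = 1))
  v <- electroneutrality_check(mix, leaky_both)
  expect_identical(v$verdict, "WARN")
  expect_setequal(v$offending, c("Mg++", "Cl-"))

  expect_identical(electroneutrality_check(mix, membrane())$verdict, "PASS")
  # anions-only permeability is acceptable
  anion_only <- membrane(sigma_species = c("Cl-" = 0.3, "SO4--" = 0))
  expect_identical(electroneutrality_check(mix, anion_only)$verdict, "PASS")
  # non-electrolytes never trigger the warning
  glu <- solution(list(solute("glucose")), 0.1)
  expect_identical(
    electroneutrality_check(glu, membrane(default_sigma = 0.2))$verdict, "PASS")
})

test_that("pressure conversion uses exact factors and round-trips", {
  expect_equal(convert_pressure(1, "bar", "mmHg"), 750.062)
  expect_equal(convert_pressure(1, "bar", "atm"), 0.986923)
  expect_equal(convert_pressure(0, "mmHg", "atm"), 0)
  expect_equal(convert_pressure(3.7, "bar", "bar"), 3.7)
  x <- c(0.5, 1, 760)
  expect_equal(convert_pressure(convert_pressure(x, "mmHg", "atm"),
                                "atm", "mmHg"), x)
  expect_error(convert_pressure(1, "psi", "bar"), "unknown pressure unit")
})

test_that("the two OC0 methods agree when phi = 1 and sigmas are aligned", {
  set.seed(303)
  for (rep in 1:50) {
    sol <- random_solution(phi_one = TRUE)
    mem <- aligned_membrane(sol)
    expect_equal(oc0_particle_based(sol, mem), oc0_molecule_based(sol, mem))
  }
})

test_that("OC0 never exceeds ideal C_TSP when sigma, phi <= 1", {
  set.seed(404)
  for (rep in 1:50) {
    sol <- random_solution(phi_one = FALSE)
    mem <- aligned_membrane(sol)
    expect_lte(oc0_molecule_based(sol, mem), ctsp_ideal(sol) + 1e-12)
    expect_lte(oc0_particle_based(sol, mem), ctsp_ideal(sol) + 1e-12)
  }
  # equality iff all sigma = phi = 1
  sol <- random_solution(phi_one = TRUE)
  expect_equal(oc0_molecule_based(sol, membrane()), ctsp_ideal(sol))
})

test_that("pressure is linear in OC0 and monotone in its drivers", {
  ctx <- thermo_context(298.15, "bar")
  set.seed(505)
  oc <- stats::runif(5, 0, 0.5)
  a <- stats::runif(1, 0, 2)
  for (x in oc) {
    expect_equal(osmotic_pressure(a * x, ctx)$value,
                 a * osmotic_pressure(x, ctx)$value)
  }
  # monotone in temperature
  hot <- thermo_context(310.15, "bar")
  expect_gt(osmotic_pressure(0.3, hot)$value, osmotic_pressure(0.3, ctx)$value)
  # monotone in concentration and sigma on a concrete solution
  base <- solution(list(solute("glucose")), 0.1)
  more <- solution(list(solute("glucose")), 0.2)
  expect_gt(oc0_molecule_based(more, membrane()),
            oc0_molecule_based(base, membrane()))
  expect_gt(oc0_molecule_based(base, membrane(default_sigma = 0.9)),
            oc0_molecule_based(base, membrane(default_sigma = 0.4)))
})
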
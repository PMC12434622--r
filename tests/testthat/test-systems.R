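# Composite-system deconstruction, pressure gradients, and the
# osmosis/diffusion split of complex systems.

test_that("deconstruction yields mirrored simple systems sharing membrane and context", {
  ctx <- thermo_context(298.15, "bar")
  mem <- membrane(default_sigma = 1)
  s1 <- solution(list(solute("glucose")), 0.3)
  s2 <- solution(list(solute("glucose")), 0.1)
  comp <- composite_system(s1, s2, mem, ctx)

  pair <- deconstruct_composite(comp)
  expect_s3_class(pair$s1, "osmo_simple_system")
  expect_identical(pair$s1$membrane, mem)
  expect_identical(pair$s2$context, ctx)
  expect_identical(pair$s1$solution, s1)
  expect_identical(pair$s2$solution, s2)

  # swapping compartments swaps the pair
  swapped <- deconstruct_composite(composite_system(s2, s1, mem, ctx))
  expect_identical(swapped$s1$solution, s2)
  expect_identical(swapped$s2$solution, s1)

  # water in compartment 2 reduces the composite to a simple system
  degenerate <- composite_system(s1, solution(), mem, ctx)
  pair0 <- deconstruct_composite(degenerate)
  expect_equal(oc0_molecule_based(pair0$s2$solution, mem), 0)
  g <- composite_gradient(degenerate)
  expect_equal(g$delta_pi, osmotic_pressure(ctsp_ideal(s1), ctx)$value)
})

test_that("composite gradient is RT * delta OC0 with a signed direction", {
  ctx <- thermo_context(295.15, "bar", gas_constant = 24.54 / 295.15)
  mem <- membrane()
  comp <- composite_system(solution(list(solute("a")), 0.3),
                           solution(list(solute("b")), 0.1), mem, ctx)
  g <- composite_gradient(comp)
  expect_equal(g$delta_pi, 24.54 * (0.3 - 0.1))
  expect_identical(g$direction, "solution_1")

  same <- composite_system(solution(list(solute("a")), 0.2),
                           solution(list(solute("b")), 0.2), mem, ctx)
  g0 <- composite_gradient(same)
  expect_equal(g0$delta_pi, 0)
  expect_identical(g0$direction, "none")
})

test_that("gradient is antisymmetric and consistent with the mirrored sum", {
  set.seed(606)
  for (rep in 1:30) {
    sol1 <- random_solution(phi_one = FALSE, prefix = "left")
    sol2 <- random_solution(phi_one = FALSE, prefix = "right")
    mem <- aligned_membrane(solution(c(sol1$solutes, sol2$solutes),
                                     c(sol1$conc, sol2$conc)))
    ctx <- thermo_context(stats::runif(1, 270, 330), "bar")
    fwd <- composite_gradient(composite_system(sol1, sol2, mem, ctx))
    rev <- composite_gradient(composite_system(sol2, sol1, mem, ctx))
    expect_equal(fwd$delta_pi, -rev$delta_pi)

    # deconstruction consistency: delta_pi equals the signed sum of the two
    # independently computed simple-system pressures
    pair <- deconstruct_composite(composite_system(sol1, sol2, mem, ctx))
    pi1 <- osmotic_pressure(oc0_molecule_based(pair$s1$solution, mem), ctx)$value
    pi2 <- osmotic_pressure(oc0_molecule_based(pair$s2$solution, mem), ctx)$value
    expect_equal(fwd$delta_pi, pi1 - pi2)
  }
})

test_that("random solutions generated for composites violate no name rules", {
  # compartments may legitimately reuse molecule names across the membrane
  sol <- solution(list(solute("glucose")), 0.1)
  expect_no_error(composite_system(sol, sol))
})

test_that("extended gradient applies one theta to the ideal C_TSP difference", {
  ctx <- thermo_context(310.15, "mmHg", gas_constant = 19.3421 * 1000 / 310.15)
  s1 <- solution(list(solute("plasma_eq")), 299.8 / 1000)
  s2 <- solution(list(solute("interstitial_eq")), 281.0 / 1000)
  comp <- composite_system(s1, s2, membrane(), ctx)

  g <- extended_gradient(comp, 0.94)
  expect_equal(g$delta_pi, 0.94 * (299.8 - 281.0) / 1000 * 19.3421 * 1000)
  expect_equal(round(g$delta_pi, 1), 341.8)

  ideal <- extended_gradient(comp, 1)
  expect_equal(ideal$delta_pi, composite_gradient(comp)$delta_pi)

  same <- composite_system(s1, s1, membrane(), ctx)
  expect_equal(extended_gradient(same, 0.94)$delta_pi, 0)
  expect_error(extended_gradient(comp, 0), "positive")
})

test_that("split_complex partitions molecules at the sigma cutoff", {
  sol <- solution(list(solute("inulin"), solute("urea")), c(0.01, 0.02))
  mem <- membrane(sigma_molecule = c(inulin = 1, urea = 0.05))
  sp <- split_complex(sol, mem, sigma_cutoff = 0.95)

  os_names <- vapply(sp$osmosis_subsystem$solution$solutes, `[[`,
                     character(1), "name")
  expect_identical(os_names, "inulin")
  expect_identical(sp$diffusion_subsystem$molecule, "urea")
  expect_equal(sp$diffusion_subsystem$sigma, 0.05)

  # ideal membrane: nothing diffuses
  all_in <- split_complex(sol, membrane(), sigma_cutoff = 0.95)
  expect_identical(nrow(all_in$diffusion_subsystem), 0L)
  # fully permeable: osmosis subsystem empty with zero OC0
  none <- split_complex(sol, membrane(default_sigma = 0))
  expect_length(none$osmosis_subsystem$solution$solutes, 0)
  expect_equal(oc0_molecule_based(none$osmosis_subsystem$solution, mem), 0)

  expect_error(split_complex(sol, mem, sigma_cutoff = 0), "\\(0, 1\\]")
  expect_error(split_complex(sol, mem, sigma_cutoff = 1.2), "\\(0, 1\\]")
})

test_that("split partition is exhaustive and matches a masked-sigma oracle", {
  set.seed(707)
  for (rep in 1:30) {
    sol <- random_solution(phi_one = FALSE)
    nm <- vapply(sol$solutes, `[[`, character(1), "name")
    sig <- stats::runif(length(nm))
    mem <- membrane(default_sigma = 1,
                    sigma_molecule = stats::setNames(sig, nm))
    cutoff <- stats::runif(1, 0.2, 1)
    sp <- split_complex(sol, mem, sigma_cutoff = cutoff)

    os_nm <- vapply(sp$osmosis_subsystem$solution$solutes, `[[`,
                    character(1), "name")
    expect_setequal(c(os_nm, sp$diffusion_subsystem$molecule), nm)
    expect_length(intersect(os_nm, sp$diffusion_subsystem$molecule), 0)

    # oracle: OC0 of the osmosis subsystem under sigma = 1 equals OC0 of the
    # full solution with sigma masked to 1 (retained) / 0 (removed)
    mask <- stats::setNames(as.numeric(sig >= cutoff), nm)
    masked_mem <- membrane(default_sigma = 1, sigma_molecule = mask)
    expect_equal(
      oc0_molecule_based(sp$osmosis_subsystem$solution, membrane()),
      oc0_molecule_based(sol, masked_mem))
  }
})
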
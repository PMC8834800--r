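test_that("retirement flow is stock over replacement period", {
  st <- turnover_settings(240)
  out <- retirement_flow(ref_comp(), st)
  expect_equal(sum(out), 208 / 240, tolerance = 1e-12)
  expect_equal(unname(out["Zelkova serrata"]), 112 / 240)
  expect_equal(unname(retirement_flow(c(Z = 240), st)), 1.0)
  expect_identical(sum(retirement_flow(validate_composition(numeric(0)), st)), 0)
})

test_that("allocation reproduces the priority split by hand", {
  comp <- ref_comp()
  pol <- planting_policy("single_priority",
                         priority_species = "Pinus densiflora",
                         target_ratio = 0.7)
  a <- allocate_plantings(10, comp, pol)
  expect_equal(unname(a["Pinus densiflora"]), 7)
  expect_equal(unname(a["Zelkova serrata"]), 10 * 0.3 * 112 / 208)
  expect_equal(unname(a["Prunus yedoensis"]), 10 * 0.3 * 70 / 208)
  expect_equal(unname(a["other"]), 10 * 0.3 * 26 / 208)
  expect_equal(sum(a), 10, tolerance = 1e-12)
})

test_that("allocation handles the three modes and their edge cases", {
  comp <- validate_composition(c(Z = 6, P = 3, O = 3))
  # status quo reproduces the composition shape
  a <- allocate_plantings(12, comp, planting_policy("status_quo"))
  expect_equal(unname(a[c("Z", "P", "O")]), c(6, 3, 3))
  # degenerate ratio 1 gives everything to the priority species
  a <- allocate_plantings(10, comp,
                          planting_policy("single_priority",
                                          priority_species = "P",
                                          target_ratio = 1))
  expect_equal(unname(a["P"]), 10)
  expect_equal(sum(a), 10)
  # zero replacements allocate nothing
  expect_equal(sum(allocate_plantings(0, comp, planting_policy("status_quo"))), 0)
  # fixed mix follows the mix fractions
  mix <- c(Z = 0.5, P = 0.25, O = 0.25)
  a <- allocate_plantings(8, comp, planting_policy("fixed_mix", mix = mix))
  expect_equal(unname(a[c("Z", "P", "O")]), c(4, 2, 2))
  # empty composition has no proportions to follow
  empty <- validate_composition(numeric(0))
  expect_error(allocate_plantings(1, empty, planting_policy("status_quo")),
               "empty")
  expect_error(allocate_plantings(1, comp,
                                  planting_policy("single_priority",
                                                  priority_species = "missing",
                                                  target_ratio = 0.5)),
               "missing")
})

test_that("policy constructor enforces its invariants", {
  expect_error(planting_policy("single_priority", priority_species = "Z",
                               target_ratio = 1.2), "\\[0, 1\\]")
  expect_error(planting_policy("single_priority", target_ratio = 0.5),
               "priority_species")
  expect_error(planting_policy("fixed_mix", mix = c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(planting_policy("fixed_mix", mix = c(a = -0.5, b = 1.5)),
               ">= 0")
})

test_that("one Euler step conserves totals and matches hand arithmetic", {
  st <- turnover_settings(240)
  comp <- ref_comp()
  # status quo is a fixed point
  after <- step_composition(comp, planting_policy("status_quo"), st)
  expect_equal(unclass(after), unclass(comp), tolerance = 1e-12)
  # Pinus-priority step: Pinus gains r * N/T = 0.7 * 208/240
  pol <- planting_policy("single_priority",
                         priority_species = "Pinus densiflora",
                         target_ratio = 0.7)
  after <- step_composition(comp, pol, st)
  expect_equal(unname(after["Pinus densiflora"]), 0.7 * 208 / 240,
               tolerance = 1e-12)
  expect_equal(total_trees(after), 208, tolerance = 1e-9)
})

test_that("total tree count is conserved for every policy mode", {
  st <- turnover_settings(180, dt_months = 1)
  comp <- validate_composition(c(a = 10, b = 55.5, c = 0, d = 142.5))
  policies <- list(
    planting_policy("status_quo"),
    planting_policy("single_priority", priority_species = "c", target_ratio = 0.9),
    planting_policy("fixed_mix", mix = c(a = 0.7, b = 0.1, c = 0.1, d = 0.1))
  )
  for (pol in policies) {
    path <- run_dynamics(comp, pol, st, horizon_months = 120)
    totals <- rowSums(path)
    expect_true(all(abs(totals - 208) <= 1e-9 * 208))
    expect_true(all(path >= 0))
  }
})

test_that("Euler single-priority trajectories match the closed-form oracle", {
  st <- turnover_settings(240)
  comp <- ref_comp()
  pol <- planting_policy("single_priority",
                         priority_species = "Pinus densiflora",
                         target_ratio = 0.7)
  path <- run_dynamics(comp, pol, st, horizon_months = 360)
  t <- 0:360
  oracle <- closed_form_priority_share(t, B0 = 0, r = 0.7, N = 208,
                                       T_months = 240)
  expect_lt(max(abs(path[, "Pinus densiflora"] - oracle)), 0.01 * 208)
  # closed form endpoints
  expect_identical(closed_form_priority_share(0, 5, 0.7, 208, 240), 5)
  expect_equal(closed_form_priority_share(1e9, 0, 0.7, 208, 240), 145.6,
               tolerance = 1e-6)
  expect_equal(closed_form_priority_share(240, 0, 0.7, 208, 240),
               92.0367533654, tolerance = 1e-9)
})

test_that("non-priority species keep constant pairwise ratios and the priority share converges monotonically", {
  st <- turnover_settings(240)
  pol <- planting_policy("single_priority", priority_species = "Pinus densiflora",
                         target_ratio = 0.7)
  path <- run_dynamics(ref_comp(), pol, st, horizon_months = 360)
  ratio_zp <- path[, "Zelkova serrata"] / path[, "Prunus yedoensis"]
  expect_true(all(abs(ratio_zp / ratio_zp[1] - 1) <= 1e-6))
  share <- path[, "Pinus densiflora"] / rowSums(path)
  expect_true(all(diff(share) > 0))        # monotone toward the target
  expect_true(all(share <= 0.7 + 1e-12))   # never overshoots
})

test_that("fixed-mix runs converge toward the mix distribution", {
  st <- turnover_settings(240)
  mix <- c("Zelkova serrata" = 0.3, "Prunus yedoensis" = 0.3,
           "Pinus densiflora" = 0.3, "other" = 0.1)
  path <- run_dynamics(ref_comp(), planting_policy("fixed_mix", mix = mix),
                       st, horizon_months = 360)
  target <- 208 * mix[colnames(path)]
  dev <- apply(abs(sweep(path, 2, target)), 1, max)
  expect_true(all(diff(dev) < 1e-12))  # max deviation decreases monotonically
})

test_that("cohort turnover conserves totals and converts faster than first-order", {
  pol <- planting_policy("single_priority", priority_species = "Pinus densiflora",
                         target_ratio = 0.7)
  cohort <- run_dynamics(ref_comp(), pol,
                         turnover_settings(240, scheme = "cohort"), 360)
  first <- run_dynamics(ref_comp(), pol, turnover_settings(240), 360)
  expect_true(all(abs(rowSums(cohort) - 208) <= 1e-9 * 208))
  # the uniformly aged cohort retires the original stock linearly, so the
  # priority species accumulates faster than under exponential turnover
  expect_gt(cohort["240", "Pinus densiflora"],
            first["240", "Pinus densiflora"])
})

test_that("turnover settings validate their fields", {
  expect_error(turnover_settings(0), "positive")
  expect_error(turnover_settings(240, dt_months = 0), "dt_months")
  expect_error(turnover_settings(240, dt_months = 241), "dt_months")
})
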
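test_that("flat monthly absorption reproduces the published initial values", {
  p <- reference_species()
  comp <- function(z, pr, pi, o) {
    validate_composition(setNames(c(z, pr, pi, o), p$species_id))
  }
  expect_equal(monthly_pm_absorption(comp(112, 70, 0, 26), p), 963.2)
  expect_equal(round(monthly_pm_absorption(comp(292, 70, 0, 26), p)), 1962)
  expect_equal(round(monthly_pm_absorption(comp(112, 250, 0, 26), p)), 1643)
  expect_equal(round(monthly_pm_absorption(comp(112, 70, 180, 26), p)), 1326)
  expect_equal(round(monthly_pm_absorption(comp(172, 130, 60, 26), p)), 1644)
  expect_identical(monthly_pm_absorption(validate_composition(numeric(0)), p), 0)
  expect_error(monthly_pm_absorption(validate_composition(c(unknown = 3)), p),
               "unknown")
})

test_that("seasonal mode with flat weights equals flat mode, and is additive", {
  p <- toy_params()
  comp <- validate_composition(c(s1 = 10, s2 = 5, s3 = 2))
  for (m in 1:12) {
    expect_equal(monthly_pm_absorption(comp, p, m, mode = "seasonal"),
                 monthly_pm_absorption(comp, p, mode = "flat"))
  }
  a <- validate_composition(c(s1 = 3, s2 = 0, s3 = 1))
  b <- validate_composition(c(s1 = 7, s2 = 5, s3 = 1))
  expect_equal(monthly_pm_absorption(a, p) + monthly_pm_absorption(b, p),
               monthly_pm_absorption(validate_composition(unclass(a) + unclass(b)), p),
               tolerance = 1e-9)
})

test_that("seasonal weights are a distribution with the specified shape", {
  # uniform mass over an 8-month leaf-on window, nothing outside
  w <- seasonal_weights("deciduous",
                        seasonal_profile(4, 11, ramp_months = 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w[1]), 0)
  expect_equal(unname(w[4:11]), rep(1 / 8, 8))
  # flat evergreen limit
  w <- seasonal_weights("evergreen",
                        seasonal_profile(evergreen_winter_fraction = 1))
  expect_equal(unname(w), rep(1 / 12, 12))
  # winter dominance: evergreen Dec-Feb mass strictly exceeds deciduous's
  prof <- seasonal_profile()
  wd <- seasonal_weights("deciduous", prof)
  we <- seasonal_weights("evergreen", prof)
  expect_gt(sum(we[c(12, 1, 2)]), sum(wd[c(12, 1, 2)]))
  expect_true(all(wd >= 0) && all(we >= 0))
  # wrapped leaf-on window (southern-hemisphere style) still normalizes
  ww <- seasonal_weights("deciduous", seasonal_profile(10, 3, ramp_months = 1))
  expect_equal(sum(ww), 1, tolerance = 1e-12)
  expect_equal(unname(ww[7]), 0)
})

test_that("seasonal monthly absorptions sum back to the annual rate", {
  p <- apply_seasonal_profile(reference_species())
  w <- monthly_weights(p)
  for (i in seq_len(nrow(p))) {
    expect_equal(sum(p$annual_pm_g[i] * w[i, ]), p$annual_pm_g[i],
                 tolerance = 1e-9)
  }
})

test_that("seasonal profile rejects invalid windows", {
  expect_error(seasonal_profile(leaf_on_start_month = 0), "1\\.\\.12")
  expect_error(seasonal_profile(leaf_on_end_month = 13), "1\\.\\.12")
  expect_error(seasonal_profile(ramp_months = -1), "ramp")
  expect_error(seasonal_profile(evergreen_winter_fraction = 0), "\\(0, 1\\]")
})

test_that("Shannon index matches hand values and the vegan cross-check", {
  expect_equal(shannon_index(c(only = 42)), 0)
  expect_equal(shannon_index(c(a = 5, b = 5, c = 5, d = 5)), log(4))
  expect_equal(shannon_index(zpo_comp()), 0.9597637984, tolerance = 1e-9)
  skip_if_not_installed("vegan")
  expect_equal(shannon_index(zpo_comp()),
               unname(vegan::diversity(c(112, 70, 26), index = "shannon")),
               tolerance = 1e-12)
})

test_that("Shannon index respects its bounds and invariances", {
  expect_error(shannon_index(validate_composition(numeric(0))), "empty")
  expect_error(shannon_index(c(a = 0, b = 0)), "empty")
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    counts <- setNames(stats::rgamma(k, 1), paste0("s", 1:k))
    counts[sample(k, 1)] <- 0  # zero-count species contribute nothing
    counts[1] <- counts[1] + 1e-3
    h <- shannon_index(counts)
    expect_gte(h, 0)
    expect_lte(h, log(sum(counts > 0)) + 1e-12)
    # scale invariance
    expect_equal(shannon_index(counts * 7.5), h, tolerance = 1e-12)
  }
  # moving mass from a dominant to a rarer species never decreases H
  counts <- c(a = 100, b = 20, c = 10)
  h0 <- shannon_index(counts)
  h1 <- shannon_index(counts + c(a = -5, b = 0, c = 5))
  expect_gte(h1, h0)
  # configurable log base
  expect_equal(shannon_index(c(a = 1, b = 1), base = 2), 1)
})

test_that("winter mean absorption isolates December-February", {
  traj <- data.frame(month_index = 0:12,
                     calendar_month = c(1:12, 1),
                     mpa_g = c(999, rep(10, 10), 40, 70))
  # winter rows among simulated months: Feb (idx 1), Dec (idx 11), Jan (idx 12);
  # the month-0 snapshot (Jan, 999) is excluded
  expect_equal(winter_mean_absorption(traj), mean(c(10, 40, 70)))
  no_winter <- data.frame(month_index = 1:3, calendar_month = 4:6,
                          mpa_g = rep(1, 3))
  expect_error(winter_mean_absorption(no_winter), "winter")
})

test_that("swapping a deciduous tree for an evergreen one raises winter absorption", {
  prof <- seasonal_profile()
  p <- species_params(c("dec", "eve"), c(50, 50), c("deciduous", "evergreen"))
  p <- apply_seasonal_profile(p, prof)
  winter_abs <- function(comp) {
    mean(vapply(winter_months(), function(m) {
      monthly_pm_absorption(comp, p, m, mode = "seasonal")
    }, numeric(1)))
  }
  before <- winter_abs(validate_composition(c(dec = 50, eve = 10)))
  after <- winter_abs(validate_composition(c(dec = 49, eve = 11)))
  expect_gt(after, before)
})
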
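make_grid_surface <- function(f, ages = 0:50, years = 1990:2009) {
  mx <- outer(ages, years, f)
  mortality_surface(mx, ages, years)
}

test_that("bilinear log surfaces pass through the smoother untouched", {
  surf <- make_grid_surface(function(a, y)
    exp(-6 + 0.05 * a - 0.01 * (y - 1990) + 1e-4 * a * (y - 1990)))
  sm <- smooth_mortality(surf, lambda_age = 1e6, lambda_year = 1e6)
  expect_equal(sm$mx, surf$mx, tolerance = 1e-6)
})

test_that("a constant surface is returned exactly", {
  surf <- make_grid_surface(function(a, y) 0.02 + 0 * a)
  sm <- smooth_mortality(surf)
  expect_equal(sm$mx, surf$mx, tolerance = 1e-12)
})

test_that("smoothing denoises a seeded noisy surface", {
  truth <- outer(0:60, 1991:2010,
                 function(a, y) -8 + 0.08 * a - 0.015 * (y - 1991))
  set.seed(3)
  noisy <- truth + matrix(rnorm(length(truth), 0, 0.05), nrow(truth))
  surf <- mortality_surface(exp(noisy), 0:60, 1991:2010)
  sm <- smooth_mortality(surf)
  rmse_in <- sqrt(mean((noisy - truth)^2))
  rmse_out <- sqrt(mean((log(sm$mx) - truth)^2))
  expect_lt(rmse_out, rmse_in)
})

test_that("grids too small for second differences are rejected", {
  surf <- mortality_surface(matrix(0.02, 5, 2), 0:4, 2000:2001)
  expect_error(smooth_mortality(surf), "at least 3")
})

test_that("a time-constant surface has zero improvement everywhere", {
  surf <- make_grid_surface(function(a, y) exp(-7 + 0.06 * a))
  im <- improvement_rates(surf)
  expect_true(all(im$rho == 0))
  expect_true(all(im$category == "little_change"))
})

test_that("exact log-linear decline gives rho = 1.0 % everywhere", {
  surf <- make_grid_surface(function(a, y)
    exp(-7 + 0.06 * a) * exp(-0.01 * (y - 1990)))
  im <- improvement_rates(surf)
  expect_equal(unname(im$rho[1, 1]), 1, tolerance = 1e-9)
  expect_true(all(abs(im$rho - 1) < 1e-9))
  expect_true(all(im$category == "improvement"))
})

test_that("rho is invariant to doubling every rate", {
  surf <- two_country_crisis()[["FSU-B"]]
  surf2 <- mortality_surface(surf$mx * 2, surf$ages, surf$years)
  expect_equal(improvement_rates(surf)$rho, improvement_rates(surf2)$rho,
               tolerance = 1e-12)
})

test_that("the crisis years show worsening concentrated at working ages", {
  surf <- two_country_crisis()[["FSU-B"]]
  im <- improvement_rates(smooth_mortality(surf))
  crisis_cols <- im$years %in% 1988:1991
  working <- im$ages >= 25 & im$ages <= 55
  old <- im$ages >= 75
  expect_lt(mean(im$rho[working, crisis_cols]), -0.5)
  expect_gt(mean(im$rho[working, crisis_cols] < -0.5), 0.8)
  expect_gt(mean(im$rho[old, crisis_cols]),
            mean(im$rho[working, crisis_cols]))
})

test_that("a constant series yields no change points", {
  seg <- detect_changepoints(rep(1, 30), years = 1981:2010, seed = 4)
  expect_length(seg$breaks, 0)
})

test_that("two clear level shifts are recovered at the right years", {
  set.seed(9)
  y <- c(rep(0, 10), rep(5, 10), rep(10, 10)) + rnorm(30)
  seg <- detect_changepoints(y, years = 1971:2000, seed = 5)
  expect_true(any(abs(seg$breaks - 1981) <= 1))
  expect_true(any(abs(seg$breaks - 1991) <= 1))
  expect_true(all(seg$p_values <= 0.05))
})

test_that("segmentation is deterministic given the seed and affine-invariant", {
  set.seed(10)
  y <- c(rep(0, 12), rep(4, 12)) + rnorm(24)
  a <- detect_changepoints(y, years = 1:24, seed = 6)
  b <- detect_changepoints(y, years = 1:24, seed = 6)
  expect_identical(a$breaks, b$breaks)
  expect_identical(a$p_values, b$p_values)
  z <- detect_changepoints(-3 * y + 100, years = 1:24, seed = 6)
  expect_identical(a$breaks, z$breaks)
})

test_that("series shorter than twice the minimum segment are rejected", {
  expect_error(detect_changepoints(rnorm(9), min_segment = 5, seed = 1),
               "2 \\* min_segment")
})

test_that("statistical breaks snap to the canonical boundaries", {
  out <- assign_periods(c(1976, 1986, 1993, 2001), span = c(1960, 2014))
  expect_identical(out$breaks, c(1980L, 1988L, 1994L, 2000L))
  expect_identical(out$labels,
                   c("stagnation", "improvements", "deterioration",
                     "divergence", "convergence"))
  # already-canonical breaks are unchanged
  out2 <- assign_periods(c(1980, 1988, 1994, 2000))
  expect_identical(out2$breaks, c(1980L, 1988L, 1994L, 2000L))
  expect_true(all(out2$canonical))
})

test_that("breaks far from every boundary are kept and flagged", {
  out <- assign_periods(c(1973, 1988), span = c(1960, 2014))
  expect_identical(out$breaks, c(1973L, 1988L))
  expect_identical(out$canonical, c(FALSE, TRUE))
  expect_match(out$labels[2], "non-canonical")
})
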
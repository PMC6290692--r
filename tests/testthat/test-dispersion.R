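test_that("e-dagger equals e0 under a constant hazard (fine grid)", {
  ages <- seq(0, 400, by = 0.1)
  lt <- lifetable(rep(0.02, length(ages)), ages, a0_rule = "midpoint")
  expect_lt(abs(e_dagger(lt) - 50), 0.5)
  expect_lt(abs(lt$ex[1] - 50), 0.5)
})

test_that("a single death atom contributes its own expectancy", {
  # all deaths in the interval [50, 51): e-dagger is that one contribution
  # everyone dies at age 50.5, so e(50) = 0.5 and the single atom
  # contributes (1 - ax/n) e(50) = 0.25
  mx <- rep(0, 111); mx[51] <- 1e9; mx[111] <- 0.5
  lt <- lifetable(mx, 0:110)
  expect_equal(e_dagger(lt), 0.25, tolerance = 1e-12)
})

test_that("e-dagger matches the Gompertz quadrature oracle", {
  mu <- function(x) 1e-4 * exp(0.1 * x)
  lt <- lifetable(mu(0:110 + 0.5), 0:110)
  oracle <- quadrature_oracle(mu)
  expect_lt(abs(e_dagger(lt) - oracle$edag), 0.1)
})

test_that("e-dagger is invariant to the radix", {
  mx <- random_schedule(7)
  expect_equal(e_dagger(lifetable(mx, 0:110, radix = 1e5)),
               e_dagger(lifetable(mx, 0:110)), tolerance = 1e-12)
})

test_that("threshold age separates compressing from expanding reductions", {
  mx <- siler_hazard(0:110, cee_male_params())
  lt <- lifetable(mx, 0:110)
  th <- threshold_age(lt)
  expect_gt(th$threshold, 55)
  expect_lt(th$threshold, 75)
  # a 1 % cut everywhere strictly below the threshold compresses
  below <- mx * ifelse(0:110 < floor(th$threshold), 0.99, 1)
  expect_lt(e_dagger(lifetable(below, 0:110)), e_dagger(lt))
  # and strictly above expands
  above <- mx * ifelse(0:110 > ceiling(th$threshold), 0.99, 1)
  expect_gt(e_dagger(lifetable(above, 0:110)), e_dagger(lt))
  # at the threshold itself the effect vanishes
  s <- e_dagger(lifetable(
    lifedisparity:::perturb_band(mx, 0:110, th$threshold, 1, 0.01),
    0:110)) - e_dagger(lt)
  expect_lt(abs(s), 1e-6)
})

test_that("threshold age errors on schedules without a sign change", {
  expect_error(threshold_age(lifetable(c(rep(0, 110), 0.02), 0:110)),
               "no threshold")
})

test_that("Keyfitz entropy hits its closed-form limits", {
  ages <- seq(0, 400, by = 0.1)
  lt_exp <- lifetable(rep(0.02, length(ages)), ages, a0_rule = "midpoint")
  expect_lt(abs(keyfitz_entropy(lt_exp) - 1), 0.02)
  # rectangular survival: everyone dies in [80, 81)
  mx <- rep(0, 111); mx[81] <- 1e9; mx[111] <- 1
  lt_rect <- lifetable(mx, 0:110)
  expect_lt(keyfitz_entropy(lt_rect), 0.02)
})

test_that("entropy equals e-dagger / e0 on randomized schedules", {
  for (seed in 1:10) {
    lt <- lifetable(random_schedule(seed), 0:110)
    expect_lt(abs(keyfitz_entropy(lt) - e_dagger(lt) / lt$ex[1]), 0.01)
  }
})

test_that("life-table Gini hits its closed-form limits", {
  ages <- seq(0, 400, by = 0.1)
  lt_exp <- lifetable(rep(0.02, length(ages)), ages, a0_rule = "midpoint")
  expect_lt(abs(gini_lifetable(lt_exp) - 0.5), 0.02)
  mx <- rep(0, 111); mx[81] <- 1e9; mx[111] <- 1
  expect_lt(gini_lifetable(lifetable(mx, 0:110)), 0.01)
})

test_that("Gini matches the pairwise age-difference oracle", {
  for (seed in 1:10) {
    lt <- lifetable(random_schedule(seed), 0:110)
    expect_lt(abs(gini_lifetable(lt) - gini_pairwise_oracle(lt)), 0.01)
  }
})

test_that("Gini and entropy rank a mean-preserving spread identically", {
  tight <- siler_hazard(0:110, cee_male_params())
  p <- cee_male_params(); p$h <- p$h * 6; p$sigma <- p$sigma * 1.4
  spread <- siler_hazard(0:110, p)
  lt_t <- lifetable(tight, 0:110); lt_s <- lifetable(spread, 0:110)
  expect_gt(gini_lifetable(lt_s), gini_lifetable(lt_t))
  expect_gt(keyfitz_entropy(lt_s), keyfitz_entropy(lt_t))
})

test_that("coefficient of variation uses the population convention", {
  expect_identical(cv_across_populations(c(4, 4, 4)), 0)
  expect_equal(cv_across_populations(c(10, 20)), 5 / 15, tolerance = 1e-12)
  expect_error(cv_across_populations(5), "at least 2")
  expect_error(cv_across_populations(c(-3, 1)), "mean must be positive")
})

test_that("monotone decline in both measures fills the (-,-) quadrant", {
  yrs <- 2000:2010
  e0 <- matrix(seq(70, 60, length.out = 11), 11, 3,
               dimnames = list(yrs, NULL))
  ed <- matrix(seq(16, 12, length.out = 11), 11, 3,
               dimnames = list(yrs, NULL))
  q <- quadrant_analysis(e0, ed)
  both_dec <- q[q$quadrant == "-/-", ]
  expect_equal(both_dec$prop, 1)
  expect_equal(both_dec$ci_high, 1)
  expect_equal(sum(q$count), q$n_pairs[1])
})

test_that("independent random signs put ~25 % in each quadrant", {
  set.seed(11)
  n <- 401
  e0 <- matrix(cumsum(sample(c(-1, 1), n, TRUE)) + 1000, n, 1,
               dimnames = list(1:n, NULL))
  ed <- matrix(cumsum(sample(c(-1, 1), n, TRUE)) + 1000, n, 1,
               dimnames = list(1:n, NULL))
  q <- quadrant_analysis(e0, ed)
  expect_true(all(q$ci_low < 0.25 & 0.25 < q$ci_high))
  expect_equal(sum(q$prop), 1, tolerance = 1e-12)
})

test_that("zero differences are excluded but can be kept", {
  e0 <- matrix(c(70, 70, 69), 3, 1, dimnames = list(2000:2002, NULL))
  ed <- matrix(c(15, 14, 13), 3, 1, dimnames = list(2000:2002, NULL))
  q <- quadrant_analysis(e0, ed)
  expect_equal(q$n_pairs[1], 1)
  expect_identical(attr(q, "n_zero"), 1L)
  q2 <- quadrant_analysis(e0, ed, drop_zero = FALSE)
  expect_equal(q2$n_pairs[1], 2)
})

test_that("periods partition the pairs and relative scaling divides", {
  yrs <- 1990:1999
  e0 <- matrix(70 + cumsum(rep(c(1, -1), 5)), 10, 1,
               dimnames = list(yrs, NULL))
  ed <- matrix(15 + cumsum(rep(c(-0.5, 0.5), 5)), 10, 1,
               dimnames = list(yrs, NULL))
  q <- quadrant_analysis(e0, ed, breaks = 1995, scale = "relative")
  expect_setequal(unique(q$period), c("1990-1995", "1995-1999"))
  expect_equal(sum(q$n_pairs[!duplicated(q$period)]), 9)
})
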
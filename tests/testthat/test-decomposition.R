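test_that("zero path gives zero contributions and zero residual", {
  f <- function(x) sum(x^2)
  x <- c(a = 1, b = 2, c = 3)
  d <- horiuchi_decompose(f, x, x)
  expect_identical(unname(d$contributions), c(0, 0, 0))
  expect_identical(d$residual, 0)
})

test_that("linear functionals decompose exactly at any step count", {
  slopes <- c(2, -3, 0.5)
  f <- function(x) sum(slopes * x) + 7
  x1 <- c(1, 1, 1); x2 <- c(4, 0, -2)
  for (ns in c(1, 3, 20)) {
    d <- horiuchi_decompose(f, x1, x2, n_steps = ns)
    expect_equal(unname(d$contributions), slopes * (x2 - x1),
                 tolerance = 1e-12)
    expect_lt(d$residual, 1e-12)
  }
})

test_that("3-age toy e0 decomposition matches a dense-path reference", {
  ages <- c(0, 1, 5)
  f <- function(mx) lifetable(mx, ages)$ex[1]
  x1 <- c(0.050, 0.010, 0.080)
  x2 <- c(0.044, 0.012, 0.070)
  ref <- horiuchi_decompose(f, x1, x2, n_steps = 10000)
  d <- horiuchi_decompose(f, x1, x2, n_steps = 20)
  expect_equal(unname(d$contributions), unname(ref$contributions),
               tolerance = 1e-6)
})

test_that("additivity holds and the residual shrinks with step count", {
  surf <- two_country_crisis()[["FSU-B"]]
  res <- vapply(c(5, 20, 80), function(ns)
    decompose_by_age(surf, 1988, 1994, "edagger", n_steps = ns)$residual,
    numeric(1))
  d <- decompose_by_age(surf, 1988, 1994, "edagger", n_steps = 20)
  expect_lt(d$residual, 1e-6 * max(1, abs(d$total)))
  expect_true(all(diff(res) < 0))
  # roughly quadratic decay: 16x fewer per 4x steps, allow slack
  expect_lt(res[3], res[1] / 50)
})

test_that("reversing the endpoints negates every contribution", {
  surf <- two_country_crisis()[["FSU-B"]]
  fwd <- decompose_by_age(surf, 1990, 1996, "edagger", n_steps = 20)
  rev_ <- decompose_by_age(surf, 1996, 1990, "edagger", n_steps = 20)
  expect_equal(fwd$contributions, -rev_$contributions, tolerance = 1e-7)
})

test_that("a change confined to one age stays at that age", {
  mx <- siler_hazard(0:110, cee_male_params())
  surf <- mortality_surface(cbind(mx, replace(mx, 41, mx[41] * 1.3)),
                            0:110, 2000:2001)
  d <- decompose_by_age(surf, 2000, 2001, "edagger")
  expect_gt(abs(d$contributions[41]), 1e-4)
  expect_true(all(abs(d$contributions[-41]) < 1e-8))
})

test_that("uniform reductions split by the threshold age", {
  mx <- siler_hazard(0:110, cee_male_params())
  surf <- mortality_surface(cbind(mx, mx * 0.99), 0:110, 2000:2001)
  d <- decompose_by_age(surf, 2000, 2001, "edagger")
  th <- threshold_age(lifetable(mx, 0:110))$threshold
  ages <- 0:110
  expect_true(all(d$contributions[ages < floor(th) & mx > 0] < 0))
  expect_true(all(d$contributions[ages > ceiling(th) & ages < 108] > 0))
})

test_that("stagnation-style adult worsening expands young, compresses old", {
  # mortality increases at every age above 20: expansion at young-adult
  # ages alongside compression at old ages, on either side of a-dagger
  mx <- siler_hazard(0:110, cee_male_params())
  worse <- mx * ifelse(0:110 >= 20, 1.3, 1)
  surf <- mortality_surface(cbind(mx, worse), 0:110, c(1965, 1979))
  d <- decompose_by_age(surf, 1965, 1979, "edagger")
  expect_gt(sum(d$contributions[21:61]), 0)   # ages 20-60 expand
  expect_lt(sum(d$contributions[71:101]), 0)  # ages 70-100 compress
})

test_that("a working-age-only crisis raises e-dagger via young adults", {
  mx <- siler_hazard(0:110, cee_male_params())
  crisis <- mx * ifelse(0:110 >= 20 & 0:110 <= 60, 1.5, 1)
  surf <- mortality_surface(cbind(mx, crisis), 0:110, c(1990, 1994))
  d <- decompose_by_age(surf, 1990, 1994, "edagger")
  expect_gt(sum(d$contributions[21:61]), 0)
  expect_gt(d$total, 0)
})

test_that("ICD-10 codes route to the printed categories", {
  expect_identical(classify_icd10("F10"), "alcohol")
  expect_identical(classify_icd10(c("K70", "K74", "X45")),
                   rep("alcohol", 3))
  expect_identical(classify_icd10("V42"), "transport")
  expect_identical(classify_icd10(c("I21", "I64", "G45", "I10", "I99")),
                   rep("circulatory", 5))
  expect_identical(classify_icd10(c("X44", "X60", "Y20", "W10", "X31")),
                   rep("other_external", 5))
  expect_identical(classify_icd10(c("A15", "B20", "J44")),
                   rep("infectious_respiratory", 3))
  expect_identical(classify_icd10(c("C34", "C97")), rep("cancers", 2))
  expect_identical(classify_icd10(c("Z99", "K75", "E11")), rep("rest", 3))
  # subcodes and case are tolerated; malformed strings are not
  expect_identical(classify_icd10("f10.2"), "alcohol")
  expect_error(classify_icd10("10F"), "malformed")
  expect_error(classify_icd10("F1"), "malformed")
})

test_that("cause splitting conserves the all-cause rates exactly", {
  tb <- make_cause_table(2000)
  mx5 <- siler_hazard(seq(0, 85, 5) + 2.5, cee_male_params())
  m <- split_rates_by_cause(mx5, tb)
  expect_identical(dim(m), c(18L, 7L))
  expect_equal(unname(rowSums(m)), unname(mx5), tolerance = 1e-14)
  # single cause with p = 1 carries the whole rate
  p1 <- matrix(0, 18, 7, dimnames = list(seq(0, 85, 5), cause_categories()))
  p1[, "rest"] <- 1
  tb1 <- cause_table(p1, 2000)
  expect_equal(unname(split_rates_by_cause(mx5, tb1)[, "rest"]),
               unname(mx5))
  # equal sevenths below the truncation age
  p7 <- matrix(1 / 7, 18, 7,
               dimnames = list(seq(0, 85, 5), cause_categories()))
  p7[18, ] <- 0; p7[18, "rest"] <- 1
  tb7 <- cause_table(p7, 2000)
  expect_equal(unname(split_rates_by_cause(mx5, tb7)[1, ]),
               rep(mx5[1] / 7, 7))
})

test_that("invalid cause tables are rejected", {
  p <- matrix(1 / 7, 18, 7,
              dimnames = list(seq(0, 85, 5), cause_categories()))
  p[18, ] <- 0; p[18, "rest"] <- 1
  bad <- p; bad[3, 1] <- bad[3, 1] + 0.01
  expect_error(cause_table(bad, 2000), "sum to 1")
  expect_error(cause_table(p[, c(2:7, 1)][, -1], 2000), "7 cause")
  expect_error(cause_table(p, 2000, truncation_age = 80), "rest")
})

test_that("no rate change means zero cause totals", {
  ages5 <- seq(0, 85, 5)
  mx5 <- siler_hazard(ages5 + 2.5, cee_male_params())
  surf <- mortality_surface(cbind(mx5, mx5), ages5, 2000:2001)
  tb <- make_cause_table(2000, ages5)
  d <- decompose_by_age_cause(surf, tb, tb, 2000, 2001)
  expect_true(all(abs(d$by_cause) < 1e-12))
  expect_lt(abs(d$total), 1e-12)
})

test_that("a single-cause perturbation lands on that cause", {
  ages5 <- seq(0, 85, 5)
  mx5 <- siler_hazard(ages5 + 2.5, cee_male_params())
  tb1 <- make_cause_table(2000, ages5)
  # raise only the transport rates at ages 20-49, keep others fixed
  m1 <- split_rates_by_cause(mx5, tb1)
  m2 <- m1
  band <- ages5 >= 20 & ages5 < 50
  m2[band, "transport"] <- m2[band, "transport"] * 1.6
  mx5_2 <- rowSums(m2)
  tb2 <- cause_table(m2 / mx5_2, 2001)
  surf <- mortality_surface(cbind(mx5, mx5_2), ages5, 2000:2001)
  d <- decompose_by_age_cause(surf, tb1, tb2, 2000, 2001,
                              functional = "edagger")
  expect_lt(abs(d$by_cause[["transport"]] - d$total), 1e-6)
  expect_true(all(abs(d$by_cause[setdiff(cause_categories(),
                                         "transport")]) < 1e-7))
  expect_gt(abs(d$total), 1e-3)
})

test_that("cause totals agree with the age-only decomposition", {
  ages5 <- seq(0, 85, 5)
  surf5 <- abridge_surface(two_country_crisis()[["FSU-B"]], ages5)
  sched <- attr(two_country_crisis()[["FSU-B"]], "schedule")
  tb1 <- make_cause_table(1994,
    weights = lifedisparity:::crisis_cause_weights(sched, 1994))
  tb2 <- make_cause_table(2000,
    weights = lifedisparity:::crisis_cause_weights(sched, 2000))
  dc <- decompose_by_age_cause(surf5, tb1, tb2, 1994, 2000,
                               functional = "edagger", n_steps = 40)
  da <- decompose_by_age(surf5, 1994, 2000, functional = "edagger",
                         n_steps = 40)
  expect_lt(abs(sum(dc$by_cause) - sum(da$contributions)), 1e-4)
  expect_equal(unname(rowSums(dc$by_age_cause)),
               unname(da$contributions), tolerance = 1e-3)
})

test_that("label mismatches are rejected", {
  f <- function(x) sum(x)
  expect_error(horiuchi_decompose(f, c(a = 1), c(b = 2)), "labels differ")
  expect_error(horiuchi_decompose(f, 1:2, 1:3), "length")
})
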
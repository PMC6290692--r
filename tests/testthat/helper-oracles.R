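# Fine-grid quadrature oracle: life-table quantities computed directly
# from a continuous hazard by midpoint integration of exp(-integral mu),
# independent of the discrete life-table closure under test.
quadrature_oracle <- function(mu_fun, upper = 150, h = 0.01) {
  x <- seq(0, upper, by = h)
  k <- length(x) - 1
  mid_mu <- mu_fun(x[-length(x)] + h / 2)
  lx <- exp(-cumsum(c(0, mid_mu)) * h)[seq_len(k + 1)]
  seg <- h * (lx[-1] + lx[-(k + 1)]) / 2       # person-years per segment
  Tx <- rev(cumsum(rev(seg)))
  dx <- -diff(lx)
  keep <- lx[-(k + 1)] > 1e-12
  ex <- numeric(k)
  ex[keep] <- Tx[keep] / lx[-(k + 1)][keep]
  e0 <- Tx[1]
  # e-dagger = integral d(a) e(a) da, e at the segment midpoint
  ex_mid <- ex - h / 2
  ex_mid[!keep] <- 0
  edag <- sum(dx * pmax(ex_mid, 0))
  # Gini via 1 - (1/e0) integral l^2
  gini <- 1 - sum(h * (lx[-1]^2 + lx[-(k + 1)]^2) / 2) / e0
  list(e0 = e0, edag = edag, gini = gini, entropy = edag / e0)
}

# Seeded family of plausible adult mortality schedules (Siler + hump with
# jittered parameters) used by the property-style tests.
random_schedule <- function(seed) {
  set.seed(seed)
  p <- cee_male_params()
  p$a1 <- p$a1 * exp(rnorm(1, 0, 0.4))
  p$c  <- p$c * exp(rnorm(1, 0, 0.4))
  p$a2 <- p$a2 * exp(rnorm(1, 0, 0.3))
  p$b2 <- p$b2 * exp(rnorm(1, 0, 0.08))
  p$h  <- p$h * exp(rnorm(1, 0, 0.5))
  p$kappa <- p$kappa + runif(1, -8, 8)
  # cap extreme senescent tails at a plausible maximum rate so every
  # closed interval keeps q < 1 (observed schedules stay well below 1)
  pmin(siler_hazard(0:110, p) * exp(rnorm(111, 0, 0.05)), 1.5)
}

# Brute-force Gini oracle: mean absolute pairwise difference of ages at
# death over the dx atoms (at the mean age at death in each interval),
# divided by twice the mean age at death.
gini_pairwise_oracle <- function(lt) {
  mean_age <- lt$age + ifelse(is.finite(lt$n), lt$ax, lt$ax)
  d <- lt$dx / sum(lt$dx)
  num <- sum(outer(d, d) * abs(outer(mean_age, mean_age, `-`)))
  num / (2 * sum(d * mean_age))
}
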
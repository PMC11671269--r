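# Naive scalar re-implementation of every disproportionality formula,
# written independently of the package internals, used as the oracle in
# equivalence tests. Deliberately plain: no vectorization, no shared code.

naive_signal <- function(a, b, c, d,
                         alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  z95 <- 1.96
  z90 <- 1.64

  odds_drug <- a / b
  odds_rest <- c / d
  ror <- odds_drug / odds_rest
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror_lo <- exp(log(ror) - z95 * se_ror)
  ror_hi <- exp(log(ror) + z95 * se_ror)

  rate_drug <- a / (a + b)
  rate_rest <- c / (c + d)
  prr <- rate_drug / rate_rest
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  prr_lo <- exp(log(prr) - z95 * se_prr)
  prr_hi <- exp(log(prr) + z95 * se_prr)

  chi_den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2_pearson <- n * (a * d - b * c)^2 / chi_den
  adj <- abs(a * d - b * c) - n / 2
  if (adj < 0) adj <- 0
  chi2_yates <- n * adj^2 / chi_den

  expected <- (a + b) * (a + c) / n
  ebgm <- a / expected
  ebgm05 <- exp(log(ebgm) - z90 * se_ror)
  ic <- log(ebgm) / log(2)

  gam <- gamma11 * (n + alpha) * (n + beta) /
    ((a + b + alpha1) * (a + c + beta1))
  e_ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                 ((n + gam) * (a + b + alpha1) * (a + c + beta1)))
  v_ic <- ((n - a + gam - gamma11) / ((a + gamma11) * (1 + n + gam)) +
             (n - (a + b) + alpha - alpha1) /
               ((a + b + alpha1) * (1 + n + alpha)) +
             (n - (a + c) + beta - beta1) /
               ((a + c + beta1) * (1 + n + beta))) / (log(2)^2)
  ic025 <- e_ic - 2 * sqrt(v_ic)

  list(ror = ror, ror_lo = ror_lo, ror_hi = ror_hi, se_ror = se_ror,
       prr = prr, prr_lo = prr_lo, prr_hi = prr_hi,
       chi2_pearson = chi2_pearson, chi2_yates = chi2_yates,
       ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = ic025,
       ebgm = ebgm, ebgm05 = ebgm05)
}
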
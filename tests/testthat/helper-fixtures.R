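# Shared fixtures: the titanium plate study's published values, built in code.

ti64 <- function() material_spec(860, 795, 110000, elongation = 0.10,
                                 poisson_ratio = 0.34)

plate_curve <- function(Cf = 1) build_sn_curve(ti64(), Cf = Cf, Nc1 = 1e6)

static_forces_published <- c(210.5, 299.6, 262.0, 236.6, 263.9)

campaign_lives_published <- c(1230, 23262, 78567, 1e5, 1e5, 1e5)

campaign_forces_published <- c(127.3, 63.6, 44.5, 35.6, 40.1, 42.3)

# Peak stresses (MPa) from the linear-elastic structural analysis, by label.
elastic_peak_stress <- c(E01 = 1824.5, E02 = 940, E03 = 658.6,
                         E04 = 526.2, E05 = 593.2, E06 = 525.9)
precondition_stress <- 220.1

plate_case <- function(label, force = 40) {
  load_case(label, force, 15, elastic_peak_stress[[label]],
            precondition_stress)
}

# Independent oracle: closed-form normal equations for log-log OLS,
# force = A * life^beta. Returns coefficient, exponent, r_squared and the
# two-sided t-test p-value of the slope.
oracle_loglog_fit <- function(force, life) {
  x <- log10(life)
  y <- log10(force)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  p <- if (n > 2) {
    se <- sqrt(ss_res / (n - 2) / sxx)
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  } else NA_real_
  list(coefficient = 10^intercept, exponent = slope,
       r_squared = 1 - ss_res / ss_tot, p_value = p)
}

# Independent oracle: invert the two-anchor log-log S-N line.
oracle_life_at_stress <- function(S1, S2, Nc1, sw) {
  10^(3 + (log10(Nc1) - 3) * (log10(S1) - log10(sw)) /
        (log10(S1) - log10(S2)))
}
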
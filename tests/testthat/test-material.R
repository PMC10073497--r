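test_that("S-N curve synthesis reproduces the two-anchor construction", {
  cv <- plate_curve()
  expect_equal(cv$S1, 688)
  expect_equal(cv$S2, 264.02)
  expect_equal(cv$b, log10(264.02 / 688) / 3, tolerance = 1e-12)
  expect_equal(cv$b, -0.13865, tolerance = 1e-4)

  # unit-scaled ultimate strength
  cv2 <- build_sn_curve(material_spec(1000, 900, 110000))
  expect_equal(cv2$S1, 800)
  expect_equal(cv2$S2, 307)

  # Cf scales the endurance anchor only
  cv_half <- plate_curve(Cf = 0.5)
  expect_equal(cv_half$S2, 132.01)
  expect_equal(cv_half$S1, 688)
})

test_that("anchor exactness and Cf scaling hold across materials", {
  set.seed(42)
  for (i in 1:25) {
    su <- runif(1, 300, 2000)
    Cf <- runif(1, 0.05, 1)
    Nc1 <- 10^runif(1, 4, 8)
    m <- material_spec(su, 0.9 * su, 110000)
    cv <- build_sn_curve(m, Cf = Cf, Nc1 = Nc1)
    expect_equal(stress_at_life(cv, 1e3), cv$S1, tolerance = 1e-12)
    expect_equal(stress_at_life(cv, Nc1), cv$S2, tolerance = 1e-12)
    expect_equal(cv$S2, 0.307 * Cf * su, tolerance = 1e-12)
  }
})

test_that("stress_at_life interpolates log-linearly and decreases", {
  cv <- plate_curve()
  expect_equal(stress_at_life(cv, 10^4.5), sqrt(688 * 264.02),
               tolerance = 1e-12)
  N <- 10^seq(2, 8, by = 0.25)
  s <- stress_at_life(cv, N)
  expect_true(all(diff(s) < 0))
  expect_error(stress_at_life(cv, 0), "positive")
})

test_that("life_at_stress inverts the curve, flags endurance and low cycle", {
  cv <- plate_curve()
  expect_equal(life_at_stress(cv, 688)$life, 1e3, tolerance = 1e-9)
  expect_equal(life_at_stress(cv, 264.02)$life, 1e6, tolerance = 1e-9)
  out <- life_at_stress(cv, 270.4)
  expect_identical(out$status, "finite")
  expect_equal(out$life, oracle_life_at_stress(688, 264.02, 1e6, 270.4),
               tolerance = 1e-9)
  expect_equal(out$life, 8.4e5, tolerance = 0.005)

  expect_identical(life_at_stress(cv, 200)$status, "endurance")
  expect_identical(life_at_stress(cv, 200)$life, Inf)
  lc <- life_at_stress(cv, 700)
  expect_identical(lc$status, "low_cycle")
  expect_true(is.na(lc$life))
  lc2 <- life_at_stress(cv, 700, extrapolate = TRUE)
  expect_true(lc2$life < 1e3)
  expect_error(life_at_stress(cv, -5), "positive")
})

test_that("stress/life round-trip holds over the validity window", {
  set.seed(7)
  for (Cf in c(1, 0.6, runif(3, 0.1, 1))) {
    cv <- plate_curve(Cf = Cf)
    for (N in 10^runif(10, 3, 6)) {
      s <- stress_at_life(cv, N)
      expect_equal(life_at_stress(cv, s)$life, N, tolerance = 1e-9)
    }
  }
})

test_that("invalid material or curve parameters are rejected", {
  expect_error(material_spec(-860, 795, 110000), "positive")
  expect_error(material_spec(860, 900, 110000), "yield")
  expect_error(material_spec(860, 795, 110000, elongation = 1.5), "fraction")
  expect_error(build_sn_curve(ti64(), Cf = 0), "Cf")
  expect_error(build_sn_curve(ti64(), Cf = 1.2), "Cf")
  expect_error(build_sn_curve(ti64(), Nc1 = 500), "Nc1")
})

test_that("strain-life construction follows the standard estimates", {
  sl <- build_strain_life(ti64())
  expect_equal(sl$sigma_f_prime, 1436.2)
  expect_equal(sl$eps_f_prime, 0.35)
  expect_equal(sl$c, -0.69)
  expect_equal(sl$b, -0.095)
  expect_equal(build_strain_life(material_spec(100, 90, 110000))$sigma_f_prime,
               167)
  expect_error(build_strain_life(ti64(), b = 0.1), "negative")
  expect_error(build_strain_life(ti64(), c = -0.05), "below")
})

test_that("strain amplitudes decompose as Basquin + Coffin-Manson", {
  sl <- build_strain_life(ti64())
  E <- 110000
  at1 <- strain_amplitudes(sl, E, 1)
  expect_equal(at1$elastic, sl$sigma_f_prime / E)
  expect_equal(at1$plastic, sl$eps_f_prime)
  expect_equal(at1$total, at1$elastic + at1$plastic)
})

test_that("transition life matches the closed-form oracle and balances strains", {
  sl <- build_strain_life(ti64())
  oracle <- function(eps_f, E, sf, b, c) (eps_f * E / sf)^(1 / (b - c))
  t1 <- transition_life(sl, 110000)
  expect_equal(t1, oracle(0.35, 110000, 1436.2, -0.095, -0.69),
               tolerance = 1e-10)
  expect_equal(t1, 251.5, tolerance = 0.001)
  # monotone increasing in E
  t2 <- transition_life(sl, 220000)
  expect_equal(t2, oracle(0.35, 220000, 1436.2, -0.095, -0.69),
               tolerance = 1e-10)
  expect_equal(t2, 805, tolerance = 0.005)
  expect_gt(t2, t1)
  # elastic and plastic strain amplitudes equal at the transition
  a <- strain_amplitudes(sl, 110000, t1)
  expect_lt(abs(a$elastic - a$plastic) / a$elastic, 1e-10)
  # eps_f' * E == sigma_f' puts the transition at one reversal
  m <- material_spec(860, 795, 1436.2 / 0.35)
  expect_equal(transition_life(build_strain_life(m), m$elastic_modulus), 1)
})

test_that("sn_curve_table spans the validity window", {
  cv <- plate_curve()
  tab <- sn_curve_table(cv, n = 11)
  expect_equal(nrow(tab), 11)
  expect_equal(tab$N[1], 1e3)
  expect_equal(tab$N[11], 1e6)
  expect_equal(tab$stress_amplitude_MPa[1], 688, tolerance = 1e-12)
})
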
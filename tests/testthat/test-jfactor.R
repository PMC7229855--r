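test_that("wormlike-chain sampling matches closed-form moments", {
  m <- wlc_model(100, persistence_length = 50, segment_bp = 1)
  ens <- wlc_sample(m, 2e4, seed = 5)
  expect_equal(dim(ens$r), c(2e4, 3))

  # seeded reproducibility: bit-identical ensembles
  ens2 <- wlc_sample(m, 2e4, seed = 5)
  expect_identical(ens$r, ens2$r)
  expect_identical(ens$t_last, ens2$t_last)

  # <R^2> against the discrete-chain closed form
  kap <- m$persistence_length / m$segment_length
  c1 <- wlc_mean_cos(kap)
  r2_th <- wlc_r2(m$n_segments, m$segment_length, c1)
  r2_mc <- mean(rowSums(ens$r^2))
  expect_equal(r2_mc, r2_th, tolerance = 0.02)

  # successive-tangent correlation ~ exp(-l/Lp) for stiff joints
  expect_equal(c1, exp(-m$segment_length / m$persistence_length),
               tolerance = 1e-4)

  # contour conservation: no chain extends beyond its contour length, and
  # a very stiff short chain stays nearly straight
  rn <- sqrt(rowSums(ens$r^2))
  expect_true(all(rn <= m$contour_length + 1e-9))
  m_stiff <- wlc_model(10, persistence_length = 5000, segment_bp = 1)
  e1 <- wlc_sample(m_stiff, 100, seed = 1)
  expect_equal(mean(sqrt(rowSums(e1$r^2))), m_stiff$contour_length,
               tolerance = 0.01)
})

test_that("encounter-referenced end angles follow the sine law", {
  m <- wlc_model(500, persistence_length = 50, segment_bp = 2)
  ens <- wlc_sample(m, 1e5, seed = 11)
  set.seed(12)
  ad <- end_angle_distribution(ens, bins = 24, reference = "encounter")
  expect_equal(sum(ad$density), 1, tolerance = 1e-9)

  # KS test of the marginals against the sine law p(t) = sin(t)/2
  ks <- stats::ks.test(ad$theta$theta1, function(q) (1 - cos(q)) / 2)
  expect_gt(ks$p.value, 0.01)
  ks2 <- stats::ks.test(ad$theta$theta2, function(q) (1 - cos(q)) / 2)
  expect_gt(ks2$p.value, 0.01)

  # chain-referenced marginals drift toward the sine law with length but
  # never reach it at these contour lengths
  D <- vapply(c(500, 2000), function(bp) {
    mm <- wlc_model(bp, persistence_length = 50, segment_bp = bp / 250)
    aa <- end_angle_distribution(wlc_sample(mm, 2e4, seed = 3))
    unname(stats::ks.test(aa$theta$theta1,
                          function(q) (1 - cos(q)) / 2)$statistic)
  }, numeric(1))
  expect_lt(D[2], D[1])
})

test_that("the constrained-ensemble sampler agrees with rejection sampling", {
  # in a regime direct sampling can reach, the Metropolis sampler and the
  # rejection-filtered direct ensemble must give the same constrained
  # statistics
  m <- wlc_model(500, persistence_length = 50, segment_bp = 2)
  dir <- wlc_sample(m, 1e5, seed = 3)
  rej <- end_angle_distribution(dir, r_max = 60)
  mc <- end_angle_distribution(wlc_sample_constrained(m, 60, 4000, seed = 4))
  expect_lt(abs(circular_variance(rej$theta$theta1) -
                  circular_variance(mc$theta$theta1)), 0.02)
  expect_lt(abs(mean(rej$theta$theta1) - mean(mc$theta$theta1)), 0.05)
  # every sampled chain honours the hard wall
  mc_ens <- wlc_sample_constrained(m, 60, 500, seed = 5)
  expect_true(all(sqrt(rowSums(mc_ens$r^2)) <= 60))
})

test_that("loop closure restrains end angles for short but not long chains", {
  r_max <- 7
  m100 <- wlc_model(100, persistence_length = 50, segment_bp = 1)
  m500 <- wlc_model(500, persistence_length = 50, segment_bp = 2)

  # 100-bp loop: angles concentrated; circular variance less than half the
  # bimolecular-encounter (sine-law) value
  con100 <- end_angle_distribution(
    wlc_sample_constrained(m100, r_max, 6000, seed = 2,
                           thin = 2 * m100$n_segments))
  cv_sine <- 1 - pi / 4
  expect_lt(circular_variance(con100$theta$theta1), cv_sine / 2)
  expect_lt(circular_variance(con100$theta$theta2), cv_sine / 2)

  # 500-bp loop: marginals stay near the sine law, much closer than the
  # unconstrained open chain of the same length
  un500 <- end_angle_distribution(wlc_sample(m500, 5e4, seed = 2))
  con500 <- end_angle_distribution(
    wlc_sample_constrained(m500, r_max, 5000, seed = 2))
  ks_un <- stats::ks.test(un500$theta$theta1,
                          function(q) (1 - cos(q)) / 2)$statistic
  ks_con <- stats::ks.test(con500$theta$theta1,
                           function(q) (1 - cos(q)) / 2)$statistic
  expect_lt(ks_con, max(2 * ks_un, 0.05))

  # too-tight constraint errors with the acceptance count for the
  # rejection path
  expect_error(end_angle_distribution(wlc_sample(m500, 200, seed = 3),
                                      r_max = 2), "more samples")
})

test_that("capture J factor matches the Gaussian limit for long chains", {
  # 1000 bp with Lp = 17 nm is 20 persistence lengths: deep in the
  # Gaussian-coil regime
  m <- wlc_model(1000, persistence_length = 17, segment_bp = 2)
  res <- jfactor_capture(m, capture_distance = 7, n_samples = 4e5, seed = 9)
  kap <- m$persistence_length / m$segment_length
  r2 <- wlc_r2(m$n_segments, m$segment_length, wlc_mean_cos(kap))
  j_gauss <- gaussian_j_capture(r2, 7)
  expect_equal(res$j_M, j_gauss, tolerance = 0.15)
  expect_identical(res$method, "monte_carlo")
})

test_that("capture J responds to flexibility and capture radius as expected", {
  mk <- function(lp) wlc_model(100, persistence_length = lp, segment_bp = 1)
  j40 <- jfactor_capture(mk(40), 12, n_samples = 3e5, seed = 4)
  j50 <- jfactor_capture(mk(50), 12, n_samples = 3e5, seed = 4)
  expect_gt(j40$j_M, j50$j_M)  # softer DNA loops more readily at 100 bp

  # monotone in capture distance
  j_small <- jfactor_capture(mk(50), 10, n_samples = 2e5, seed = 6)
  j_big <- jfactor_capture(mk(50), 14, n_samples = 2e5, seed = 6)
  expect_gt(j_big$p_capture, j_small$p_capture)

  # capture ball larger than the contour: every chain captured
  m_small <- wlc_model(30, persistence_length = 50, segment_bp = 1)
  a <- 30 * 0.34 + 1
  res <- jfactor_capture(m_small, a, n_samples = 5e3, seed = 1)
  expect_equal(res$p_capture, 1)
  avo <- 6.02214076e23
  expect_equal(res$j_M, 1 / (4 / 3 * pi * a^3 * 1e-24 * avo),
               tolerance = 1e-9)

  # zero captures: flagged upper bound, not a bare zero
  m_stiff <- wlc_model(50, persistence_length = 50, segment_bp = 1)
  res0 <- jfactor_capture(m_stiff, 0.5, n_samples = 2e3, seed = 1)
  expect_true(res0$censored_zero)
  expect_gt(res0$j_M, 0)
})

test_that("aligned J factor carries the helical-phase modulation", {
  m <- wlc_model(105, persistence_length = 50)
  # integer-turn length: twist factor near its maximum
  j_int <- jfactor_aligned(m, 105)
  j_half <- jfactor_aligned(m, 110)  # 10.48 turns, near half-integer
  expect_gt(j_int$twist_factor, j_half$twist_factor)

  # modulation across one helical period at L ~ 100 bp spans >= 2 decades
  Ls <- seq(100, 111, 0.5)
  tw <- vapply(Ls, function(L) jfactor_aligned(m, L)$twist_factor, numeric(1))
  expect_gte(log10(max(tw) / min(tw)), 2)

  # outside the validity window
  expect_error(jfactor_aligned(m, 10), "L/Lp")
  expect_error(jfactor_aligned(m, 500), "L/Lp")
})

test_that("alignment free energy behaves like a log ratio", {
  expect_equal(alignment_free_energy(1e-8, 1e-8), 0)
  expect_equal(alignment_free_energy(1e-8 / exp(1), 1e-8), 1)
  expect_error(alignment_free_energy(-1, 1), "positive")

  # half-integer loops pay far more alignment free energy than integer loops
  m <- wlc_model(105, persistence_length = 50)
  res_int <- jfactor_aligned(m, 105)
  res_half <- jfactor_aligned(m, 100.75)  # 9.595 turns
  dg_int <- alignment_free_energy(res_int$j_aligned_M, res_int$j_unaligned_M)
  dg_half <- alignment_free_energy(res_half$j_aligned_M,
                                   res_half$j_unaligned_M)
  expect_gt(dg_half, dg_int)
  expect_gt(dg_int, 0)
})

test_that("stacking comparison flags compensated and marginal cases", {
  expect_true(compare_to_stacking(0, -5)$stacking_compensated)
  edge <- compare_to_stacking(5, -5)
  expect_true(edge$marginal)

  # computed alignment costs vs a plausible stacking free energy:
  # integer loop compensated, half-integer not
  m <- wlc_model(105, persistence_length = 50)
  dg_int <- alignment_free_energy(jfactor_aligned(m, 105)$j_aligned_M,
                                  jfactor_aligned(m, 105)$j_unaligned_M)
  dg_half <- alignment_free_energy(jfactor_aligned(m, 100.75)$j_aligned_M,
                                   jfactor_aligned(m, 100.75)$j_unaligned_M)
  dg_stack <- -(dg_int + 1)  # a stacking energy 1 kT beyond the integer cost
  expect_true(compare_to_stacking(dg_int, dg_stack)$stacking_compensated)
  expect_false(compare_to_stacking(dg_half, dg_stack)$stacking_compensated)
})

test_that("experimental J factor is the rate ratio", {
  expect_equal(j_exp(1.196e-2, 1.196e6), 1e-8)
  expect_equal(j_exp(5, 5), 1)
  expect_equal(j_exp(1, 0.5e6) / j_exp(1, 1e6), 2)
  expect_error(j_exp(-1, 1), "positive")
})

test_that("integer-turn lengths reproduce the helical-period arithmetic", {
  lens <- integer_turn_lengths(10.5, c(90, 140))
  expect_true(115.5 %in% lens)
  expect_equal(lens, c(94.5, 105, 115.5, 126, 136.5))
})
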
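test_that("circular-arc initialization has the documented conventions", {
  # zero intrinsic twist, theta = 0: all bend in roll
  p <- dna_params(60, helical_repeat = 1e9)
  arc <- init_circular_arc(p, register_angle = 0, closure_fraction = 0.5)
  expect_lt(max(abs(arc$tilt)), 1e-6)
  expect_lt(max(abs(arc$twist)), 1e-6)
  expect_equal(arc$roll, rep(0.5 * 2 * pi / 59, 59), tolerance = 1e-7)

  # the arc's end-to-end distance equals the chord of the total bend
  p2 <- dna_params(105)
  for (cf in c(0.4, 0.9)) {
    arc2 <- init_circular_arc(p2, register_angle = 1.1, closure_fraction = cf)
    conf <- build_conformation(arc2, p2)
    ee <- sqrt(sum((conf$origins[105, ] - conf$origins[1, ])^2))
    total <- cf * 2 * pi
    chord <- (104 * 0.34) * sin(total / 2) / (total / 2)
    expect_equal(ee, chord, tolerance = 0.01)
  }

  # opposite registers give mirror arcs with identical bend energy
  e0 <- bend_energy(init_circular_arc(p2, 0), p2)
  epi <- bend_energy(init_circular_arc(p2, pi), p2)
  expect_equal(e0, epi, tolerance = 1e-9)

  expect_error(init_circular_arc(p2, 0, closure_fraction = 0), "closure")
})

test_that("a loose constraint relaxes to the ground state", {
  p <- dna_params(60)
  straight <- build_conformation(ground_state_angles(p), p)
  d_rel <- backbone_end_distance(straight)
  fit <- minimize_loop(p, register_angle = 0.7, constraint_target = d_rel + 1,
                       closure_fraction = 0.3)
  expect_true(fit$converged)
  expect_lt(fit$energy_kT, 1e-4)
})

test_that("zero-width teardrop energies match the elastica oracle", {
  coef <- teardrop_elastica_coef()
  expect_equal(coef, 14.055, tolerance = 1e-3)
  # L/Lp spanning the short-loop regime
  for (n_bp in c(35, 105, 175)) {
    p <- dna_params(n_bp, persistence_length = 50, helix_radius = 0)
    fit <- minimize_loop(p, constraint_target = 0,
                         kc_schedule = c(10, 100, 1000, 1e4))
    L <- (n_bp - 1) * 0.34
    expect_true(fit$converged)
    expect_equal(fit$energy_kT, coef * 50 / L, tolerance = 0.03)
  }
})

test_that("constrained optimum satisfies the distance constraint", {
  for (L in c(95, 108)) {
    p <- dna_params(L)
    fit <- minimize_loop(p, register_angle = 2.0, constraint_target = 1)
    expect_true(fit$converged)
    expect_lte(fit$constraint_violation_nm, 0.05)
    # reported energy excludes the penalty: rebuilding the conformation and
    # re-scoring the elastic term reproduces it exactly
    expect_equal(bend_energy(fit$angles, p), fit$energy_kT, tolerance = 1e-9)
    expect_equal(backbone_end_distance(loop_conformation(fit)),
                 fit$distance_nm, tolerance = 1e-9)
  }
})

test_that("fully relaxed loops are costlier at integer than half-integer turns", {
  # 105 bp = 10 turns; 100 bp = 9.52 turns (near half-integer).  The sticky
  # ends sit on opposite helix faces at integer turns, frustrating a planar
  # inward-facing loop.
  e <- vapply(c(100, 105), function(L) {
    p <- dna_params(L)
    min(vapply(seq(0, 2 * pi, length.out = 7)[1:6], function(th) {
      minimize_loop(p, register_angle = th)$energy_kT
    }, numeric(1)))
  }, numeric(1))
  expect_gt(e[2], e[1])
})

test_that("quasi-static descent resolves the register angle", {
  # without the polish, the minimization freezes the soft register-rotation
  # mode and E_bend(Theta) keeps a smooth single-minimum structure
  p <- tune_curvature(dna_params(105))
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  e <- vapply(th, function(t) {
    minimize_loop(p, register_angle = t, polish = FALSE, grad_tol = 0.5,
                  flow_iters = 15000, kc_schedule = 1000,
                  flow_ftol = 1e-6)$energy_kT
  }, numeric(1))
  expect_gt(diff(range(e)), 1)          # several kT of register structure
  expect_equal(length(unique(round(e, 6))), 6L)  # all distinct
})

test_that("energy landscape composes minimize_loop and records convergence", {
  p <- dna_params(105)
  ls <- energy_landscape(p, lengths = c(100, 105), thetas = c(0, pi / 2, pi))
  expect_s3_class(ls, "energy_landscape")
  expect_equal(nrow(ls), 6L)
  expect_true(all(is.finite(ls$energy_kT[ls$converged])))

  # 1 length x 1 theta reduces to a single minimize_loop call
  one <- energy_landscape(p, lengths = 105, thetas = 0)
  direct <- minimize_loop(dna_params(105), register_angle = 0,
                          polish = FALSE, grad_tol = 0.5,
                          flow_iters = 15000, kc_schedule = 1000,
                          flow_ftol = 1e-6)
  expect_equal(one$energy_kT, direct$energy_kT, tolerance = 1e-12)

  expect_error(energy_landscape(p, lengths = 20, thetas = 4), "30")
  expect_error(energy_landscape(p, lengths = 100, thetas = c(-1)), "thetas")
})

test_that("rate profile is a Boltzmann sum over register angles", {
  flat <- structure(
    tidyr::expand_grid(length_bp = c(100, 102, 104), theta_rad =
                         seq(0, 2 * pi, length.out = 9)[1:8]) |>
      dplyr::mutate(energy_kT = 5, converged = TRUE),
    class = c("energy_landscape", "tbl_df", "tbl", "data.frame")
  )
  pr <- looping_rate_profile(flat)
  expect_true(all(abs(pr$k_rel - pr$k_rel[1]) < 1e-12))

  # two angles, one prohibitively expensive: sum equals half the all-zero sum
  two <- structure(
    tibble::tibble(length_bp = 100, theta_rad = c(0, pi),
                   energy_kT = c(0, 500), converged = TRUE),
    class = c("energy_landscape", "tbl_df", "tbl", "data.frame")
  )
  zero2 <- structure(
    tibble::tibble(length_bp = 100, theta_rad = c(0, pi),
                   energy_kT = c(0, 0), converged = TRUE),
    class = c("energy_landscape", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(looping_rate_profile(two)$k_rel,
               looping_rate_profile(zero2)$k_rel / 2, tolerance = 1e-12)

  # half-interval selection keeps angles in [start, start + pi)
  pr_half <- looping_rate_profile(flat, register_interval = "half")
  expect_equal(pr_half$k_rel, pr$k_rel / 2, tolerance = 1e-12)
  empty <- flat[flat$theta_rad >= pi, ]
  expect_error(looping_rate_profile(empty, register_interval = "half"),
               "empty")
})

test_that("nicked-loop minimization reproduces the planarity contrast", {
  fits <- lapply(c(105, 100), function(L) {
    minimize_nicked_loop(dna_params(L), closure_fraction = 0.95)
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  pl <- vapply(fits, function(f) planarity_metric(loop_conformation(f)),
               numeric(1))
  # integer-turn loop (105 bp) nearly planar; half-integer (100 bp) is not
  expect_lt(pl[1], 0.1)
  expect_gt(pl[2], 2 * pl[1])

  # with no excluded volume and the sticky-end constraint it reduces to
  # minimize_loop behaviour
  p <- dna_params(70, helix_radius = 0)
  a <- minimize_nicked_loop(p, excluded_bp = 0, constraint_target = 0,
                            closure_fraction = 0.9)
  b <- minimize_loop(p, constraint_target = 0, closure_fraction = 0.9)
  expect_equal(a$energy_kT, b$energy_kT, tolerance = 0.02)
})

test_that("oscillation periods are recovered from synthetic profiles", {
  L <- seq(90, 136, 2)
  quad <- 0.002 * (L - 110)^2 - 0.05 * L
  clean <- exp(quad + 0.4 * sin(2 * pi * L / 10.5))
  fit <- oscillation_period(tibble::tibble(length_bp = L, value = log(clean)))
  expect_equal(fit$period_bp, 10.5, tolerance = 0.5)
  expect_true(fit$significant)

  # a stronger two-turn component dominates
  mix <- quad + 0.2 * sin(2 * pi * L / 10.5) + 0.6 * sin(2 * pi * L / 21)
  fit2 <- oscillation_period(tibble::tibble(length_bp = L, value = mix))
  expect_equal(fit2$period_bp, 21, tolerance = 1.5)

  # white noise: no significant dominant period
  set.seed(3)
  noise <- tibble::tibble(length_bp = L, value = rnorm(length(L)))
  fit3 <- oscillation_period(noise, n_perm = 500)
  expect_false(fit3$significant)

  expect_error(oscillation_period(tibble::tibble(length_bp = 1:4,
                                                 value = rnorm(4))),
               "uniformly spaced|coverage")
})

test_that("rate profiles are stable under register-grid refinement", {
  p <- dna_params(103)
  ls_a <- energy_landscape(p, lengths = c(100, 105), thetas = 8)
  ls_b <- energy_landscape(p, lengths = c(100, 105), thetas = 16)
  ra <- looping_rate_profile(ls_a)
  rb <- looping_rate_profile(ls_b)
  ratio_a <- ra$k_rel[1] / ra$k_rel[2]
  ratio_b <- rb$k_rel[1] / rb$k_rel[2]
  expect_equal(ratio_a, ratio_b, tolerance = 0.02)
})
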
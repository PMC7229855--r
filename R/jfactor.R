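#' Discrete wormlike-chain model
#'
#' Defines a discrete wormlike chain for Monte Carlo sampling of end-to-end
#' statistics: contour discretized into segments of `segment_bp` base pairs
#' (0.34 nm/bp), with per-joint bending drawn from the Boltzmann measure
#' \eqn{p(\cos\theta) \propto \exp[(L_p/\ell)\cos\theta]} (the exact discrete
#' analogue of wormlike bending; Gaussian in \eqn{\theta} for stiff joints)
#' and uniform azimuth.
#'
#' @param length_bp Chain length in base pairs.
#' @param persistence_length Bending persistence length Lp in nm (default 50).
#' @param torsional_persistence Torsional persistence length in nm, used only
#'   by the helically aligned J factor (default 90).
#' @param helical_repeat Helical repeat in bp (default 10.5).
#' @param segment_bp Segment size in bp (default 1).
#' @param rise nm per bp (default 0.34).
#' @return A `wlc_model` object.
#' @export
wlc_model <- function(length_bp, persistence_length = 50,
                      torsional_persistence = 90, helical_repeat = 10.5,
                      segment_bp = 1, rise = 0.34) {
  check_positive(length_bp, "length_bp")
  check_positive(persistence_length, "persistence_length")
  check_positive(torsional_persistence, "torsional_persistence")
  check_positive(segment_bp, "segment_bp")
  check_positive(rise, "rise")
  n_segments <- max(2L, as.integer(round(length_bp / segment_bp)))
  structure(
    list(length_bp = length_bp, n_segments = n_segments,
         segment_length = length_bp * rise / n_segments,
         contour_length = length_bp * rise,
         persistence_length = persistence_length,
         torsional_persistence = torsional_persistence,
         helical_repeat = helical_repeat, rise = rise),
    class = "wlc_model"
  )
}

#' @export
print.wlc_model <- function(x, ...) {
  cat("<wlc_model> ", x$length_bp, " bp (", x$n_segments, " segments of ",
      signif(x$segment_length, 4), " nm), Lp = ", x$persistence_length,
      " nm\n", sep = "")
  invisible(x)
}

#' Sample wormlike-chain conformations
#'
#' Draws independent chains and records, for each, the end-to-end vector and
#' the terminal tangents (the first tangent is the z axis by construction).
#' Reproducible: the sampler uses R's RNG, so a fixed `seed` gives an
#' identical ensemble.
#'
#' @param model A [wlc_model()].
#' @param n_samples Number of chains (>= 1).
#' @param seed Integer seed.
#' @return A `wlc_ensemble` object: list with `r` (n x 3, nm), `t_first`,
#'   `t_last` (n x 3 unit vectors) and the model.
#' @export
wlc_sample <- function(model, n_samples, seed = 1) {
  stopifnot(inherits(model, "wlc_model"))
  if (n_samples < 1) stop_param("`n_samples` must be >= 1")
  set.seed(as.integer(seed))
  kappa <- model$persistence_length / model$segment_length
  m <- .wlc_sample_cpp(as.integer(n_samples), model$n_segments,
                       model$segment_length, kappa)
  structure(
    list(r = m[, 1:3, drop = FALSE],
         t_first = matrix(rep(c(0, 0, 1), each = nrow(m)), ncol = 3),
         t_last = m[, 4:6, drop = FALSE],
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         model = model),
    class = "wlc_ensemble"
  )
}

#' @export
print.wlc_ensemble <- function(x, ...) {
  cat("<wlc_ensemble> ", x$n_samples, " chains of ", x$model$length_bp,
      " bp (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Joint distribution of end angles
#'
#' For each chain, computes the angles theta1 and theta2 between the terminal
#' tangents and the end-to-end vector: theta1 against the outward end-to-end
#' vector at the first end and theta2 against the inward vector at the last
#' end, so that for an unconstrained chain both marginals follow the sine law
#' \eqn{p(\theta) = \sin(\theta)/2} on \eqn{[0, \pi]}.  Optionally keeps only
#' chains whose end separation is at most `r_max` (the looping-relevant
#' sub-ensemble) before building the normalized joint histogram.
#'
#' With `reference = "encounter"`, angles are computed against independent
#' uniformly random directions instead of the chain's own end-to-end vector:
#' this is the bimolecular-encounter null (two separate molecules meet with
#' uncorrelated orientations), whose marginals follow the sine law exactly.
#' The chain-referenced marginals approach the sine law only for chains much
#' longer than the persistence length.
#'
#' @param ensemble A [wlc_sample()] or [wlc_sample_constrained()] result.
#' @param r_max End-to-end cap in nm, or `NULL` for no constraint.
#' @param bins Number of bins per angle (default 30).
#' @param reference `"chain"` (against the end-to-end vector) or
#'   `"encounter"` (against independent random directions; uses the current
#'   RNG state).
#' @return An `angle_distribution` object: `density` matrix (sums to 1), bin
#'   edges, per-chain angles (`theta` tibble) and acceptance info.
#' @export
end_angle_distribution <- function(ensemble, r_max = NULL, bins = 30,
                                   reference = c("chain", "encounter")) {
  stopifnot(inherits(ensemble, "wlc_ensemble"))
  reference <- match.arg(reference)
  rn <- sqrt(rowSums(ensemble$r^2))
  keep <- if (is.null(r_max)) rep(TRUE, length(rn)) else rn <= r_max
  n_acc <- sum(keep)
  if (n_acc == 0) {
    stop_param("no chains satisfy |r| <= ", r_max,
               " (acceptance rate 0 of ", length(rn), "); draw more samples")
  }
  if (!is.null(r_max) && n_acc < 100) {
    stop_param("only ", n_acc, " of ", length(rn), " chains satisfy |r| <= ",
               r_max, "; draw more samples (need >= 100)")
  }
  if (reference == "chain") {
    rhat <- ensemble$r[keep, , drop = FALSE] / rn[keep]
  } else {
    z <- matrix(stats::rnorm(3 * n_acc), ncol = 3)
    rhat <- z / sqrt(rowSums(z^2))
  }
  ct1 <- rowSums(ensemble$t_first[keep, , drop = FALSE] * rhat)
  ct2 <- rowSums(ensemble$t_last[keep, , drop = FALSE] * rhat)
  th1 <- acos(pmin(1, pmax(-1, ct1)))
  th2 <- acos(pmin(1, pmax(-1, ct2)))  # inward convention at the far end
  edges <- seq(0, pi, length.out = bins + 1)
  h <- table(cut(th1, edges, include.lowest = TRUE),
             cut(th2, edges, include.lowest = TRUE))
  density <- unclass(h) / n_acc
  structure(
    list(theta1_edges = edges, theta2_edges = edges, density = density,
         theta = tibble::tibble(theta1 = th1, theta2 = th2),
         n_samples = length(rn), n_accepted = n_acc,
         r_max = r_max %||% NA_real_, model = ensemble$model),
    class = "angle_distribution"
  )
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat("<angle_distribution> ", x$n_accepted, "/", x$n_samples,
      " chains", if (!is.na(x$r_max)) paste0(" with |r| <= ", x$r_max, " nm"),
      ", ", nrow(x$density), "x", ncol(x$density), " bins\n", sep = "")
  invisible(x)
}

#' Circular variance of an angle sample
#'
#' `1 - |mean(exp(i*theta))|`; 0 for a point mass, larger for spread-out
#' angles.  Used to quantify how strongly loop closure restrains the end
#' angles.
#'
#' @param theta Angles in radians.
#' @return Circular variance in `[0, 1]`.
#' @export
circular_variance <- function(theta) {
  1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Monte Carlo J factor with a capture-distance end condition
#'
#' Estimates the probability that the chain ends approach within the capture
#' distance `a` and converts it to an effective molar concentration:
#' \eqn{J = P(|r| \le a) / (\tfrac{4}{3}\pi a^3 N_A)} in mol/L.  No
#' orientational condition is imposed: this is the torsionally and axially
#' unaligned J factor relevant to sticky-end capture.
#'
#' @param model A [wlc_model()].
#' @param capture_distance Capture radius a in nm (default 7).
#' @param n_samples Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A one-row tibble: `length_bp`, `j_M` (mol/L), `p_capture`,
#'   `n_captured`, `mc_error` (relative standard error), `capture_nm`,
#'   `method`.  If no chain is captured, `j_M` is an upper bound (one
#'   capture) and `censored_zero` is `TRUE`.
#' @export
jfactor_capture <- function(model, capture_distance = 7, n_samples = 1e5,
                            seed = 1) {
  stopifnot(inherits(model, "wlc_model"))
  check_positive(capture_distance, "capture_distance")
  ens <- wlc_sample(model, n_samples, seed)
  rn <- sqrt(rowSums(ens$r^2))
  k <- sum(rn <= capture_distance)
  vol_L <- 4 / 3 * pi * capture_distance^3 * 1e-24  # nm^3 -> L
  conc1 <- 1 / (vol_L * .AVOGADRO)                  # mol/L per unit P
  censored_zero <- k == 0
  keff <- max(k, 1L)
  p <- keff / n_samples
  tibble::tibble(
    length_bp = model$length_bp,
    j_M = p * conc1,
    p_capture = p,
    n_captured = as.integer(k),
    mc_error = sqrt(max(1 - p, 0) / keff),
    capture_nm = capture_distance,
    method = "monte_carlo",
    censored_zero = censored_zero
  )
}

# Shimada-Yamakawa-type saddle-point closure densities, in chains per Lp^3.
# l = L / Lp.  The teardrop form (position-only contact, free end
# orientations) carries the teardrop elastica exponent 14.055; the ring form
# (tangent-aligned ends) the circular exponent 2*pi^2.
.sy_teardrop <- function(l) 28.01 * l^-5 * exp(0.246 * l - 14.055 / l)
.sy_ring <- function(l) 112.04 * l^-5 * exp(0.246 * l - 2 * pi^2 / l)

#' Semi-analytic J factors with and without helical alignment
#'
#' Closed-form (Shimada-Yamakawa-type saddle-point) cyclization densities for
#' a twisted wormlike chain.  The unaligned J uses the teardrop closure
#' (ends in contact, orientations free).  The helically aligned J factor
#' J_thetaphi additionally requires axial alignment (ring closure exponent
#' \eqn{2\pi^2 L_p/L}) and torsional registry: a Gaussian twist-mismatch
#' factor \eqn{\sum_n \exp[-(2\pi^2 C/L)(n - L/h)^2]} summed over integer
#' linking offsets, which is maximal when the contour holds an integer
#' number of helical turns and suppresses J_thetaphi by orders of magnitude
#' at half-integer turns.  Valid for `0.1 <= L/Lp <= 2`.
#'
#' @param model A [wlc_model()] (supplies Lp, torsional persistence C, and
#'   the helical repeat).
#' @param length_bp Chain length in bp (default: the model's length).
#' @return One-row tibble: `length_bp`, `j_aligned_M`, `j_unaligned_M`,
#'   `twist_factor`, `turns`, `method = "closed_form"`.
#' @export
jfactor_aligned <- function(model, length_bp = NULL) {
  stopifnot(inherits(model, "wlc_model"))
  length_bp <- length_bp %||% model$length_bp
  L <- length_bp * model$rise
  l <- L / model$persistence_length
  if (l < 0.1 || l > 2) {
    stop_param("aligned closed form valid for 0.1 <= L/Lp <= 2; got L/Lp = ",
               signif(l, 3))
  }
  turns <- length_bp / model$helical_repeat
  n <- seq(floor(turns) - 2, ceiling(turns) + 2)
  tw <- sum(exp(-(2 * pi^2 * model$torsional_persistence / L) *
                  (n - turns)^2))
  per_lp3 <- 1e-24 / (model$persistence_length^3 * 1e-24)  # -> per nm^3
  to_molar <- 1 / (model$persistence_length^3 * 1e-24 * .AVOGADRO)
  tibble::tibble(
    length_bp = length_bp,
    j_aligned_M = .sy_ring(l) * tw * to_molar,
    j_unaligned_M = .sy_teardrop(l) * to_molar,
    twist_factor = tw,
    turns = turns,
    method = "closed_form"
  )
}

#' Free-energy cost of helical alignment
#'
#' \eqn{\Delta G_{\theta\phi} = -k_BT \ln(J_{\theta\phi} / J)}: the free
#' energy a teardrop loop must pay to align its ends axially and torsionally
#' for nick closing.  Large for half-integer-turn loops, smaller (comparable
#' to the base-stacking energy) for integer-turn loops.
#'
#' @param j_aligned,j_unaligned J factors in mol/L (both > 0).
#' @return Free energy in kT.
#' @export
alignment_free_energy <- function(j_aligned, j_unaligned) {
  if (any(!is.finite(j_aligned)) || any(!is.finite(j_unaligned)) ||
      any(j_aligned <= 0) || any(j_unaligned <= 0)) {
    stop_param("J factors must be positive and finite")
  }
  -log(j_aligned / j_unaligned)
}

#' Compare alignment cost to base-stacking energy
#'
#' Whether nick stacking can pay for helical alignment: a smooth (stacked)
#' loop is thermodynamically accessible when the alignment cost does not
#' exceed the magnitude of the stacking free energy at the nicks.
#'
#' @param dg_align Alignment free energy in kT (>= 0 in practice).
#' @param dg_stack Stacking free energy per nick in kT (signed; stabilizing
#'   stacking is negative).
#' @param margin_kT Band around equality flagged as marginal (default 1 kT).
#' @return One-row tibble: `dg_align_kT`, `dg_stack_kT`, `difference_kT`
#'   (`dg_align - |dg_stack|`), `stacking_compensated`, `marginal`.
#' @export
compare_to_stacking <- function(dg_align, dg_stack, margin_kT = 1) {
  diff <- dg_align - abs(dg_stack)
  tibble::tibble(
    dg_align_kT = dg_align,
    dg_stack_kT = dg_stack,
    difference_kT = diff,
    stacking_compensated = diff <= 0,
    marginal = abs(diff) <= margin_kT
  )
}

#' Experimental J factor from rates
#'
#' \eqn{J_{exp} = k_{loop} / k_{on}}: the looping rate divided by the
#' bimolecular annealing rate constant of the sticky ends cancels the
#' annealing step and leaves an effective molar concentration.
#'
#' @param k_loop Looping rate in 1/s.
#' @param k_on Annealing rate constant in 1/(M s).
#' @return J_exp in mol/L.
#' @export
j_exp <- function(k_loop, k_on) {
  if (any(!is.finite(k_loop)) || any(!is.finite(k_on)) ||
      any(k_loop <= 0) || any(k_on <= 0)) {
    stop_param("`k_loop` and `k_on` must be positive and finite")
  }
  k_loop / k_on
}

#' Lengths holding a whole number of helical turns
#'
#' Integer multiples of the helical repeat within a length range; loops at
#' these lengths need no torsional realignment for nick closing (twist
#' mismatch zero), so the decyclization rate is slowest there.
#'
#' @param helical_repeat Helical repeat in bp (default 10.5).
#' @param range Length range in bp (default `c(90, 140)`).
#' @return Numeric vector of lengths in bp.
#' @export
integer_turn_lengths <- function(helical_repeat = 10.5, range = c(90, 140)) {
  check_positive(helical_repeat, "helical_repeat")
  n <- seq(ceiling(range[1] / helical_repeat),
           floor(range[2] / helical_repeat))
  n * helical_repeat
}

#' Sample wormlike chains constrained to a short end-to-end distance
#'
#' Metropolis Monte Carlo for the looped sub-ensemble: discrete wormlike
#' chains conditioned on `|r| <= r_max`, which direct sampling cannot reach
#' for chains much shorter than their persistence length (the unconstrained
#' probability of such a tight closure is astronomically small).  Tail-pivot
#' moves with Gaussian rotation angles; Metropolis acceptance in the bending
#' energy with a hard wall on the end separation; started from a planar
#' ring.
#'
#' @param model A [wlc_model()].
#' @param r_max End-to-end cap in nm.
#' @param n_samples Number of (thinned) samples to keep.
#' @param seed Integer seed.
#' @param burn Burn-in moves (default `200 * n_segments`).
#' @param thin Moves between kept samples (default `n_segments`).
#' @param step_sd Pivot rotation angle scale in radians (default 0.3).
#' @return A `wlc_ensemble` whose chains all satisfy the constraint; the
#'   constraint radius is stored in the `r_max` element.
#' @export
wlc_sample_constrained <- function(model, r_max, n_samples, seed = 1,
                                   burn = NULL, thin = NULL, step_sd = 0.3) {
  stopifnot(inherits(model, "wlc_model"))
  check_positive(r_max, "r_max")
  if (n_samples < 1) stop_param("`n_samples` must be >= 1")
  set.seed(as.integer(seed))
  burn <- burn %||% (200L * model$n_segments)
  thin <- thin %||% model$n_segments
  kappa <- model$persistence_length / model$segment_length
  m <- .wlc_sample_constrained_cpp(as.integer(n_samples), model$n_segments,
                                   model$segment_length, kappa, r_max,
                                   as.integer(burn), as.integer(thin),
                                   step_sd)
  structure(
    list(r = m[, 1:3, drop = FALSE],
         t_first = matrix(rep(c(0, 0, 1), each = nrow(m)), ncol = 3),
         t_last = m[, 4:6, drop = FALSE],
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         r_max = r_max, model = model),
    class = "wlc_ensemble"
  )
}
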
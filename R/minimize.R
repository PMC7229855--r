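#' Circular-arc initial conformation for loop minimization
#'
#' Distributes a total bend of `closure_fraction * 2*pi` uniformly over all
#' steps, bending about a fixed lab direction so the arc is planar, with the
#' bending plane set by the register angle `theta` (the rotational direction,
#' about the helical axis of the first base pair, in which the molecule
#' bends).  Intrinsic twist is kept at its ground-state value; the bend is
#' carried by tilt/roll components counter-rotated by the accumulated twist.
#' At `theta = 0` with zero intrinsic twist all bend appears as roll.
#'
#' @param params A [dna_params()] object.
#' @param register_angle Bending direction Theta in radians, in `[0, 2*pi)`.
#' @param closure_fraction Fraction of a full circle to close (0, 1]; 1 gives
#'   a closed circular arc.
#' @return Tibble of step angles (`tilt`, `roll`, `twist`).
#' @export
init_circular_arc <- function(params, register_angle = 0,
                              closure_fraction = 0.9) {
  stopifnot(inherits(params, "dna_params"))
  if (!is.finite(closure_fraction) || closure_fraction <= 0 ||
      closure_fraction > 1) {
    stop_param("`closure_fraction` must be in (0, 1]")
  }
  ns <- params$n_bp - 1L
  kappa <- closure_fraction * 2 * pi / ns
  twist0 <- params$steps$twist0
  # Build the arc triads directly: junction rotation about a fixed lab axis
  # b(theta), then intrinsic twist about the local helical axis; extract the
  # step angles in the package's rotation convention.
  bhat <- c(-sin(register_angle), cos(register_angle), 0)
  rot_axis <- function(a, ang) {
    c1 <- cos(ang); s1 <- sin(ang); C <- 1 - c1
    matrix(c(
      c1 + a[1]^2 * C, a[1] * a[2] * C - a[3] * s1, a[1] * a[3] * C + a[2] * s1,
      a[2] * a[1] * C + a[3] * s1, c1 + a[2]^2 * C, a[2] * a[3] * C - a[1] * s1,
      a[3] * a[1] * C - a[2] * s1, a[3] * a[2] * C + a[1] * s1, c1 + a[3]^2 * C
    ), 3, 3, byrow = TRUE)
  }
  Rb <- rot_axis(bhat, kappa)
  triads <- array(0, c(3, 3, params$n_bp))
  Tcur <- diag(3)
  triads[, , 1] <- Tcur
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  for (i in seq_len(ns)) {
    Tcur <- Rb %*% Tcur %*% rz(twist0[i])
    triads[, , i + 1] <- Tcur
  }
  m <- .extract_angles_cpp(triads)
  tibble::tibble(tilt = m[, 1], roll = m[, 2], twist = m[, 3])
}

.default_kc_schedule <- c(10, 100, 1000, 1e4)

.loop_fit <- function(res, params, register_angle, d_target, nicked) {
  structure(
    list(angles = tibble::tibble(tilt = res$angles[, 1],
                                 roll = res$angles[, 2],
                                 twist = res$angles[, 3]),
         energy_kT = res$energy_kT,
         distance_nm = res$distance_nm,
         constraint_violation_nm = res$constraint_violation_nm,
         grad_norm = res$grad_norm,
         iterations = res$iterations,
         converged = res$converged,
         n_objective_increase = res$n_objective_increase,
         register_angle = register_angle,
         constraint_target_nm = d_target,
         nicked = nicked,
         params = params),
    class = "loop_fit"
  )
}

#' @export
print.loop_fit <- function(x, ...) {
  cat("<loop_fit> ", x$params$n_bp, " bp",
      if (x$nicked) " (nicked-circle constraint)" else "",
      ": E_bend = ", signif(x$energy_kT, 5), " kT, end distance ",
      signif(x$distance_nm, 4), " nm (target ", x$constraint_target_nm,
      "), ", if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
tidy.loop_fit <- function(x, ...) {
  dplyr::mutate(x$angles, step = dplyr::row_number(), .before = 1)
}

#' @export
glance.loop_fit <- function(x, ...) {
  tibble::tibble(
    n_bp = x$params$n_bp,
    register_angle = x$register_angle,
    energy_kT = x$energy_kT,
    distance_nm = x$distance_nm,
    constraint_violation_nm = x$constraint_violation_nm,
    grad_norm = x$grad_norm,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Minimum-energy loop conformation at a fixed register angle
#'
#' Gradient-descent minimization (with backtracking line search) of the rigid
#' base-pair deformation energy plus a stiff harmonic potential
#' \eqn{(k_c/2)(d - d_{target})^2} on the distance `d` between the terminal
#' sticky-end attachment points (strand a at the last base pair, strand b at
#' the first).  The constraint stiffness is ramped geometrically (default 10
#' to 1e4 kT/nm^2) until the residual violation is at most 0.05 nm.  The
#' initial conformation is a planar circular arc in the requested bending
#' direction; the returned energy is the elastic term only (the penalty is
#' excluded).  Deterministic for fixed inputs.
#'
#' @param params A [dna_params()] object.
#' @param register_angle Bending direction Theta in radians.
#' @param constraint_target Desired end distance in nm (default 1, a
#'   sticky-end contact distance).
#' @param closure_fraction Initial-arc closure passed to
#'   [init_circular_arc()].
#' @param kc_schedule Increasing constraint stiffnesses in kT/nm^2.
#' @param grad_tol Convergence threshold on the gradient norm (kT/rad).
#' @param max_iter Iteration cap per stiffness stage.
#' @param step_max Cap on the largest per-angle move (radians) of a single
#'   polish iteration; bounds how far one step can jump so the polish stays
#'   inside the basin selected by the flow phase.
#' @param flow_iters Budget of initial plain gradient-descent iterations
#'   (small bounded steps approximating the continuous gradient flow, run
#'   until the gradient norm falls to 0.5 kT/rad); this settles each
#'   register angle into its own basin instead of hopping to the global
#'   one.
#' @param flow_ftol Energy-plateau stopping rule for the flow phase: stop
#'   once 50 consecutive iterations each lower the objective by less than
#'   this amount (kT).  0 disables the rule.  Used by the quasi-static
#'   landscape mode, where the slow residual drift is the soft
#'   register-rotation mode that the procedure deliberately freezes.
#' @param polish Run the quasi-Newton polish after the flow phase?  `TRUE`
#'   (default) fully relaxes the conformation -- appropriate for single
#'   minimum-energy shapes; for an isotropic chain the fully relaxed energy
#'   no longer depends on the starting register angle because rotating the
#'   bending direction is a soft mode.  `FALSE` stops at the quasi-static
#'   gradient-flow optimum at `grad_tol` (use a looser tolerance, e.g. 0.3),
#'   which retains the register-angle resolution needed for
#'   E_bend(Theta, L) landscapes.
#' @param init_angles Optional explicit initial step angles (tibble or
#'   matrix), overriding the circular arc.
#' @return A `loop_fit` object (see [glance()] / [tidy()] methods); never
#'   silently reports convergence when the tolerance was not met.
#' @export
minimize_loop <- function(params, register_angle = 0, constraint_target = 1,
                          closure_fraction = 0.9,
                          kc_schedule = .default_kc_schedule,
                          grad_tol = 0.02, max_iter = 4000,
                          step_max = 0.05, flow_iters = 2000,
                          flow_ftol = 0, polish = TRUE,
                          init_angles = NULL) {
  stopifnot(inherits(params, "dna_params"))
  if (!is.finite(constraint_target) || constraint_target < 0) {
    stop_param("`constraint_target` must be a non-negative distance in nm")
  }
  if (any(!is.finite(kc_schedule)) || any(kc_schedule <= 0)) {
    stop_param("`kc_schedule` must be positive")
  }
  init <- init_angles %||% init_circular_arc(params, register_angle,
                                             closure_fraction)
  xinit <- .angles_matrix(init, params)
  s <- params$steps
  res <- .minimize_loop_cpp(
    xinit, cbind(s$tilt0, s$roll0, s$twist0),
    cbind(s$a_tilt, s$a_roll, s$a_twist),
    params$rise, params$helix_radius * cos(params$corner_angle),
    params$helix_radius * sin(params$corner_angle), constraint_target, 0L,
    kc_schedule, grad_tol, as.integer(max_iter), 1e-4, step_max,
    as.integer(flow_iters), flow_ftol, as.integer(polish), 0L, 0, 0
  )
  .loop_fit(res, params, register_angle, constraint_target, nicked = FALSE)
}

#' Minimum-energy nicked-circle conformation
#'
#' Variant of [minimize_loop()] for a loop closed through one continuous
#' strand: the two ends of the *same* (un-nicked) backbone strand are pulled
#' to zero distance, and the first and last `excluded_bp` base pairs repel
#' each other through a soft half-harmonic contact penalty so the duplex ends
#' cannot interpenetrate.  Integer-turn loops relax to a nearly planar
#' teardrop; half-integer-turn loops are forced out of plane.
#'
#' @inheritParams minimize_loop
#' @param constraint_target End-distance target in nm (default 0).
#' @param excluded_bp Number of base pairs at each end carrying the
#'   excluded-volume penalty (default 10).
#' @param contact_radius_nm Contact radius of the repulsion in nm (default 2,
#'   one helix diameter).
#' @param contact_stiffness Penalty stiffness in kT/nm^2 (default 50).
#' @return A `loop_fit` object with `nicked = TRUE`.
#' @export
minimize_nicked_loop <- function(params, register_angle = 0,
                                 constraint_target = 0,
                                 closure_fraction = 0.95,
                                 excluded_bp = 10, contact_radius_nm = 2,
                                 contact_stiffness = 50,
                                 kc_schedule = .default_kc_schedule,
                                 grad_tol = 0.02, max_iter = 4000,
                                 step_max = 0.05, flow_iters = 2000,
                                 flow_ftol = 0, polish = TRUE,
                                 init_angles = NULL) {
  stopifnot(inherits(params, "dna_params"))
  init <- init_angles %||% init_circular_arc(params, register_angle,
                                             closure_fraction)
  xinit <- .angles_matrix(init, params)
  s <- params$steps
  res <- .minimize_loop_cpp(
    xinit, cbind(s$tilt0, s$roll0, s$twist0),
    cbind(s$a_tilt, s$a_roll, s$a_twist),
    params$rise, params$helix_radius * cos(params$corner_angle),
    params$helix_radius * sin(params$corner_angle), constraint_target, 1L,
    kc_schedule, grad_tol, as.integer(max_iter), 1e-4, step_max,
    as.integer(flow_iters), flow_ftol, as.integer(polish),
    as.integer(excluded_bp), contact_radius_nm, contact_stiffness
  )
  .loop_fit(res, params, register_angle, constraint_target, nicked = TRUE)
}

#' Conformation of a loop fit
#'
#' @param fit A `loop_fit` object.
#' @return The minimized `dna_conformation`.
#' @export
loop_conformation <- function(fit) {
  stopifnot(inherits(fit, "loop_fit"))
  build_conformation(fit$angles, fit$params)
}

#' Loop energy landscape over lengths and register angles
#'
#' Runs [minimize_loop()] for every combination of chain length and register
#' angle and collects the minimized elastic energies E_bend(Theta, L).  The
#' geometric and stiffness constants are taken from `base_params`; a chain of
#' the right length is built for each L.  With `curvature = TRUE`, phased
#' intrinsic curvature over a central window of two helical turns is tuned
#' per length (via [tune_curvature()]) so the relaxed molecule's axis
#' deflects by `deflection_nm` end to end.
#'
#' @param base_params A [dna_params()] object supplying stiffnesses and
#'   geometry (its `n_bp` is ignored).
#' @param lengths Integer vector of chain lengths in bp (each >= 30).
#' @param thetas Register angles in radians, or a single integer giving the
#'   number of equally spaced angles in `[0, 2*pi)` (default 24).
#' @param curvature Add tuned central intrinsic curvature per length?
#' @param deflection_nm Curvature tuning target (default one helix width).
#' @param ... Passed on to [minimize_loop()]; the landscape defaults to the
#'   register-resolved quasi-static descent (`polish = FALSE`,
#'   `grad_tol = 0.5`, `flow_iters = 15000`, `kc_schedule = 1000`,
#'   `flow_ftol = 1e-6`)
#'   so that E_bend(Theta, L) keeps its dependence on the bending
#'   direction.
#' @return A tibble of class `energy_landscape` with columns `length_bp`,
#'   `theta_rad`, `energy_kT`, `converged`, `iterations`.
#' @export
energy_landscape <- function(base_params, lengths, thetas = 24,
                             curvature = FALSE, deflection_nm = NULL, ...) {
  dots <- rlang::list2(...)
  if (is.null(dots$polish)) dots$polish <- FALSE
  if (is.null(dots$grad_tol)) dots$grad_tol <- 0.5
  if (is.null(dots$flow_iters)) dots$flow_iters <- 15000
  if (is.null(dots$kc_schedule)) dots$kc_schedule <- 1000
  if (is.null(dots$flow_ftol)) dots$flow_ftol <- 1e-6
  stopifnot(inherits(base_params, "dna_params"))
  if (any(lengths < 30)) stop_param("all `lengths` must be >= 30 bp")
  if (length(thetas) == 1 && thetas == round(thetas) && thetas >= 1) {
    thetas <- seq(0, 2 * pi, length.out = thetas + 1)[seq_len(thetas)]
  }
  if (any(thetas < 0 | thetas >= 2 * pi)) {
    stop_param("`thetas` must lie in [0, 2*pi)")
  }
  rows <- purrr::map(as.integer(lengths), function(L) {
    p <- dna_params(
      L, persistence_length = base_params$persistence_length,
      torsional_persistence = base_params$torsional_persistence,
      helical_repeat = base_params$helical_repeat, rise = base_params$rise,
      helix_radius = base_params$helix_radius,
      corner_angle = base_params$corner_angle
    )
    if (curvature) p <- tune_curvature(p, deflection_nm = deflection_nm)
    purrr::map(thetas, function(th) {
      fit <- rlang::exec(minimize_loop, p, register_angle = th, !!!dots)
      tibble::tibble(length_bp = L, theta_rad = th,
                     energy_kT = fit$energy_kT, converged = fit$converged,
                     iterations = fit$iterations)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("energy_landscape", class(out))
  attr(out, "curvature") <- curvature
  out
}

#' Relative looping rate versus length
#'
#' Transition-state estimate of the looping rate: for each length,
#' \eqn{k_{loop}(L) \propto \sum_\Theta \exp(-E_{bend}(\Theta, L)/k_BT)},
#' summed over the full register-angle grid or, to mimic surface hindrance
#' of bending directions, over a contiguous half interval of register angles.
#' Values are relative (arbitrary units); only ratios across lengths are
#' meaningful.
#'
#' @param landscape An [energy_landscape()] tibble.
#' @param register_interval `"full"` or `"half"`; the half interval keeps
#'   angles in `[half_start, half_start + pi)`.
#' @param half_start Start of the half interval in radians (default 0).
#' @return A tibble of class `rate_profile` with columns `length_bp`,
#'   `k_rel`.
#' @export
looping_rate_profile <- function(landscape,
                                 register_interval = c("full", "half"),
                                 half_start = 0) {
  register_interval <- match.arg(register_interval)
  stopifnot(all(c("length_bp", "theta_rad", "energy_kT") %in%
                  names(landscape)))
  d <- landscape
  if (register_interval == "half") {
    keep <- ((d$theta_rad - half_start) %% (2 * pi)) < pi
    d <- d[keep, ]
  }
  if (nrow(d) == 0) stop_param("empty register-angle selection")
  out <- d |>
    dplyr::group_by(.data$length_bp) |>
    dplyr::summarise(k_rel = sum(exp(-.data$energy_kT)), .groups = "drop")
  if (any(!is.finite(out$k_rel)) || any(out$k_rel <= 0)) {
    stop_param("non-finite Boltzmann weights in landscape")
  }
  class(out) <- c("rate_profile", class(out))
  attr(out, "register_interval") <- register_interval
  out
}

#' Dominant oscillation period of a length profile
#'
#' Quantifies helical-phasing oscillations in a rate or energy profile:
#' detrends the (log-)values with a quadratic fit in length, then evaluates a
#' least-squares periodogram (sine + cosine regression) on a fine period grid
#' between `period_range[1]` and `period_range[2]` bp and reports the period
#' of maximum power.  Significance of the peak is assessed by permutation of
#' the detrended residuals.
#'
#' For an [energy_landscape()], the default (`landscape_stat = "register"`)
#' analyses the length dependence of E_bend at each register angle
#' separately and averages the per-angle periodograms: the minimized loop
#' energy at a fixed bending direction is the quantity whose length
#' oscillation reveals the helical phasing (one helical turn for a straight
#' molecule, two turns when intrinsic curvature rotates relative to the
#' loop).  `landscape_stat = "min"` instead analyses the per-length minima
#' over all register angles.
#'
#' @param x A `rate_profile` tibble (columns `length_bp`, `k_rel`), an
#'   `energy_landscape`, or a data frame with columns `length_bp` and
#'   `value`.
#' @param period_range Periods to scan, bp (default `c(5, 40)`).
#' @param n_perm Number of permutations for the significance flag.
#' @param log_values Detrend log-transformed values?  Default `TRUE` for rate
#'   profiles, `FALSE` otherwise.
#' @param landscape_stat For `energy_landscape` input: `"register"`
#'   (per-angle E_bend series, averaged periodogram) or `"min"` (per-length
#'   minima over angles).
#' @return A list of class `oscillation_fit`: `period_bp`, `power` (R^2 of
#'   the sinusoid at the peak), `p_value`, `significant`, and the
#'   `periodogram` tibble.
#' @export
oscillation_period <- function(x, period_range = c(5, 40), n_perm = 200,
                               log_values = NULL,
                               landscape_stat = c("register", "min")) {
  landscape_stat <- match.arg(landscape_stat)
  series <- list()
  if (inherits(x, "rate_profile")) {
    series <- list(list(L = x$length_bp, v = x$k_rel))
    log_values <- log_values %||% TRUE
  } else if (inherits(x, "energy_landscape")) {
    log_values <- log_values %||% FALSE
    if (landscape_stat == "min") {
      m <- x |>
        dplyr::group_by(.data$length_bp) |>
        dplyr::summarise(value = min(.data$energy_kT), .groups = "drop")
      series <- list(list(L = m$length_bp, v = m$value))
    } else {
      series <- lapply(split(x, x$theta_rad), function(sl) {
        list(L = sl$length_bp, v = sl$energy_kT)
      })
    }
  } else if (is.data.frame(x) && all(c("length_bp", "value") %in% names(x))) {
    series <- list(list(L = x$length_bp, v = x$value))
    log_values <- log_values %||% FALSE
  } else {
    stop_param("`x` must be a rate_profile, energy_landscape, or a data ",
               "frame with columns length_bp and value")
  }
  resids <- lapply(series, function(s) {
    ord <- order(s$L)
    L <- s$L[ord]
    v <- s$v[ord]
    dL <- diff(L)
    if (length(L) < 5 || max(abs(dL - dL[1])) > 1e-8) {
      stop_param("need >= 5 uniformly spaced lengths")
    }
    span <- diff(range(L))
    if (span < 2 * period_range[1]) {
      stop_param("length coverage too short for the requested periods")
    }
    y <- if (log_values) log(v) else v
    list(L = L, r = stats::residuals(stats::lm(y ~ L + I(L^2))))
  })
  L1 <- resids[[1]]$L
  periods <- seq(max(period_range[1], 2 * diff(L1)[1]),
                 min(period_range[2], diff(range(L1))), by = 0.1)
  power_one <- function(L, r) {
    vapply(periods, function(p) {
      X <- cbind(1, sin(2 * pi * L / p), cos(2 * pi * L / p))
      fit <- stats::lm.fit(X, r)
      1 - sum(fit$residuals^2) / sum((r - mean(r))^2)
    }, numeric(1))
  }
  mean_power <- function(rl) {
    Reduce(`+`, lapply(rl, function(s) power_one(s$L, s$r))) / length(rl)
  }
  pw <- mean_power(resids)
  best <- which.max(pw)
  obs <- pw[best]
  pval <- NA_real_
  if (n_perm > 0) {
    perm <- vapply(seq_len(n_perm), function(i) {
      max(mean_power(lapply(resids, function(s) {
        list(L = s$L, r = sample(s$r))
      })))
    }, numeric(1))
    pval <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  structure(
    list(period_bp = periods[best], power = obs, p_value = pval,
         significant = is.finite(pval) && pval < 0.05,
         n_series = length(resids),
         periodogram = tibble::tibble(period_bp = periods, power = pw)),
    class = "oscillation_fit"
  )
}

#' @export
print.oscillation_fit <- function(x, ...) {
  cat("<oscillation_fit> dominant period ", signif(x$period_bp, 4),
      " bp (R^2 = ", signif(x$power, 3), ", permutation p = ",
      signif(x$p_value, 3), if (x$significant) ", significant" else
        ", not significant", ")\n", sep = "")
  invisible(x)
}

#' @export
glance.oscillation_fit <- function(x, ...) {
  tibble::tibble(period_bp = x$period_bp, power = x$power,
                 p_value = x$p_value, significant = x$significant)
}
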
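#' Rigid base-pair step parameters
#'
#' Builds the per-step parameter set of the rigid base-pair elastic model: for
#' each of the `n_bp - 1` base-pair steps, ground-state (tilt, roll, twist)
#' angles and the associated quadratic stiffnesses, plus the geometric
#' constants of the double helix.  The deformation energy of a conformation
#' with step angles \eqn{x_i} is \eqn{E/k_BT = \sum_i \alpha_i (x_i -
#' x_{0,i})^2}, summed over the three angles of every step.
#'
#' Continuum bending and torsional persistence lengths are mapped onto
#' isotropic per-step stiffnesses \eqn{\alpha = L_p / (2\,\ell)} in
#' \eqn{k_BT/\mathrm{rad}^2}, with \eqn{\ell} the rise per step.  The
#' ground state is straight (tilt0 = roll0 = 0) with intrinsic twist
#' \eqn{2\pi/h} for helical repeat `h`.
#'
#' @param n_bp Number of base pairs (>= 3).
#' @param persistence_length Bending persistence length in nm (default 50).
#' @param torsional_persistence Torsional persistence length in nm
#'   (default 90).
#' @param helical_repeat Helical repeat in bp per turn (default 10.5).
#' @param rise Rise per base-pair step in nm (default 0.34).
#' @param helix_radius Helix radius in nm: distance of the backbone
#'   attachment corners from the helical axis (default 1).
#' @param corner_angle Angular offset (radians) of the backbone attachment
#'   corners from the base-pair long axis: the strands sit at the two corners
#'   of the longer side of the base-pair rectangle, at azimuths
#'   `corner_angle` and `pi - corner_angle`, so both are displaced toward the
#'   same short-axis side.  This encodes the groove asymmetry of the double
#'   helix (the angular gap between the strands is `pi - 2*corner_angle` on
#'   one side and `pi + 2*corner_angle` on the other).  Default `pi/6`
#'   (120/240 degree grooves); 0 places the strands diametrically.
#' @param step_table Optional data frame overriding the per-step parameters;
#'   must have `n_bp - 1` rows and columns `tilt0, roll0, twist0, a_tilt,
#'   a_roll, a_twist` (radians and kT/rad^2).
#'
#' @return An object of class `dna_params`: a list with `n_bp`, geometric
#'   constants, and `$steps`, a tibble with one row per step.
#' @examples
#' p <- dna_params(105)
#' p$steps
#' @export
dna_params <- function(n_bp, persistence_length = 50,
                       torsional_persistence = 90, helical_repeat = 10.5,
                       rise = 0.34, helix_radius = 1, corner_angle = pi / 6,
                       step_table = NULL) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) ||
      n_bp < 3 || n_bp != round(n_bp)) {
    stop_param("`n_bp` must be a whole number >= 3")
  }
  n_bp <- as.integer(n_bp)
  check_positive(persistence_length, "persistence_length")
  check_positive(torsional_persistence, "torsional_persistence")
  check_positive(helical_repeat, "helical_repeat")
  check_positive(rise, "rise")
  if (!is.numeric(helix_radius) || !is.finite(helix_radius) || helix_radius < 0) {
    stop_param("`helix_radius` must be a finite non-negative number")
  }
  if (!is.finite(corner_angle) || corner_angle < 0 || corner_angle >= pi / 2) {
    stop_param("`corner_angle` must lie in [0, pi/2)")
  }
  ns <- n_bp - 1L
  if (is.null(step_table)) {
    a_bend <- persistence_length / (2 * rise)
    a_twist <- torsional_persistence / (2 * rise)
    steps <- tibble::tibble(
      tilt0 = rep(0, ns), roll0 = rep(0, ns),
      twist0 = rep(2 * pi / helical_repeat, ns),
      a_tilt = rep(a_bend, ns), a_roll = rep(a_bend, ns),
      a_twist = rep(a_twist, ns)
    )
  } else {
    need <- c("tilt0", "roll0", "twist0", "a_tilt", "a_roll", "a_twist")
    if (!all(need %in% names(step_table))) {
      stop_param("`step_table` must have columns ", paste(need, collapse = ", "))
    }
    if (nrow(step_table) != ns) {
      stop_param("`step_table` must have n_bp - 1 = ", ns, " rows")
    }
    steps <- tibble::as_tibble(step_table)[need]
    if (!all(vapply(steps, function(x) all(is.finite(x)), logical(1)))) {
      stop_param("`step_table` entries must be finite")
    }
    if (any(steps$a_tilt <= 0 | steps$a_roll <= 0 | steps$a_twist <= 0)) {
      stop_param("all stiffnesses in `step_table` must be > 0")
    }
  }
  structure(
    list(n_bp = n_bp, steps = steps, rise = rise,
         helical_repeat = helical_repeat, helix_radius = helix_radius,
         corner_angle = corner_angle,
         persistence_length = persistence_length,
         torsional_persistence = torsional_persistence),
    class = "dna_params"
  )
}

#' @export
print.dna_params <- function(x, ...) {
  cat("<dna_params> ", x$n_bp, " bp (", x$n_bp - 1L, " steps)\n", sep = "")
  cat("  rise ", x$rise, " nm, helical repeat ", x$helical_repeat,
      " bp, helix radius ", x$helix_radius, " nm\n", sep = "")
  cat("  mean bend stiffness ",
      signif(mean(c(x$steps$a_tilt, x$steps$a_roll)), 5),
      " kT/rad^2, mean twist stiffness ", signif(mean(x$steps$a_twist), 5),
      " kT/rad^2\n", sep = "")
  invisible(x)
}

#' Ground-state step angles of a parameter set
#'
#' @param params A [dna_params()] object.
#' @return A tibble with columns `tilt`, `roll`, `twist` (radians), one row
#'   per base-pair step.
#' @export
ground_state_angles <- function(params) {
  stopifnot(inherits(params, "dna_params"))
  tibble::tibble(tilt = params$steps$tilt0, roll = params$steps$roll0,
                 twist = params$steps$twist0)
}

.angles_matrix <- function(angles, params = NULL) {
  if (is.matrix(angles)) {
    m <- angles
  } else if (is.data.frame(angles)) {
    if (!all(c("tilt", "roll", "twist") %in% names(angles))) {
      stop_param("`angles` must have columns tilt, roll, twist")
    }
    m <- cbind(angles$tilt, angles$roll, angles$twist)
  } else {
    stop_param("`angles` must be a data frame or matrix of step angles")
  }
  if (!all(is.finite(m))) stop_param("step angles must be finite")
  if (!is.null(params) && nrow(m) != params$n_bp - 1L) {
    stop_param("`angles` has ", nrow(m), " steps but `params` describes ",
               params$n_bp - 1L)
  }
  m
}

#' Add intrinsic curvature to a parameter set
#'
#' Increments the ground-state bend of the steps inside `window` so that the
#' relaxed molecule is curved.  With `phase = "helical"` (default) the bias is
#' distributed between roll0 and tilt0, counter-rotated by the accumulated
#' intrinsic twist, so that successive biased steps bend about a common lab
#' direction and the window produces a coherent planar bend (phased curvature,
#' as in A-tract DNA).  With `phase = "constant"` the bias is added to roll0
#' only; note that with ~34 degrees of twist per step a constant roll bias
#' largely cancels over a full helical turn.
#'
#' The energy zero point moves with the ground state: the curved molecule's
#' relaxed conformation still has zero deformation energy.
#'
#' @param params A [dna_params()] object.
#' @param window Integer vector of step indices (within `1:(n_bp-1)`) to bias,
#'   e.g. a central window of two helical turns.
#' @param per_step_roll_bias Bend bias per step in radians.
#' @param phase `"helical"` or `"constant"` (see Details).
#' @return A modified `dna_params` object.
#' @seealso [tune_curvature()] to choose the bias from a target end-to-end
#'   axis deflection, [axis_deflection()] to measure it.
#' @export
add_intrinsic_curvature <- function(params, window, per_step_roll_bias,
                                    phase = c("helical", "constant")) {
  stopifnot(inherits(params, "dna_params"))
  phase <- match.arg(phase)
  ns <- params$n_bp - 1L
  window <- as.integer(window)
  if (length(window) == 0 || any(window < 1L | window > ns)) {
    stop_param("`window` must lie within 1..", ns)
  }
  if (!is.finite(per_step_roll_bias)) stop_param("bias must be finite")
  out <- params
  if (phase == "constant") {
    out$steps$roll0[window] <- out$steps$roll0[window] + per_step_roll_bias
  } else {
    # accumulated intrinsic twist at each junction, measured from the first
    # biased step so the bend direction is coherent in the lab frame
    phi <- cumsum(c(0, params$steps$twist0))[window] -
      cumsum(c(0, params$steps$twist0))[window[1]]
    out$steps$roll0[window] <- out$steps$roll0[window] +
      per_step_roll_bias * cos(phi)
    out$steps$tilt0[window] <- out$steps$tilt0[window] +
      per_step_roll_bias * sin(phi)
  }
  out
}

#' End-to-end axis deflection of the relaxed molecule
#'
#' Builds the ground-state conformation and returns the perpendicular
#' distance (nm) of the last base-pair origin from the straight line through
#' the first origin along the initial helical axis.  For a straight molecule
#' this is zero; curvature tuned so this equals one helix width (2 x
#' helix_radius) reproduces the heuristic magnitude at which intrinsic
#' curvature modulates looping.
#'
#' @param params A [dna_params()] object.
#' @return Deflection in nm.
#' @export
axis_deflection <- function(params) {
  conf <- build_conformation(ground_state_angles(params), params)
  o <- conf$origins
  t0 <- conf$triads[, 3, 1]
  rel <- o[nrow(o), ] - o[1, ]
  para <- sum(rel * t0)
  sqrt(max(0, sum(rel^2) - para^2))
}

#' Tune intrinsic curvature to a target axis deflection
#'
#' Chooses the per-step bend bias of a central window so that the relaxed
#' molecule's end-to-end axis deflection equals `deflection_nm` (default one
#' helix width, 2 x helix_radius).  Deflection is linear in the bias to a very
#' good approximation; one linear solve plus a secant refinement is used.
#'
#' @param params A [dna_params()] object (straight).
#' @param window Step indices to bias; default a central window of two helical
#'   turns.
#' @param deflection_nm Target deflection in nm; default `2 * helix_radius`.
#' @param phase Passed to [add_intrinsic_curvature()].
#' @return A curved `dna_params` object with attribute `"roll_bias"`.
#' @export
tune_curvature <- function(params, window = NULL, deflection_nm = NULL,
                           phase = "helical") {
  stopifnot(inherits(params, "dna_params"))
  ns <- params$n_bp - 1L
  if (is.null(window)) {
    w <- round(2 * params$helical_repeat)
    mid <- ns %/% 2L
    window <- seq(max(1L, mid - w %/% 2L), min(ns, mid + (w - w %/% 2L) - 1L))
  }
  deflection_nm <- deflection_nm %||% (2 * params$helix_radius)
  defl_at <- function(b) {
    axis_deflection(add_intrinsic_curvature(params, window, b, phase = phase))
  }
  b1 <- 0.01
  d1 <- defl_at(b1)
  if (d1 <= 0) stop_param("window produces no deflection; widen or rephase it")
  b2 <- b1 * deflection_nm / d1
  d2 <- defl_at(b2)
  # one secant refinement for the small nonlinearity
  if (abs(d2 - deflection_nm) > 1e-9 && abs(d2 - d1) > 1e-12) {
    b2 <- b2 + (deflection_nm - d2) * (b2 - b1) / (d2 - d1)
  }
  out <- add_intrinsic_curvature(params, window, b2, phase = phase)
  attr(out, "roll_bias") <- b2
  attr(out, "curvature_window") <- window
  out
}

#' Read a per-step or per-dinucleotide parameter table
#'
#' CSV with columns `tilt0, roll0, twist0, a_tilt, a_roll, a_twist`
#' (radians, kT/rad^2) and either one row per base-pair step (passed
#' directly to `dna_params(step_table = )`) or one row per dinucleotide
#' step type in a `step_type` column (e.g. "AA", "AC", ...; expanded to a
#' per-step table with [step_table_from_sequence()]).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_step_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Expand a dinucleotide parameter table over a sequence
#'
#' Maps a per-dinucleotide table of ground-state angles and stiffnesses onto
#' the `nchar(sequence) - 1` steps of a DNA sequence, producing the per-step
#' table accepted by [dna_params()].
#'
#' @param sequence Character scalar of A/C/G/T (length N).
#' @param dinucleotide_table Data frame with `step_type` (two-letter
#'   dinucleotide) plus `tilt0, roll0, twist0, a_tilt, a_roll, a_twist`.
#' @return Tibble with N - 1 rows in step order.
#' @export
step_table_from_sequence <- function(sequence, dinucleotide_table) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (!grepl("^[ACGT]+$", s) || nchar(s) < 2) {
    stop_param("`sequence` must be A/C/G/T of length >= 2")
  }
  steps <- substring(s, 1:(nchar(s) - 1), 2:nchar(s))
  idx <- match(steps, toupper(dinucleotide_table$step_type))
  if (anyNA(idx)) {
    stop_param("dinucleotide table is missing step types: ",
               paste(unique(steps[is.na(idx)]), collapse = ", "))
  }
  need <- c("tilt0", "roll0", "twist0", "a_tilt", "a_roll", "a_twist")
  tibble::as_tibble(dinucleotide_table[idx, need])
}
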
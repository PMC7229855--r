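#' Deformation energy of a set of step angles
#'
#' Quadratic rigid base-pair energy \eqn{E/k_BT = \sum_i \alpha_i (x_i -
#' x_{0,i})^2}, summed over the tilt, roll and twist angles of all
#' `n_bp - 1` steps.  Zero if and only if the angles equal the ground state.
#'
#' @param angles Tibble (columns `tilt`, `roll`, `twist`, radians) or
#'   `(n_bp-1) x 3` matrix of step angles.
#' @param params A [dna_params()] object with the same number of steps.
#' @return Energy in units of kT (non-negative scalar).
#' @export
bend_energy <- function(angles, params) {
  stopifnot(inherits(params, "dna_params"))
  m <- .angles_matrix(angles, params)
  s <- params$steps
  sum(s$a_tilt * (m[, 1] - s$tilt0)^2) +
    sum(s$a_roll * (m[, 2] - s$roll0)^2) +
    sum(s$a_twist * (m[, 3] - s$twist0)^2)
}

#' Reconstruct a 3-D chain conformation from step angles
#'
#' Propagates base-pair triads step by step (twist about the local helical
#' axis, then roll about the local short axis, then tilt about the local long
#' axis), advances origins by the rise along each step's helical axis, and
#' places backbone attachment points at the two corners of the longer side
#' of the base-pair rectangle (strand a at azimuth `corner_angle` from the
#' long axis, strand b mirrored across the short axis), at distance
#' `helix_radius` from the origin.
#'
#' @inheritParams bend_energy
#' @return A `dna_conformation` object: list with `origins`, `backbone_a`,
#'   `backbone_b` (`n_bp x 3` matrices, nm), `triads` (`3 x 3 x n_bp` array,
#'   columns = long, short, helical axes) and the generating `params`.
#' @examples
#' p <- dna_params(105)
#' conf <- build_conformation(ground_state_angles(p), p)
#' backbone_end_distance(conf)
#' @export
build_conformation <- function(angles, params) {
  stopifnot(inherits(params, "dna_params"))
  m <- .angles_matrix(angles, params)
  res <- .build_chain_cpp(m, params$rise,
                          params$helix_radius * cos(params$corner_angle),
                          params$helix_radius * sin(params$corner_angle))
  structure(
    list(origins = res$origins, triads = res$triads,
         backbone_a = res$backbone_a, backbone_b = res$backbone_b,
         params = params),
    class = "dna_conformation"
  )
}

#' @export
print.dna_conformation <- function(x, ...) {
  n <- nrow(x$origins)
  ee <- sqrt(sum((x$origins[n, ] - x$origins[1, ])^2))
  cat("<dna_conformation> ", n, " bp, axis end-to-end ", signif(ee, 5),
      " nm\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.dna_conformation <- function(x, ...) {
  n <- nrow(x$origins)
  tibble::tibble(
    bp = seq_len(n),
    x_nm = x$origins[, 1], y_nm = x$origins[, 2], z_nm = x$origins[, 3],
    bb_a_x_nm = x$backbone_a[, 1], bb_a_y_nm = x$backbone_a[, 2],
    bb_a_z_nm = x$backbone_a[, 3],
    bb_b_x_nm = x$backbone_b[, 1], bb_b_y_nm = x$backbone_b[, 2],
    bb_b_z_nm = x$backbone_b[, 3]
  )
}

#' Recover step angles from a conformation
#'
#' Inverts the rotation convention of [build_conformation()]; round-trips to
#' high precision and is used to verify reconstruction consistency.
#'
#' @param conf A `dna_conformation`.
#' @return Tibble with columns `tilt`, `roll`, `twist` (radians).
#' @export
extract_step_angles <- function(conf) {
  stopifnot(inherits(conf, "dna_conformation"))
  m <- .extract_angles_cpp(conf$triads)
  tibble::tibble(tilt = m[, 1], roll = m[, 2], twist = m[, 3])
}

#' Distance between sticky-end attachment points
#'
#' Euclidean distance (nm) between the terminal backbone attachment point of
#' strand a at the last base pair and that of strand b at the first base pair
#' -- the pair of 5'-protruding single-strand ends whose annealing closes the
#' loop.  This is the coordinate constrained during loop minimization.
#'
#' @param conf A `dna_conformation`.
#' @return Distance in nm.
#' @export
backbone_end_distance <- function(conf) {
  stopifnot(inherits(conf, "dna_conformation"))
  n <- nrow(conf$backbone_a)
  sqrt(sum((conf$backbone_a[n, ] - conf$backbone_b[1, ])^2))
}

#' Planarity of a loop conformation
#'
#' Least-squares plane fit to the base-pair origins; returns the RMS
#' out-of-plane deviation divided by the RMS in-plane radius about the
#' centroid.  Zero for a perfectly planar loop; order one for a shape whose
#' out-of-plane extent rivals its radius.  Invariant under rigid-body motion.
#'
#' @param conf A `dna_conformation` with at least 4 base pairs.
#' @return Dimensionless ratio.
#' @export
planarity_metric <- function(conf) {
  stopifnot(inherits(conf, "dna_conformation"))
  o <- conf$origins
  if (nrow(o) < 4) stop_param("need at least 4 base pairs")
  oc <- sweep(o, 2, colMeans(o))
  sv <- svd(oc)
  d2 <- sv$d^2 / nrow(o)
  if (d2[2] < 1e-12 * max(d2[1], 1e-300)) {
    stop_param("degenerate (collinear) conformation: plane fit undefined")
  }
  sqrt(d2[3]) / sqrt(d2[1] + d2[2])
}
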
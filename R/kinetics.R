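#' Three-state cyclization rates
#'
#' Rate constants of the three-state model of sticky-end cyclization:
#' unlooped (U) <-> teardrop loop (T) <-> smooth loop (S).  `k1` is the
#' looping rate U -> T (bending + sticky-end annealing), `k2` the unlooping
#' rate T -> U, and `k3`/`k4` the nick-closing/nick-opening rates T <-> S
#' (stacking plus axial/torsional alignment).  T and S share the same high
#' FRET level and are indistinguishable in a trace.
#'
#' @param k1,k2,k3,k4 Rates in 1/s (all >= 0, finite).
#' @return A `three_state_rates` object.
#' @export
three_state_rates <- function(k1, k2, k3 = 0, k4 = 0) {
  r <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop_param("all rates must be finite and >= 0")
  }
  structure(as.list(r), class = "three_state_rates")
}

#' @export
print.three_state_rates <- function(x, ...) {
  cat("<three_state_rates> k1 = ", x$k1, ", k2 = ", x$k2, ", k3 = ", x$k3,
      ", k4 = ", x$k4, " s^-1\n", sep = "")
  invisible(x)
}

.STATES <- c("U", "T", "S")

#' Exact stochastic simulation of the three-state chain
#'
#' Continuous-time Markov chain U <->(k1, k2) T <->(k3, k4) S simulated by
#' the direct (Gillespie) method: exponential waiting times with the total
#' exit rate, categorical jumps.  A state with zero total exit rate is
#' absorbing and ends the trajectory.  Reproducible given `seed`.
#'
#' @param rates A [three_state_rates()] object.
#' @param initial Initial state, one of `"U"`, `"T"`, `"S"`, or
#'   `"looped_equilibrium"` to start from the stationary mixture of T and S
#'   given (k3, k4) (the unlooping-experiment start).
#' @param t_max Simulated time horizon in s.
#' @param n_traj Number of independent trajectories.
#' @param seed Integer seed.
#' @return A tibble of class `state_trajectory` with columns `trace_id`,
#'   `time_s` (entry time), `state`; every trajectory starts at time 0 and
#'   states change at every event.  `t_max` is stored as an attribute.
#' @export
simulate_kinetics <- function(rates, initial = "U", t_max = 300, n_traj = 1,
                              seed = 1) {
  stopifnot(inherits(rates, "three_state_rates"))
  check_positive(t_max, "t_max")
  set.seed(as.integer(seed))
  out <- .simulate_kinetics_noseed(rates, initial, t_max, n_traj)
  attr(out, "seed") <- as.integer(seed)
  out
}

# internal: simulate without touching the RNG seed (used by the trace
# generator, which manages one seed for the whole synthetic experiment)
.simulate_kinetics_noseed <- function(rates, initial, t_max, n_traj) {
  qmat <- rbind(
    U = c(0, rates$k1, 0),
    T = c(rates$k2, 0, rates$k3),
    S = c(0, rates$k4, 0)
  )
  init_state <- function() {
    if (identical(initial, "looped_equilibrium")) {
      if (rates$k4 <= 0 && rates$k3 > 0) return(3L)
      if (rates$k3 <= 0) return(2L)
      pT <- rates$k4 / (rates$k3 + rates$k4)
      if (runif(1) < pT) 2L else 3L
    } else {
      m <- match(initial, .STATES)
      if (is.na(m)) stop_param("`initial` must be U, T, S or looped_equilibrium")
      m
    }
  }
  sim_one <- function(id) {
    s <- init_state()
    times <- 0
    states <- s
    t <- 0
    repeat {
      exit <- sum(qmat[s, ])
      if (exit <= 0) break
      t <- t + rexp(1, exit)
      if (t >= t_max) break
      s <- sample.int(3L, 1L, prob = qmat[s, ])
      times <- c(times, t)
      states <- c(states, s)
    }
    tibble::tibble(trace_id = id, time_s = times, state = .STATES[states])
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_traj), sim_one))
  attr(out, "t_max") <- t_max
  class(out) <- c("state_trajectory", class(out))
  out
}

#' Equilibrium occupancies of the three states
#'
#' Detailed-balance stationary distribution: \eqn{\pi_T/\pi_U = k_1/k_2},
#' \eqn{\pi_S/\pi_T = k_3/k_4}, normalized.  Requires `k2 > 0` and `k4 > 0`
#' unless the corresponding forward rate is zero.
#'
#' @param rates A [three_state_rates()] object.
#' @return Named numeric vector of probabilities over U, T, S.
#' @export
equilibrium_occupancy <- function(rates) {
  stopifnot(inherits(rates, "three_state_rates"))
  if (rates$k2 <= 0 || (rates$k3 > 0 && rates$k4 <= 0)) {
    stop_param("no stationary distribution: k2 (and k4 when k3 > 0) must be > 0")
  }
  w <- c(U = 1, T = rates$k1 / rates$k2,
         S = if (rates$k3 > 0) rates$k1 / rates$k2 * rates$k3 / rates$k4 else 0)
  w / sum(w)
}

#' Effective decyclization rate of the looped pair
#'
#' In the fast nick-closing/opening limit the teardrop and smooth states
#' equilibrate before unlooping, and the looped pair decays at
#' \eqn{k_{unloop} = k_2\,k_4/(k_3 + k_4)}: unlooping happens only from the
#' teardrop state, occupied with probability \eqn{k_4/(k_3+k_4)}.  With
#' `k3 = 0` (half-integer loops stalled in the teardrop) this reduces to
#' `k2`.
#'
#' @param rates A [three_state_rates()] object with `k3 + k4 > 0`.
#' @return Rate in 1/s.
#' @export
effective_unloop_rate <- function(rates) {
  stopifnot(inherits(rates, "three_state_rates"))
  if (rates$k3 + rates$k4 <= 0) stop_param("k3 + k4 must be > 0")
  rates$k2 * rates$k4 / (rates$k3 + rates$k4)
}

#' First-passage times from state trajectories
#'
#' Time of first entry into the looped pair \{T, S\} (`direction = "loop"`)
#' or into U (`direction = "unloop"`), per trajectory; trajectories without a
#' qualifying event are censored at the horizon `t_max`.  T and S are not
#' distinguished, matching their identical FRET level.
#'
#' @param trajectories A [simulate_kinetics()] tibble.
#' @param direction `"loop"` or `"unloop"`.
#' @return A tibble of class `fpt_sample`: `trace_id`, `fpt_s`, `censored`
#'   (logical), `censor_time_s`.
#' @export
first_passage_times <- function(trajectories,
                                direction = c("loop", "unloop")) {
  direction <- match.arg(direction)
  t_max <- attr(trajectories, "t_max")
  target <- if (direction == "loop") c("T", "S") else "U"
  out <- trajectories |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::summarise(
      fpt_s = {
        hit <- which(.data$state %in% target & .data$time_s > 0)
        if (length(hit)) .data$time_s[hit[1]] else t_max
      },
      censored = !any(.data$state %in% target & .data$time_s > 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(censor_time_s = t_max)
  class(out) <- c("fpt_sample", class(out))
  out
}

#' Censoring-aware exponential rate estimate
#'
#' Maximum-likelihood exponential rate for first-passage samples with
#' right-censoring: \eqn{\hat k = d / \sum_i t_i} with `d` the number of
#' uncensored events and the sum over all observation times (events and
#' censoring times alike).  The 95% confidence interval is the profile
#' likelihood interval; the standard error \eqn{\hat k/\sqrt d} is also
#' reported.  For parity with survival-curve fitting practice, a least
#' squares fit of \eqn{e^{-kt}} to the Kaplan-Meier survival curve is
#' returned as `ls_rate`.  Setting `naive = TRUE` instead drops censored
#' observations entirely (`d / sum of uncensored times`), the biased
#' estimator that overestimates the rate when photobleaching competes with
#' the transition.
#'
#' @param samples An `fpt_sample` tibble (columns `fpt_s`, `censored`).
#' @param conf_level Confidence level (default 0.95).
#' @param naive Use the censoring-ignoring estimator as the point estimate?
#' @return A `rate_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_exponential <- function(samples, conf_level = 0.95, naive = FALSE) {
  stopifnot(all(c("fpt_s", "censored") %in% names(samples)))
  t_all <- samples$fpt_s
  cens <- samples$censored
  d <- sum(!cens)
  if (d == 0) {
    stop_param("all observations are censored; record longer or use more ",
               "traces before fitting a rate")
  }
  total <- sum(t_all)
  k_mle <- d / total
  k_naive <- d / sum(t_all[!cens])
  k_hat <- if (naive) k_naive else k_mle
  # profile likelihood CI for the censored-exponential MLE
  loglik <- function(k) d * log(k) - k * total
  cut <- loglik(k_mle) - qchisq(conf_level, 1) / 2
  f <- function(k) loglik(k) - cut
  lo <- uniroot(f, c(k_mle * 1e-4, k_mle))$root
  hi <- uniroot(f, c(k_mle, k_mle * 1e4))$root
  km <- survival_curve(samples)
  ls_obj <- function(k) sum((km$survival - exp(-k * km$time_s))^2)
  ls_rate <- optimize(ls_obj, c(k_mle / 50, k_mle * 50))$minimum
  structure(
    list(rate = k_hat, mle_rate = k_mle, naive_rate = k_naive,
         ls_rate = ls_rate, se = k_mle / sqrt(d),
         conf_low = lo, conf_high = hi, conf_level = conf_level,
         n = nrow(samples), n_events = d,
         censored_fraction = mean(cens), naive = naive,
         loglik = loglik(k_mle)),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> k = ", signif(x$rate, 4), " s^-1 (",
      x$conf_level * 100, "% CI ", signif(x$conf_low, 4), "-",
      signif(x$conf_high, 4), "), ", x$n_events, "/", x$n,
      " events, ", round(100 * x$censored_fraction, 1), "% censored",
      if (x$naive) " [naive estimator]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(
    term = "rate", estimate = x$rate, std.error = x$se,
    conf.low = x$conf_low, conf.high = x$conf_high
  )
}

#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$rate, mle_rate = x$mle_rate, naive_rate = x$naive_rate,
    ls_rate = x$ls_rate, se = x$se, conf.low = x$conf_low,
    conf.high = x$conf_high, n = x$n, n_events = x$n_events,
    censored_fraction = x$censored_fraction, logLik = x$loglik
  )
}

#' Kaplan-Meier survival curve of first-passage samples
#'
#' Fraction of molecules that have not yet made the transition, versus time
#' since the trigger, accounting for censored exits (photobleaching, end of
#' recording).  Monotone non-increasing, starting at 1.
#'
#' @param samples An `fpt_sample` tibble.
#' @return Tibble with columns `time_s`, `survival`, `n_risk`, `n_event`.
#' @export
survival_curve <- function(samples) {
  stopifnot(all(c("fpt_s", "censored") %in% names(samples)))
  if (nrow(samples) == 0) stop_param("no samples")
  sf <- survival::survfit(
    survival::Surv(samples$fpt_s, !samples$censored) ~ 1
  )
  tibble::tibble(time_s = c(0, sf$time), survival = c(1, sf$surv),
                 n_risk = c(nrow(samples), sf$n.risk),
                 n_event = c(0, sf$n.event))
}
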
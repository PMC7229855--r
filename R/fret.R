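#' Configuration for synthetic smFRET traces
#'
#' Describes the salt-jump single-molecule FRET experiment the generator
#' emulates: molecules held in the pre-exchange state until the buffer
#' exchange, then evolving under the three-state kinetics; donor/acceptor
#' intensities read out at a fixed frame interval with Gaussian noise;
#' exponential photobleaching of either fluorophore censoring the trace.
#'
#' @param rates A [three_state_rates()] object.
#' @param n_traces Number of molecules (default 200, the typical number of
#'   trajectories behind one decay curve).
#' @param frame_interval_s Seconds per frame: 0.5 for looping runs, 0.1 for
#'   unlooping runs (default 0.5).
#' @param fret_low,fret_high FRET efficiency of the unlooped and looped
#'   states (defaults 0.1 and 0.8).
#' @param total_intensity Mean total counts per frame (default 1000).
#' @param noise_sd Gaussian noise sd per channel in counts (default 10% of
#'   the total intensity).
#' @param bleach_rate Total photobleaching rate in 1/s, split equally
#'   between donor and acceptor (default 0 = no bleaching).
#' @param exchange_time_s Time of the buffer exchange in s (default 20).
#' @param t_max_s Recording length in s (default 320).
#' @param direction `"loop"` (molecules start unlooped) or `"unloop"`
#'   (molecules start in the looped T/S equilibrium mixture).
#' @param seed Integer seed.
#' @return A `trace_config` object.
#' @export
trace_config <- function(rates, n_traces = 200, frame_interval_s = 0.5,
                         fret_low = 0.1, fret_high = 0.8,
                         total_intensity = 1000,
                         noise_sd = 0.1 * total_intensity,
                         bleach_rate = 0, exchange_time_s = 20,
                         t_max_s = 320, direction = c("loop", "unloop"),
                         seed = 1) {
  stopifnot(inherits(rates, "three_state_rates"))
  direction <- match.arg(direction)
  if (!(fret_low >= 0 && fret_low < fret_high && fret_high <= 1)) {
    stop_param("need 0 <= fret_low < fret_high <= 1")
  }
  if (n_traces < 1) stop_param("`n_traces` must be >= 1")
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(total_intensity, "total_intensity")
  if (noise_sd < 0 || bleach_rate < 0) {
    stop_param("`noise_sd` and `bleach_rate` must be >= 0")
  }
  if (exchange_time_s <= 0 || exchange_time_s >= t_max_s) {
    stop_param("`exchange_time_s` must lie inside (0, t_max_s)")
  }
  structure(
    list(rates = rates, n_traces = as.integer(n_traces),
         frame_interval_s = frame_interval_s, fret_low = fret_low,
         fret_high = fret_high, total_intensity = total_intensity,
         noise_sd = noise_sd, bleach_rate = bleach_rate,
         exchange_time_s = exchange_time_s, t_max_s = t_max_s,
         direction = direction, seed = as.integer(seed)),
    class = "trace_config"
  )
}

#' @export
print.trace_config <- function(x, ...) {
  cat("<trace_config> ", x$n_traces, " ", x$direction, " traces, ",
      x$frame_interval_s * 1000, " ms/frame, exchange at ",
      x$exchange_time_s, " s, bleach rate ", x$bleach_rate, " s^-1 (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate synthetic smFRET intensity traces
#'
#' Before the exchange frame the hidden state is pinned (U for looping runs,
#' the stationary T/S mixture for unlooping runs); afterwards it evolves by
#' exact stochastic simulation of the three-state chain.  Each frame reads
#' out `acceptor = E * I_tot + noise` and `donor = (1 - E) * I_tot + noise`
#' with E the state's FRET level.  Exponential photobleaching times are
#' drawn for each fluorophore (total rate `bleach_rate`, split equally):
#' after acceptor bleach the acceptor drops to background and the donor
#' recovers the full intensity; after donor bleach both channels drop to
#' background.  Fully reproducible from `config$seed`.
#'
#' @param config A [trace_config()] object.
#' @return A tibble of class `fret_traces` with columns `trace_id`, `frame`,
#'   `time_s`, `donor`, `acceptor`, `state` (hidden truth, for validation).
#'   Attributes: `config`, and a `trace_info` tibble (`trace_id`,
#'   `exchange_frame`, `bleach_frame` (NA if unbleached), `bleach_channel`).
#' @export
generate_traces <- function(config) {
  stopifnot(inherits(config, "trace_config"))
  set.seed(config$seed)
  dt <- config$frame_interval_s
  n_frames <- floor(config$t_max_s / dt)
  exchange_frame <- ceiling(config$exchange_time_s / dt)
  t_post <- config$t_max_s - config$exchange_time_s
  frame_time <- (seq_len(n_frames) - 0.5) * dt  # frame midpoints
  pin_state <- if (config$direction == "loop") "U" else "looped_equilibrium"

  per_trace <- lapply(seq_len(config$n_traces), function(id) {
    traj <- .simulate_kinetics_noseed(config$rates, pin_state, t_post, 1L)
    # state per frame: pinned start state before exchange, then evolve
    st <- character(n_frames)
    pre <- frame_time < config$exchange_time_s
    st[pre] <- traj$state[1]
    tp <- frame_time[!pre] - config$exchange_time_s
    idx <- findInterval(tp, traj$time_s)
    st[!pre] <- traj$state[idx]
    e <- ifelse(st == "U", config$fret_low, config$fret_high)
    # photobleaching
    bleach_channel <- NA_character_
    bleach_frame <- NA_integer_
    bleach_time <- NA_real_
    if (config$bleach_rate > 0) {
      tb_d <- rexp(1, config$bleach_rate / 2)
      tb_a <- rexp(1, config$bleach_rate / 2)
      tb <- min(tb_d, tb_a)
      if (tb < config$t_max_s) {
        bleach_channel <- if (tb_d < tb_a) "donor" else "acceptor"
        bleach_frame <- max(1L, findInterval(tb, frame_time) + 1L)
        bleach_time <- tb
      }
    }
    acceptor_live <- rep(TRUE, n_frames)
    donor_live <- rep(TRUE, n_frames)
    if (!is.na(bleach_frame) && bleach_frame <= n_frames) {
      gone <- seq_len(n_frames) >= bleach_frame
      if (bleach_channel == "donor") {
        donor_live[gone] <- FALSE
        acceptor_live[gone] <- FALSE  # no excitation transfer after donor loss
      } else {
        acceptor_live[gone] <- FALSE
      }
    }
    acc_mean <- ifelse(acceptor_live, e * config$total_intensity, 0)
    don_mean <- ifelse(donor_live,
                       ifelse(acceptor_live, (1 - e), 1) *
                         config$total_intensity, 0)
    list(
      frames = tibble::tibble(
        trace_id = id, frame = seq_len(n_frames), time_s = frame_time,
        donor = don_mean + stats::rnorm(n_frames, 0, config$noise_sd),
        acceptor = acc_mean + stats::rnorm(n_frames, 0, config$noise_sd),
        state = st
      ),
      info = tibble::tibble(trace_id = id, exchange_frame = exchange_frame,
                            bleach_frame = bleach_frame,
                            bleach_time_s = bleach_time,
                            bleach_channel = bleach_channel)
    )
  })
  out <- dplyr::bind_rows(lapply(per_trace, `[[`, "frames"))
  attr(out, "config") <- config
  attr(out, "trace_info") <- dplyr::bind_rows(lapply(per_trace, `[[`, "info"))
  class(out) <- c("fret_traces", class(out))
  out
}

#' FRET efficiency from background-subtracted intensities
#'
#' `acceptor / (acceptor + donor)`, clamped to `[0, 1]`.  Frames whose total
#' intensity is not positive carry no signal and return `NA` (flagged
#' invalid, excluded downstream).
#'
#' @param donor,acceptor Background-subtracted intensities (counts).
#' @return FRET efficiency in `[0, 1]`, `NA` for invalid frames.
#' @export
fret_signal <- function(donor, acceptor) {
  tot <- donor + acceptor
  e <- ifelse(tot > 0, acceptor / tot, NA_real_)
  pmin(1, pmax(0, e))
}

#' Two-point moving average of a FRET series
#'
#' Averages consecutive frames; the output has `n - 1` points with
#' timestamps at the frame-pair midpoints (the alignment used throughout the
#' transition detector).
#'
#' @param e FRET values (length >= 2).
#' @param time_s Optional frame times; if given, midpoint times are
#'   returned.
#' @return If `time_s` is `NULL`, a numeric vector of length `n - 1`;
#'   otherwise a tibble with `time_s` (midpoints) and `fret`.
#' @export
smooth_fret <- function(e, time_s = NULL) {
  if (length(e) < 2) stop_param("need at least 2 frames")
  sm <- (e[-1] + e[-length(e)]) / 2
  if (is.null(time_s)) return(sm)
  tibble::tibble(time_s = (time_s[-1] + time_s[-length(time_s)]) / 2,
                 fret = sm)
}

#' Detect the first FRET transition after the exchange
#'
#' Two-state segmentation of a smoothed FRET series by thresholding midway
#' between the configured low and high levels, with a persistence rule: a
#' transition is called at the first frame after the exchange whose level,
#' and that of the following `persist - 1` frames, lies on the far side of
#' the threshold.  The first-passage time runs from the exchange time to
#' that frame; traces that bleach (or end) first are censored at the bleach
#' (or last) frame.  Traces on the wrong side of the threshold immediately
#' before the exchange are rejected.
#'
#' @param trace Tibble with columns `time_s`, `donor`, `acceptor` (one
#'   trace), or `time_s`, `fret`.
#' @param direction `"low_to_high"` (looping) or `"high_to_low"`
#'   (unlooping).
#' @param exchange_time_s Exchange time in s.
#' @param fret_low,fret_high Nominal FRET levels (defaults 0.1, 0.8).
#' @param persist Number of consecutive frames required beyond the
#'   threshold (default 2).
#' @param bleach_time_s Optional bleach time in s; frames at or after it are
#'   discarded and censor the passage time.
#' @return One-row tibble: `fpt_s`, `censored`, `censor_time_s`, `valid`,
#'   `reason` (NA when valid).
#' @export
detect_transition <- function(trace,
                              direction = c("low_to_high", "high_to_low"),
                              exchange_time_s, fret_low = 0.1,
                              fret_high = 0.8, persist = 2,
                              bleach_time_s = NA) {
  direction <- match.arg(direction)
  if (!("fret" %in% names(trace))) {
    trace <- dplyr::mutate(trace,
                           fret = fret_signal(.data$donor, .data$acceptor))
  }
  sm <- smooth_fret(trace$fret, trace$time_s)
  sm <- sm[is.finite(sm$fret), ]
  if (is.finite(bleach_time_s)) sm <- sm[sm$time_s < bleach_time_s, ]
  if (!any(sm$time_s < exchange_time_s) || !any(sm$time_s >= exchange_time_s)) {
    return(tibble::tibble(fpt_s = NA_real_, censored = NA, censor_time_s =
                            NA_real_, valid = FALSE,
                          reason = "series does not cover the exchange"))
  }
  thr <- (fret_low + fret_high) / 2
  high <- sm$fret > thr
  want_high <- direction == "low_to_high"
  # starting level check just before the exchange
  pre <- high[max(which(sm$time_s < exchange_time_s))]
  if (pre == want_high) {
    return(tibble::tibble(fpt_s = NA_real_, censored = NA,
                          censor_time_s = NA_real_, valid = FALSE,
                          reason = "wrong FRET level before exchange"))
  }
  post_idx <- which(sm$time_s >= exchange_time_s)
  flag <- if (want_high) high[post_idx] else !high[post_idx]
  # persistence: first index where `persist` consecutive frames hold
  run <- 0L
  hit <- NA_integer_
  for (i in seq_along(flag)) {
    run <- if (flag[i]) run + 1L else 0L
    if (run >= persist) {
      hit <- i - persist + 1L
      break
    }
  }
  end_time <- if (is.finite(bleach_time_s)) {
    min(bleach_time_s, max(sm$time_s))
  } else {
    max(sm$time_s)
  }
  if (is.na(hit)) {
    tibble::tibble(fpt_s = end_time - exchange_time_s, censored = TRUE,
                   censor_time_s = end_time - exchange_time_s, valid = TRUE,
                   reason = NA_character_)
  } else {
    tibble::tibble(fpt_s = sm$time_s[post_idx[hit]] - exchange_time_s,
                   censored = FALSE,
                   censor_time_s = end_time - exchange_time_s, valid = TRUE,
                   reason = NA_character_)
  }
}

#' Run the full synthetic FRET pipeline and recover rates
#'
#' Generates traces from `config`, computes FRET efficiencies, smooths,
#' detects first transitions, and fits the censoring-aware exponential rate;
#' optionally converts the looping rate to an experimental J factor
#' \eqn{J_{exp} = \hat k_{loop} / k_{on}}.
#'
#' @param config A [trace_config()] object.
#' @param k_on Annealing rate constant in 1/(M s) for J_exp, or `NULL`.
#' @param naive Also report the censoring-naive estimate?  (Always computed;
#'   this flag selects which one is the headline `rate`.)
#' @return A list of class `recovery_result`: `fit` (a `rate_fit`),
#'   `fpt` (the first-passage tibble), `n_usable`, `censored_fraction`,
#'   `j_exp_M` (NA without `k_on`), `direction`, `config`.
#' @export
recover_rates <- function(config, k_on = NULL, naive = FALSE) {
  stopifnot(inherits(config, "trace_config"))
  traces <- generate_traces(config)
  fpt <- analyze_traces(traces)
  n_usable <- nrow(fpt)
  if (n_usable < 20) {
    stop_param("only ", n_usable, " usable traces; increase `n_traces`")
  }
  fit <- fit_exponential(fpt, naive = naive)
  jexp <- if (!is.null(k_on)) j_exp(fit$rate, k_on) else NA_real_
  structure(
    list(fit = fit, fpt = fpt, n_usable = n_usable,
         censored_fraction = fit$censored_fraction, j_exp_M = jexp,
         direction = config$direction, config = config),
    class = "recovery_result"
  )
}

#' First-passage analysis of a set of FRET traces
#'
#' Applies [detect_transition()] to every trace of a [generate_traces()]
#' result (or any tibble with `trace_id`, `time_s`, `donor`, `acceptor`) and
#' returns the usable first-passage samples.
#'
#' @param traces A `fret_traces` tibble; the generator's config supplies the
#'   exchange time, FRET levels and direction unless overridden.
#' @param direction,exchange_time_s,fret_low,fret_high Overrides for
#'   externally supplied traces.
#' @return An `fpt_sample` tibble (`trace_id`, `fpt_s`, `censored`,
#'   `censor_time_s`); excluded traces are dropped, with counts in attribute
#'   `"n_excluded"`.
#' @export
analyze_traces <- function(traces, direction = NULL, exchange_time_s = NULL,
                           fret_low = NULL, fret_high = NULL) {
  cfg <- attr(traces, "config")
  if (is.null(cfg) && (is.null(direction) || is.null(exchange_time_s))) {
    stop_param("supply `direction` and `exchange_time_s` for external traces")
  }
  direction <- direction %||%
    if (cfg$direction == "loop") "low_to_high" else "high_to_low"
  exchange_time_s <- exchange_time_s %||% cfg$exchange_time_s
  fret_low <- fret_low %||% (if (is.null(cfg)) 0.1 else cfg$fret_low)
  fret_high <- fret_high %||% (if (is.null(cfg)) 0.8 else cfg$fret_high)
  info <- attr(traces, "trace_info")
  bleach_of <- function(id) {
    if (is.null(info)) return(NA_real_)
    bt <- info$bleach_time_s[match(id, info$trace_id)]
    if (length(bt) == 0) NA_real_ else bt
  }
  res <- traces |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(tr, key) {
      detect_transition(tr, direction = direction,
                        exchange_time_s = exchange_time_s,
                        fret_low = fret_low, fret_high = fret_high,
                        bleach_time_s = bleach_of(key$trace_id))
    }) |>
    dplyr::ungroup()
  excluded <- sum(!res$valid)
  out <- res |>
    dplyr::filter(.data$valid) |>
    dplyr::select("trace_id", "fpt_s", "censored", "censor_time_s")
  attr(out, "n_excluded") <- excluded
  class(out) <- c("fpt_sample", class(out))
  out
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result> ", x$direction, " experiment: k = ",
      signif(x$fit$rate, 4), " s^-1 (95% CI ", signif(x$fit$conf_low, 4),
      "-", signif(x$fit$conf_high, 4), "), ", x$n_usable,
      " usable traces, ", round(100 * x$censored_fraction, 1),
      "% censored", sep = "")
  if (is.finite(x$j_exp_M)) {
    cat(", J_exp = ", signif(x$j_exp_M * 1e9, 4), " nM", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
glance.recovery_result <- function(x, ...) {
  dplyr::mutate(glance(x$fit), j_exp_M = x$j_exp_M,
                direction = x$direction, n_usable = x$n_usable)
}
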
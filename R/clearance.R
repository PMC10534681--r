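#' Continuous clearance coefficient from a per-minute clearance fraction
#'
#' A donor compartment cleared at a constant fraction \eqn{c} of its
#' current volume per minute follows \eqn{V(t) = V_0 e^{-\beta t}} with
#' \eqn{\beta = -\ln(1 - c)} per minute.  In canonical mode the
#' coefficient is rounded half-up to 3 decimals, the convention that
#' reproduces the published operating-condition coefficients
#' (11\%/min -> 0.117, 16\%/min -> 0.174) and every volume percentage
#' derived from them.
#'
#' @param rate per-minute fractional clearance, \code{0 <= rate < 1}
#'   (0.11 means 11\% of the present volume removed per minute).
#' @param rounded logical; round the coefficient half-up to 3 decimals
#'   (canonical mode, default) or keep full precision.
#' @return clearance coefficient \eqn{\beta} in 1/min.
#' @seealso [clearance_schedule()], [rate_for_flow()]
#' @examples
#' beta_from_rate(0.11)            # 0.117
#' beta_from_rate(0.16)            # 0.174
#' beta_from_rate(0.5, rounded = FALSE)
#' @export
beta_from_rate <- function(rate, rounded = TRUE) {
  if (any(!is.finite(rate)) || any(rate < 0) || any(rate >= 1))
    .fail("clearance must remove less than the whole volume per minute (0 <= rate < 1)")
  beta <- -log1p(-rate)
  if (rounded) beta <- round_half_up(beta, 3)
  beta
}

#' Pump flow delivering a given clearance rate
#'
#' The peristaltic pump flow that clears \code{rate} of a reference
#' volume per minute: \code{rate * reference_volume}.  With the 300 uL
#' donor load of the dynamic model, 16\%/min corresponds to 48 uL/min
#' and 11\%/min to 33 uL/min.
#'
#' @param rate per-minute fractional clearance in \code{[0, 1)}.
#' @param reference_volume volume over which the rate is defined (uL).
#' @return pump flow in uL/min.
#' @export
flow_for_rate <- function(rate, reference_volume) {
  if (any(!is.finite(reference_volume)) || any(reference_volume <= 0))
    .fail("reference_volume must be positive")
  if (any(rate < 0) || any(rate >= 1))
    .fail("clearance must remove less than the whole volume per minute (0 <= rate < 1)")
  rate * reference_volume
}

#' Clearance rate implied by a pump flow
#'
#' Inverse of [flow_for_rate()]: the per-minute fractional clearance a
#' constant withdrawal of \code{flow} uL/min represents relative to a
#' reference volume.  The basal human tear flow of about 1.1 uL/min over
#' a 7--10 uL tear volume gives turnover rates of roughly 11--16\%/min,
#' the physiological anchor for the simulated regimes.
#'
#' @param flow pump flow in uL/min (non-negative).
#' @param reference_volume reference volume in uL (positive).
#' @return per-minute fractional clearance.
#' @export
rate_for_flow <- function(flow, reference_volume) {
  if (any(!is.finite(reference_volume)) || any(reference_volume <= 0))
    .fail("reference_volume must be positive")
  if (any(flow < 0)) .fail("flow must be non-negative")
  flow / reference_volume
}

#' Volume after whole minutes of discrete per-minute clearance
#'
#' Compounds the clearance minute by minute: \eqn{V_0 (1-c)^k}.  At
#' 11\%/min this gives 89\%, 79.21\% and 70.50\% of the initial volume
#' after 1, 2 and 3 minutes.  Serves as the independent discrete oracle
#' against which the continuous model converges as the step shrinks.
#'
#' @param rate per-minute fractional clearance in \code{[0, 1)}.
#' @param v0 initial volume (uL).
#' @param k whole minutes elapsed (non-negative integer).
#' @return remaining volume in uL.
#' @export
discrete_volume <- function(rate, v0, k) {
  if (any(rate < 0) || any(rate >= 1))
    .fail("clearance must remove less than the whole volume per minute (0 <= rate < 1)")
  if (any(k < 0) || any(k != floor(k))) .fail("k must be a non-negative integer")
  v0 * (1 - rate)^k
}

#' Multi-regime clearance schedule
#'
#' Builds a piecewise-exponential washout schedule for the donor
#' compartment: an ordered sequence of constant-clearance regimes over
#' an initial volume.  Each regime occupies a half-open interval
#' \eqn{[t_k, t_{k+1})}; the volume at the end of one regime is the
#' starting volume of the next, so the trajectory is continuous.  The
#' published operating condition is 300 uL cleared at 16\%/min for
#' 2 min (the reflex-tearing stage) then 11\%/min for 13 min (basal
#' turnover).
#'
#' @param rates per-minute fractional clearance of each regime, each in
#'   \code{[0, 1)}.
#' @param durations regime durations in minutes, all positive; the last
#'   may be \code{Inf} for an unbounded final regime.
#' @param v0 initial volume in uL (default 300).
#' @param round_beta logical; use coefficients rounded half-up to 3
#'   decimals (canonical mode, default) or full-precision
#'   \eqn{-\ln(1-c)}.
#' @return an object of class \code{"clearance_schedule"}: a list with
#'   elements \code{v0}, \code{rates}, \code{betas}, \code{durations},
#'   \code{flows} (uL/min against \code{v0}), \code{t_start} (regime
#'   start times) and \code{v_start} (regime start volumes).
#' @examples
#' sched <- clearance_schedule(c(0.16, 0.11), c(2, 13), v0 = 300)
#' volume_at(sched, 2)        # ~211.83 uL
#' percent_remaining(sched, 15)
#' @export
clearance_schedule <- function(rates, durations, v0 = 300, round_beta = TRUE) {
  if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0) || v0 <= 0)
    .fail("v0 must be a single positive volume")
  if (length(rates) == 0L || length(rates) != length(durations))
    .fail("rates and durations must be non-empty and of equal length")
  if (any(rates < 0) || any(rates >= 1))
    .fail("clearance must remove less than the whole volume per minute (0 <= rate < 1)")
  if (any(durations <= 0)) .fail("durations must be positive")
  rates <- unname(as.numeric(rates))
  durations <- unname(as.numeric(durations))
  n <- length(rates)
  if (any(!is.finite(durations[-n])))
    .fail("only the final regime may have unbounded duration")
  betas <- beta_from_rate(rates, rounded = round_beta)
  t_start <- c(0, cumsum(durations[-n]))
  v_start <- numeric(n)
  v_start[1] <- v0
  if (n > 1) for (k in seq_len(n - 1))
    v_start[k + 1] <- v_start[k] * exp(-betas[k] * durations[k])
  structure(
    list(v0 = v0, rates = rates, betas = betas, durations = durations,
         flows = rates * v0, t_start = t_start, v_start = v_start),
    class = "clearance_schedule")
}

#' @export
print.clearance_schedule <- function(x, ...) {
  n <- length(x$rates)
  cat("Clearance schedule: V0 =", x$v0, "uL,", n,
      if (n == 1) "regime\n" else "regimes\n")
  tab <- data.frame(
    start_min = x$t_start,
    duration_min = x$durations,
    rate_pct_per_min = 100 * x$rates,
    beta_per_min = x$betas,
    flow_uL_per_min = x$flows,
    start_volume_uL = round_half_up(x$v_start, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.clearance_schedule <- function(object, ...) {
  print(object)
  T_end <- sum(object$durations)
  if (is.finite(T_end)) {
    v <- volume_at(object, T_end)
    cat(sprintf("End of schedule (t = %g min): %.2f uL (%.2f%% of V0); AUC = %.1f uL*min\n",
                T_end, v, 100 * v / object$v0, auc_volume(object, T_end)))
  }
  invisible(object)
}

#' @export
coef.clearance_schedule <- function(object, ...) {
  stats::setNames(object$betas, paste0("beta", seq_along(object$betas)))
}

# schedule horizon in minutes (Inf when the last regime is unbounded)
schedule_horizon <- function(schedule) sum(schedule$durations)

# regime index for each time under the half-open [t_start, t_end) convention;
# t == T_end (bounded schedule) evaluates in the final regime
regime_index <- function(schedule, t) findInterval(t, schedule$t_start)

#' Donor volume at a time point
#'
#' Piecewise evaluation of the schedule: within regime \eqn{k} starting
#' at \eqn{t_k} with start volume \eqn{V_k}, the volume is
#' \eqn{V_k e^{-\beta_k (t - t_k)}}.  Continuous at regime switches and
#' strictly decreasing wherever \eqn{\beta > 0}.
#'
#' @param schedule a [clearance_schedule()].
#' @param t time(s) in minutes; must lie in \code{[0, T_end]}.
#' @return volume(s) in uL.
#' @export
volume_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "clearance_schedule"))
  T_end <- schedule_horizon(schedule)
  if (any(!is.finite(t)) || any(t < 0) || any(t > T_end))
    .fail("t must lie within the schedule horizon [0, ", T_end, "]")
  k <- regime_index(schedule, t)
  schedule$v_start[k] * exp(-schedule$betas[k] * (t - schedule$t_start[k]))
}

#' @rdname volume_at
#' @param object a \code{clearance_schedule}.
#' @param times time(s) in minutes at which to predict the volume.
#' @param ... unused.
#' @export
predict.clearance_schedule <- function(object, times, ...) volume_at(object, times)

#' Percent of the initial volume remaining
#'
#' \code{100 * volume_at(schedule, t) / v0}, reported half-up at two
#' decimals — the reporting convention of the published simulation
#' (17.29\% and 7.35\% after 15 min at 11 and 16\%/min; 15.43\% for the
#' two-stage run).
#'
#' @inheritParams volume_at
#' @return percent of \code{v0} remaining, rounded to 2 decimals.
#' @export
percent_remaining <- function(schedule, t) {
  round_half_up(100 * volume_at(schedule, t) / schedule$v0, 2)
}

#' Simulate a volume trajectory on a time grid
#'
#' Evaluates the schedule on a regular grid and tracks the cumulative
#' drained volume, \code{v0 - V(t)}, so mass balance holds exactly at
#' every grid point.
#'
#' @inheritParams volume_at
#' @param dt grid step in minutes (default 0.01).
#' @param t_end simulation horizon in minutes; defaults to the schedule
#'   horizon, which must then be finite.
#' @return a \code{data.frame} of class \code{"volume_trajectory"} with
#'   columns \code{time_min}, \code{volume_uL}, \code{percent},
#'   \code{drained_uL}.
#' @export
simulate_trajectory <- function(schedule, dt = 0.01, t_end = NULL) {
  stopifnot(inherits(schedule, "clearance_schedule"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .fail("dt must be a positive step in minutes")
  if (is.null(t_end)) t_end <- schedule_horizon(schedule)
  if (!is.finite(t_end))
    .fail("t_end must be given for a schedule with an unbounded final regime")
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  vols <- volume_at(schedule, times)
  structure(
    data.frame(time_min = times,
               volume_uL = vols,
               percent = 100 * vols / schedule$v0,
               drained_uL = schedule$v0 - vols),
    class = c("volume_trajectory", "data.frame"),
    v0 = schedule$v0)
}

#' Write a trajectory to CSV
#'
#' @param trajectory a [simulate_trajectory()] result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "volume_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.volume_trajectory <- function(x, ...) {
  graphics::plot(x$time_min, x$percent, type = "l",
                 xlab = "time (min)", ylab = "volume remaining (% of V0)",
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' @rdname simulate_trajectory
#' @param x a \code{clearance_schedule}.
#' @param ... passed to \code{plot.volume_trajectory}.
#' @export
plot.clearance_schedule <- function(x, dt = 0.01, t_end = NULL, ...) {
  plot(simulate_trajectory(x, dt = dt, t_end = t_end), ...)
}

#' Area under the volume curve
#'
#' Exposure metric \eqn{\int_0^T V(t)\,dt}, evaluated piecewise in
#' closed form: each regime contributes
#' \eqn{V_k (1 - e^{-\beta_k \Delta_k}) / \beta_k}, with the limit
#' \eqn{V_k \Delta_k} when \eqn{\beta_k = 0}.
#'
#' @inheritParams volume_at
#' @param T upper limit of integration in minutes, within the horizon.
#' @return area in uL*min.
#' @export
auc_volume <- function(schedule, T) {
  stopifnot(inherits(schedule, "clearance_schedule"))
  T_end <- schedule_horizon(schedule)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0 || T > T_end)
    .fail("T must lie within the schedule horizon [0, ", T_end, "]")
  if (T == 0) return(0)
  n <- length(schedule$betas)
  total <- 0
  for (k in seq_len(n)) {
    t0 <- schedule$t_start[k]
    if (t0 >= T) break
    dk <- min(schedule$durations[k], T - t0)
    b <- schedule$betas[k]
    vk <- schedule$v_start[k]
    total <- total + if (b == 0) vk * dk else vk * (1 - exp(-b * dk)) / b
  }
  total
}

#' Recover the clearance coefficient from a sampled trajectory
#'
#' Least-squares fit of the single-regime model on the log scale:
#' regresses \eqn{-\ln V} on \eqn{t}, whose slope is \eqn{\beta}.  On
#' noiseless single-regime data this recovers the generating
#' coefficient to machine precision.
#'
#' @param times sampling times in minutes (at least 3).
#' @param volumes measured volumes in uL, all positive.
#' @return an object of class \code{"clearance_fit"} with elements
#'   \code{beta} (1/min), \code{v0} (fitted initial volume),
#'   \code{fitted} and \code{residuals} (log-scale); \code{coef()}
#'   returns the named coefficient.
#' @examples
#' t <- 0:15
#' fit <- fit_beta(t, 300 * exp(-0.117 * t))
#' coef(fit)
#' @export
fit_beta <- function(times, volumes) {
  if (length(times) < 3 || length(times) != length(volumes))
    .fail("need at least 3 (time, volume) samples of equal length")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    .fail("volumes must be positive")
  y <- -log(volumes)
  fit <- stats::lm.fit(cbind(1, times), y)
  beta <- max(unname(fit$coefficients[2]), 0)  # clearance cannot be negative
  structure(list(beta = beta,
                 v0 = exp(-unname(fit$coefficients[1])),
                 fitted = -fit$fitted.values,
                 residuals = -fit$residuals),
            class = "clearance_fit")
}

#' @export
coef.clearance_fit <- function(object, ...) c(beta = object$beta)

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("Single-regime clearance fit: beta = %.6g /min, V0 = %.4g uL\n",
              x$beta, x$v0))
  invisible(x)
}

#' Build a schedule from a config file or compact text
#'
#' \code{schedule_from_config()} reads a YAML or JSON file with fields
#' \code{v0} and \code{regimes} (a list of \code{rate_percent} /
#' \code{duration} pairs, duration \code{"inf"} allowed last).
#' \code{parse_schedule()} parses the compact
#' \code{"percent:duration,percent:duration"} syntax, e.g.
#' \code{"16:2,11:13"}.
#'
#' @param path YAML (.yml/.yaml) or JSON config file.
#' @param round_beta passed to [clearance_schedule()].
#' @return a \code{clearance_schedule}.
#' @export
schedule_from_config <- function(path, round_beta = TRUE) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$v0) || is.null(cfg$regimes))
    .fail("schedule config must have fields 'v0' and 'regimes'")
  reg <- cfg$regimes
  if (is.data.frame(reg)) reg <- split(reg, seq_len(nrow(reg)))
  rates <- vapply(reg, function(r) as.numeric(r$rate_percent) / 100, numeric(1))
  durations <- vapply(reg, function(r) {
    d <- r$duration
    if (identical(tolower(as.character(d)), "inf")) Inf else as.numeric(d)
  }, numeric(1))
  clearance_schedule(rates, durations, v0 = as.numeric(cfg$v0),
                     round_beta = round_beta)
}

#' @rdname schedule_from_config
#' @param spec compact schedule text, \code{"percent:minutes,..."}.
#' @param v0 initial volume in uL.
#' @export
parse_schedule <- function(spec, v0 = 300, round_beta = TRUE) {
  parts <- strsplit(trimws(spec), ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L) .fail("empty schedule spec")
  pieces <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(pieces) != 2L))
    .fail("schedule spec must be 'percent:duration' pairs, e.g. '16:2,11:13'")
  rates <- vapply(pieces, function(p) as.numeric(p[1]) / 100, numeric(1))
  durations <- vapply(pieces, function(p)
    if (tolower(p[2]) == "inf") Inf else as.numeric(p[2]), numeric(1))
  clearance_schedule(rates, durations, v0 = v0, round_beta = round_beta)
}
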
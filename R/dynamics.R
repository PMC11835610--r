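#' Simulate the hospital flow model
#'
#' Integrates the model forward with an adaptive, stiffness-switching solver
#' (\code{deSolve::ode}, lsoda by default) and returns dense output on the
#' requested grid together with the derived cumulative series: discharges
#' \eqn{D(t) = \int_0^t \omega E\,ds} and deaths
#' \eqn{M(t) = \int_0^t (m_1C + m_2G + m_3I)\,ds}, computed by trapezoidal
#' quadrature of the stored states.
#'
#' The model's oscillations drive the strictly positive compartments through
#' collapses many hundreds of orders of magnitude deep (the classic
#' "atto-patient" problem of saturating population models). In linear state
#' space such collapses either defeat adaptive solvers (a numeric zero
#' crossing of E meets the \eqn{1+b_1E} singularity) or are silently floored
#' at the solver's error tolerance. When `log_states = TRUE` the E and C
#' equations are therefore integrated in logarithmic coordinates, which is
#' exact for the same vector field and keeps both compartments positive by
#' construction; G and I remain linear (their zero faces are reachable).
#' The default (`NULL`) enables the log form automatically when the initial
#' E and C are both strictly positive; initial states on the invariant faces
#' E = 0 or C = 0 fall back to linear integration, where those faces are
#' preserved exactly.
#'
#' No clipping is applied in either form.
#'
#' @inheritParams ward_rhs
#' @param init initial state (E, C, G, I), all components >= 0.
#' @param t_end end time (hours), > 0.
#' @param dt_out output grid spacing (hours).
#' @param rtol,atol relative and absolute integration tolerances.
#' @param log_states `TRUE`, `FALSE`, or `NULL` (auto; see Details).
#' @param method solver passed to [deSolve::ode()].
#' @param maxsteps maximum internal steps per output interval.
#' @return An object of class `ward_trajectory`: list with `times`, `states`
#'   (matrix with columns E, C, G, I), `D_cum`, `M_cum`, `params`, `variant`,
#'   `init`, `log_states`, and `negativity_violation` (logical: any stored
#'   component below -1e-8).
#' @examples
#' p <- ward_params()
#' tr <- ward_simulate(p, init = c(100, 0, 0, 233.3333333), t_end = 50)
#' max(abs(tr$states[, "E"] - 100))   # E2 is a fixed point
#' @export
ward_simulate <- function(params, init, t_end, dt_out = 0.5,
                          variant = "balanced", rtol = 1e-8, atol = 1e-10,
                          log_states = NULL, method = "lsoda",
                          maxsteps = 500000) {
  p <- validate_params(params)
  check_variant(variant)
  y0 <- as_ward_state(init)
  stopifnot(is.numeric(t_end), length(t_end) == 1L, t_end > 0,
            is.numeric(dt_out), dt_out > 0, rtol > 0, atol > 0)
  times <- seq(0, t_end, by = dt_out)
  if (is.null(log_states)) log_states <- y0[["E"]] > 0 && y0[["C"]] > 0
  if (log_states && (y0[["E"]] <= 0 || y0[["C"]] <= 0))
    stop("log_states = TRUE requires strictly positive initial E and C",
         call. = FALSE)

  if (log_states) {
    ## Under the balanced variant dG/dt is proportional to G, so the G = 0
    ## face is invariant and a round-off sign error in a linear G is
    ## self-amplifying; integrating ln(G) removes the failure mode. Under
    ## as_printed the gain term is independent of G and a linear G is
    ## self-correcting, so it stays linear (its zero face is not invariant).
    log_G <- variant == "balanced" && y0[["G"]] > 0
    deriv <- function(t, s, parms) {
      E <- exp(s[1]); C <- exp(s[2])
      G <- if (log_G) exp(s[3]) else s[3]
      I <- s[4]
      sat <- 1 + p$zeta * I / (1 + p$epsilon * I)
      phi <- p$a * E / (1 + p$b1 * E)
      lead <- if (variant == "balanced") G else I
      dG_per <- p$gamma2 * p$beta * C / (1 + p$b2 * C) * sat  # balanced gain/G
      list(c(p$r * (1 - E / p$K) - p$a * C / (1 + p$b1 * E),
             p$gamma1 * phi - p$m1 - p$beta * G / (1 + p$b2 * C) * sat,
             if (log_G) dG_per - p$m2
             else p$gamma2 * p$beta * lead * C / (1 + p$b2 * C) * sat -
               p$m2 * G,
             p$beta * phi * C - p$m3 * I + p$omega * E))
    }
    s0 <- c(log(y0[["E"]]), log(y0[["C"]]),
            if (log_G) log(y0[["G"]]) else y0[["G"]], y0[["I"]])
  } else {
    deriv <- function(t, s, parms) list(unname(ward_rhs(s, p, variant)))
    s0 <- unname(y0)
  }

  sol <- deSolve::ode(y = s0, times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = maxsteps)
  if (nrow(sol) < length(times) || any(!is.finite(sol)))
    stop(sprintf(
      "integration failed (step-size collapse); last valid time: %.6g h",
      sol[max(which(apply(is.finite(sol), 1, all))), 1]), call. = FALSE)

  states <- sol[, -1, drop = FALSE]
  if (log_states) {
    states[, 1:2] <- exp(states[, 1:2])
    if (variant == "balanced" && y0[["G"]] > 0)
      states[, 3] <- exp(states[, 3])
  }
  colnames(states) <- c("E", "C", "G", "I")

  dis_rate <- p$omega * states[, "E"]
  mor_rate <- p$m1 * states[, "C"] + p$m2 * states[, "G"] +
    p$m3 * states[, "I"]
  structure(list(times = times, states = states,
                 D_cum = cum_trapz(times, dis_rate),
                 M_cum = cum_trapz(times, mor_rate),
                 params = p, variant = variant, init = y0,
                 log_states = log_states,
                 negativity_violation = min(states) < -1e-8),
            class = "ward_trajectory")
}

## internal: cumulative trapezoidal integral
cum_trapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' @export
print.ward_trajectory <- function(x, ...) {
  cat(sprintf("<ward trajectory> %d samples over [0, %g] h (variant %s%s)\n",
              length(x$times), max(x$times), x$variant,
              if (x$log_states) ", log-space E,C" else ""))
  cat(sprintf("  final state: E=%.5g C=%.5g G=%.5g I=%.5g\n",
              x$states[nrow(x$states), 1], x$states[nrow(x$states), 2],
              x$states[nrow(x$states), 3], x$states[nrow(x$states), 4]))
  if (x$negativity_violation) cat("  ** negativity violation recorded **\n")
  invisible(x)
}

#' @export
as.data.frame.ward_trajectory <- function(x, ...) {
  data.frame(time = x$times, E = x$states[, "E"], C = x$states[, "C"],
             G = x$states[, "G"], I = x$states[, "I"],
             D_cum = x$D_cum, M_cum = x$M_cum)
}

#' Check trajectory non-negativity
#'
#' Scans a trajectory for components below `-tol`, distinguishing solver
#' round-off (within the slack) from genuine violations.
#'
#' @param traj a `ward_trajectory`.
#' @param tol negativity slack (default 1e-8).
#' @return Data frame with columns `time`, `component`, `value`; zero rows
#'   means the trajectory passes.
#' @export
check_nonnegativity <- function(traj, tol = 1e-8) {
  stopifnot(inherits(traj, "ward_trajectory"))
  bad <- which(traj$states < -tol, arr.ind = TRUE)
  data.frame(time = traj$times[bad[, 1]],
             component = colnames(traj$states)[bad[, 2]],
             value = traj$states[bad])
}

## internal: strict local maxima with topographic prominence.
## The prominence of a peak is its height above the highest saddle that
## separates it from any higher point of the series.
find_peaks <- function(x) {
  dx <- diff(x)
  pk <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  pk <- pk[x[pk] > x[pmax(pk - 1L, 1L)]]          # strictness on the left
  if (!length(pk)) return(list(idx = integer(), prominence = numeric()))
  prom <- vapply(pk, function(i) {
    h <- x[i]
    left <- x[seq_len(i)]
    right <- x[i:length(x)]
    hi_l <- which(left > h)
    hi_r <- which(right > h)
    key_l <- if (length(hi_l)) min(left[max(hi_l):i]) else min(left)
    key_r <- if (length(hi_r)) min(right[1:min(hi_r)]) else min(right)
    h - max(key_l, key_r)
  }, numeric(1))
  list(idx = pk, prominence = prom)
}

#' Estimate the oscillation period of a trajectory
#'
#' Discards the leading `transient_fraction` of samples, locates strict local
#' maxima of the chosen component whose topographic prominence is at least
#' `prominence` times the post-transient amplitude, refines each peak time by
#' quadratic interpolation, and reports the median inter-peak spacing.
#'
#' Status is `"no_cycle"` when fewer than three qualifying peaks are found,
#' `"damped"` when successive peak heights decay monotonically and the last
#' peak has lost more than half the first peak's height above the
#' post-transient minimum, and `"ok"` otherwise.
#'
#' @param traj a `ward_trajectory`, or any list/data frame carrying a `times`
#'   (or `time`) vector and a numeric component of the same length.
#' @param component component name, one of "E", "C", "G", "I" (or a column of
#'   the supplied object).
#' @param transient_fraction fraction of leading samples to discard, in
#'   \[0, 0.9\].
#' @param prominence peak-prominence threshold as a fraction of the
#'   post-transient amplitude (default 0.01).
#' @return An object of class `period_estimate`: list with `period` (hours),
#'   `n_peaks`, `peak_times`, `status`.
#' @examples
#' t <- seq(0, 500, by = 0.1)
#' est <- estimate_period(list(times = t, x = sin(2 * pi * t / 42)), "x",
#'                        transient_fraction = 0)
#' est$period    # 42 up to grid resolution
#' @export
estimate_period <- function(traj, component = "E", transient_fraction = 0.5,
                            prominence = 0.01) {
  stopifnot(transient_fraction >= 0, transient_fraction <= 0.9)
  if (inherits(traj, "ward_trajectory")) {
    times <- traj$times
    if (!component %in% colnames(traj$states))
      stop("unknown component '", component, "'", call. = FALSE)
    x <- traj$states[, component]
  } else {
    times <- traj$times %||% traj$time
    if (is.null(times)) stop("no 'times' in supplied object", call. = FALSE)
    x <- traj[[component]]
    if (is.null(x)) stop("unknown component '", component, "'", call. = FALSE)
  }
  i0 <- max(1L, floor(length(times) * transient_fraction) + 1L)
  times <- times[i0:length(times)]
  x <- x[i0:length(x)]

  out <- function(period, n, pts, status)
    structure(list(period = period, n_peaks = n, peak_times = pts,
                   status = status), class = "period_estimate")

  amp <- diff(range(x))
  if (!is.finite(amp) || amp <= 0) return(out(NA_real_, 0L, numeric(), "no_cycle"))
  pks <- find_peaks(x)
  sel <- pks$prominence >= prominence * amp
  idx <- pks$idx[sel]
  if (length(idx) < 3L) return(out(NA_real_, length(idx),
                                   times[idx], "no_cycle"))
  ## quadratic refinement of peak times
  pt <- vapply(idx, function(i) {
    if (i <= 1L || i >= length(x)) return(times[i])
    den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (den >= 0) return(times[i])
    dt <- (times[i + 1L] - times[i - 1L]) / 2
    times[i] + 0.5 * dt * (x[i - 1L] - x[i + 1L]) / den
  }, numeric(1))
  heights <- x[idx] - min(x)
  damped <- all(diff(heights) < 0) &&
    heights[length(heights)] < 0.5 * heights[1]
  period <- stats::median(diff(pt))
  out(period, length(idx), pt, if (damped) "damped" else "ok")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("<period estimate> status: %s  peaks: %d  period: %s h\n",
              x$status, x$n_peaks,
              if (is.na(x$period)) "NA" else format(x$period)))
  invisible(x)
}
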
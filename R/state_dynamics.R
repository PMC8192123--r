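#' Growth rate from doubling time
#'
#' Converts a doubling time in days to an exponential growth rate per day,
#' `g = ln(2) / T`.
#'
#' @param T_double Doubling time in days. Must be positive.
#' @return Growth rate per day.
#' @examples
#' growth_rate(1)    # log(2)
#' growth_rate(1.09) # EpCAM-lo doubling time of HCT116
#' @export
growth_rate <- function(T_double) {
  if (!is.numeric(T_double) || any(!is.finite(T_double)) || any(T_double <= 0)) {
    stop("doubling time must be a positive finite number (days)")
  }
  log(2) / T_double
}

#' Parameters of the two-state growth/switching model
#'
#' Bundles the doubling times and state-transition rates of the two-state
#' model in which an epithelial (hi) and a quasi-mesenchymal (lo)
#' subpopulation each grow exponentially while cells stochastically switch
#' between states:
#' \deqn{dH/dt = (g_{hi} - k_{HL}) H + k_{LH} L}
#' \deqn{dL/dt = (g_{lo} - k_{LH}) L + k_{HL} H}
#' with growth rates `g = ln(2)/T`.
#'
#' @param T_hi,T_lo Doubling times (days) of the hi and lo states; positive.
#' @param k_HL Transition rate hi -> lo, per day; non-negative.
#' @param k_LH Transition rate lo -> hi, per day; non-negative.
#' @return An object of class `state_params`: a list with the four inputs
#'   plus derived growth rates `g_hi`, `g_lo` and the rate ratio
#'   `ratio = k_LH / k_HL` (NA when `k_HL = 0`).
#' @seealso [cell_line_fixture()] for calibrated HCT116/SW480 parameter sets.
#' @export
state_params <- function(T_hi, T_lo, k_HL = 0, k_LH = 0) {
  for (v in list(T_hi = T_hi, T_lo = T_lo, k_HL = k_HL, k_LH = k_LH)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("state_params fields must be finite scalars")
    }
  }
  if (T_hi <= 0 || T_lo <= 0) stop("doubling times must be positive")
  if (k_HL < 0 || k_LH < 0) stop("transition rates must be non-negative")
  structure(
    list(
      T_hi = T_hi, T_lo = T_lo, k_HL = k_HL, k_LH = k_LH,
      g_hi = growth_rate(T_hi), g_lo = growth_rate(T_lo),
      ratio = if (k_HL > 0) k_LH / k_HL else NA_real_
    ),
    class = "state_params"
  )
}

#' @export
print.state_params <- function(x, ...) {
  cat("Two-state model parameters\n")
  cat(sprintf("  doubling times: T_hi = %.4g d, T_lo = %.4g d\n", x$T_hi, x$T_lo))
  cat(sprintf("  transition rates: k_HL = %.6g /d, k_LH = %.6g /d (ratio %.4g)\n",
              x$k_HL, x$k_LH, x$ratio))
  cat(sprintf("  per-day switch probabilities: hi->lo %.6g, lo->hi %.6g\n",
              1 - exp(-x$k_HL), 1 - exp(-x$k_LH)))
  invisible(x)
}

# 2x2 rate matrix of the linear ODE system, acting on (H, L)
state_rate_matrix <- function(params) {
  rbind(
    c(params$g_hi - params$k_HL, params$k_LH),
    c(params$k_HL, params$g_lo - params$k_LH)
  )
}

new_timecourse <- function(times, hi, lo) {
  total <- hi + lo
  frac <- ifelse(total > 0, lo / total, NA_real_)
  structure(
    data.frame(
      time_days = times, count_hi = hi, count_lo = lo,
      fraction_lo = frac
    ),
    class = c("timecourse", "data.frame")
  )
}

#' Deterministic trajectory of the two-state model
#'
#' Solves the linear two-state ODE system exactly, via the eigendecomposition
#' of the 2x2 rate matrix (both eigenvalues are real because the off-diagonal
#' switching terms are non-negative).
#'
#' @param params A [state_params()] object.
#' @param init Named numeric vector `c(hi = , lo = )` of initial cell counts;
#'   non-negative, not both zero.
#' @param times Sampling times in days; non-empty, non-negative.
#' @return A `timecourse` data frame with columns `time_days`, `count_hi`,
#'   `count_lo`, `fraction_lo`.
#' @examples
#' p <- cell_line_fixture("HCT116")
#' tc <- simulate_deterministic(p, c(hi = 1e4, lo = 0), times = 0:30)
#' tail(tc$fraction_lo, 1) # approaches the 5% equilibrium
#' @export
simulate_deterministic <- function(params, init, times) {
  stopifnot(inherits(params, "state_params"))
  if (length(times) == 0L) stop("times must be non-empty")
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be non-negative and finite")
  init <- c(hi = unname(init[["hi"]]), lo = unname(init[["lo"]]))
  if (any(init < 0) || sum(init) <= 0) stop("init counts must be non-negative and not both zero")

  A <- state_rate_matrix(params)
  if (params$k_HL == 0 && params$k_LH == 0) {
    # decoupled pure exponentials (also covers the defective equal-rate case)
    hi <- init[["hi"]] * exp(params$g_hi * times)
    lo <- init[["lo"]] * exp(params$g_lo * times)
  } else {
    ev <- eigen(A)
    Vi <- solve(ev$vectors)
    w <- Vi %*% matrix(init, ncol = 1)
    traj <- vapply(times, function(t) {
      as.numeric(ev$vectors %*% (exp(ev$values * t) * w))
    }, numeric(2))
    hi <- pmax(traj[1, ], 0)
    lo <- pmax(traj[2, ], 0)
  }
  new_timecourse(times, hi, lo)
}

#' Stochastic simulation of the two-state model
#'
#' Discrete-time, operator-split counterpart of [simulate_deterministic()].
#' Each step of length `step` days is split symmetrically: cells divide for
#' half a step (probability `2^(step/(2T)) - 1`, chosen so that expected
#' growth matches the doubling time exactly), switch state with probability
#' `1 - exp(-k * step)`, then divide for the remaining half step; all events
#' are independent binomial draws per state. With this symmetric splitting
#' the mean trajectory matches the ODE solution to `O(step^2)`, so
#' Monte-Carlo means are statistically indistinguishable from
#' [simulate_deterministic()] at the default step.
#'
#' @inheritParams simulate_deterministic
#' @param init Named integer vector `c(hi = , lo = )`; total must be >= 1.
#' @param step Step size in days (default 0.05). Every per-step event
#'   probability must stay below 0.2, otherwise an error asks for a smaller
#'   step.
#' @param seed Optional integer seed for reproducibility.
#' @return A `timecourse` data frame sampled at the grid points nearest to
#'   `times`.
#' @export
simulate_stochastic <- function(params, init, times, step = 0.05, seed = NULL) {
  stopifnot(inherits(params, "state_params"))
  if (length(times) == 0L) stop("times must be non-empty")
  init <- c(hi = as.integer(round(init[["hi"]])), lo = as.integer(round(init[["lo"]])))
  if (any(init < 0)) stop("init counts must be non-negative")
  if (sum(init) < 1L) stop("initial population is empty: need at least one cell")
  p_half <- 2^(step / (2 * c(params$T_hi, params$T_lo))) - 1
  p_sw <- 1 - exp(-c(params$k_HL, params$k_LH) * step)
  if (max(c(2 * p_half, p_sw)) >= 0.2) {
    stop("per-step event probability >= 0.2; use a smaller `step`")
  }
  if (!is.null(seed)) set.seed(seed)

  n_steps <- ceiling(max(times) / step + 1e-9)
  grid <- (0:n_steps) * step
  rec_idx <- vapply(times, function(t) which.min(abs(grid - t)), integer(1))

  hi <- init[["hi"]]; lo <- init[["lo"]]
  out_hi <- numeric(length(times)); out_lo <- numeric(length(times))
  hit <- which(rec_idx == 1L)
  out_hi[hit] <- hi; out_lo[hit] <- lo
  for (s in seq_len(n_steps)) {
    hi <- hi + stats::rbinom(1L, hi, p_half[1])
    lo <- lo + stats::rbinom(1L, lo, p_half[2])
    sw_hl <- stats::rbinom(1L, hi, p_sw[1])
    sw_lh <- stats::rbinom(1L, lo, p_sw[2])
    hi <- hi - sw_hl + sw_lh
    lo <- lo - sw_lh + sw_hl
    hi <- hi + stats::rbinom(1L, hi, p_half[1])
    lo <- lo + stats::rbinom(1L, lo, p_half[2])
    hit <- which(rec_idx == s + 1L)
    out_hi[hit] <- hi; out_lo[hit] <- lo
  }
  new_timecourse(grid[rec_idx], out_hi, out_lo)
}

#' Equilibrium EpCAM-lo fraction of the two-state model
#'
#' The lo-state fraction `f = L / (H + L)` obeys
#' \deqn{df/dt = (g_{lo} - k_{LH}) f + k_{HL}(1 - f) - f [g_{hi}(1-f) + g_{lo} f]}
#' whose stationary points solve the quadratic
#' `(g_hi - g_lo) f^2 + (g_lo - g_hi - k_HL - k_LH) f + k_HL = 0`.
#' This returns the unique attracting root in `[0, 1]`, which is the fraction
#' any mixed culture converges to regardless of its starting composition.
#'
#' @param params A [state_params()] object with `k_HL > 0` or `k_LH > 0`.
#' @return The stable equilibrium lo fraction, in `[0, 1]`.
#' @examples
#' equilibrium_lo_fraction(cell_line_fixture("HCT116")) # 0.050
#' @export
equilibrium_lo_fraction <- function(params) {
  stopifnot(inherits(params, "state_params"))
  if (params$k_HL <= 0 && params$k_LH <= 0) {
    stop("equilibrium undefined without switching: need k_HL > 0 or k_LH > 0")
  }
  a <- params$g_hi - params$g_lo
  b <- params$g_lo - params$g_hi - params$k_HL - params$k_LH
  c0 <- params$k_HL
  if (abs(a) < 1e-14) {
    f <- c0 / (params$k_HL + params$k_LH)
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) stop("no real equilibrium root; invalid parameters")
    # the attracting root is where the quadratic crosses from + to - (slope -sqrt(disc))
    f <- (-b - sqrt(disc)) / (2 * a)
  }
  if (f < -1e-12 || f > 1 + 1e-12) stop("no stable root in [0, 1]; invalid parameters")
  min(max(f, 0), 1)
}

#' Calibrate transition rates from a rate ratio and equilibrium fraction
#'
#' Inverts the equilibrium condition of the two-state model: given the two
#' doubling times, the ratio `rho = k_LH / k_HL`, and a target equilibrium
#' lo fraction `f_star`, the unique consistent rates are
#' \deqn{k_{HL} = \frac{f^*(1-f^*)(g_{hi}-g_{lo})}{1 - f^* - \rho f^*},\quad
#'       k_{LH} = \rho\, k_{HL}.}
#' This pins absolute rates from the two printed cell-line summaries (fold
#' ratio of transition probabilities and steady-state lo prevalence) when
#' absolute rates themselves are not reported.
#'
#' @param T_hi,T_lo Doubling times (days); require `T_hi < T_lo` (the hi
#'   state grows faster).
#' @param ratio Target `k_LH / k_HL` (positive).
#' @param f_star Target equilibrium lo fraction in (0, 1).
#' @return A list with `k_HL` and `k_LH` (per day).
#' @examples
#' calibrate_rates(1.00, 1.09, ratio = 8.1, f_star = 0.050)
#' @export
calibrate_rates <- function(T_hi, T_lo, ratio, f_star) {
  if (!(T_hi > 0 && T_lo > 0)) stop("doubling times must be positive")
  if (T_hi >= T_lo) stop("calibration requires T_hi < T_lo (hi state grows faster)")
  if (!(ratio > 0)) stop("rate ratio must be positive")
  if (!(f_star > 0 && f_star < 1)) stop("f_star must lie strictly in (0, 1)")
  denom <- 1 - f_star - ratio * f_star
  if (denom <= 0) {
    stop(sprintf(
      "infeasible calibration: 1 - f_star - ratio*f_star = %.4g must be > 0",
      denom
    ))
  }
  g_hi <- growth_rate(T_hi); g_lo <- growth_rate(T_lo)
  k_HL <- f_star * (1 - f_star) * (g_hi - g_lo) / denom
  if (k_HL <= 0) stop("infeasible calibration: derived k_HL is not positive")
  list(k_HL = k_HL, k_LH = ratio * k_HL)
}

#' Calibrated cell-line parameter fixtures
#'
#' Returns a fully parameterized [state_params()] object for one of the two
#' characterized colon cancer cell lines. Doubling times, transition-rate
#' fold ratios, and equilibrium EpCAM-lo prevalences are the published
#' summary values; the absolute rates are derived from them at call time
#' with [calibrate_rates()]:
#' \itemize{
#'   \item HCT116: `T_hi = 1.00` d, `T_lo = 1.09` d, `k_LH/k_HL = 8.1`,
#'     equilibrium lo fraction 5.0%.
#'   \item SW480: `T_hi = 1.68` d, `T_lo = 1.86` d, `k_LH/k_HL = 4.0`,
#'     equilibrium lo fraction 16.7%.
#' }
#'
#' @param line `"HCT116"` or `"SW480"`.
#' @return A `state_params` object.
#' @export
cell_line_fixture <- function(line = c("HCT116", "SW480")) {
  line <- match.arg(line)
  spec <- switch(line,
    HCT116 = list(T_hi = 1.00, T_lo = 1.09, ratio = 8.1, f_star = 0.050),
    SW480  = list(T_hi = 1.68, T_lo = 1.86, ratio = 4.0, f_star = 0.167)
  )
  k <- calibrate_rates(spec$T_hi, spec$T_lo, spec$ratio, spec$f_star)
  p <- state_params(spec$T_hi, spec$T_lo, k$k_HL, k$k_LH)
  attr(p, "line") <- line
  attr(p, "f_star") <- spec$f_star
  p
}

#' Estimate doubling times from pure-culture growth curves
#'
#' Fits `log2(total cells)` against time by least squares for each pure
#' starting culture and reports the reciprocal slope as the doubling time,
#' the standard first analysis step applied to sorted-culture FACS counts
#' before transition rates are fitted.
#'
#' @param tc_hi,tc_lo `timecourse` data frames (or any data frame with
#'   `time_days`, `count_hi`, `count_lo`) from cultures started pure in the
#'   hi and lo state respectively. Each needs >= 2 time points with positive
#'   totals.
#' @return A list with `T_hi` and `T_lo` in days.
#' @export
fit_doubling_times <- function(tc_hi, tc_lo) {
  fit_one <- function(tc, label) {
    total <- tc$count_hi + tc$count_lo
    keep <- is.finite(total) & total > 0
    if (sum(keep) < 2L) stop(sprintf("culture '%s': need >= 2 time points with positive totals", label))
    y <- log2(total[keep]); t <- tc$time_days[keep]
    if (stats::sd(y) < 1e-12) {
      stop(sprintf("culture '%s': totals do not change over time; doubling time is not identifiable", label))
    }
    slope <- stats::coef(stats::lm(y ~ t))[["t"]]
    if (slope <= 0) stop(sprintf("culture '%s': non-positive growth slope", label))
    1 / slope
  }
  list(T_hi = fit_one(tc_hi, "hi-start"), T_lo = fit_one(tc_lo, "lo-start"))
}

#' Fit transition rates from lo-fraction trajectories
#'
#' Least-squares estimation of the two switching rates of the two-state
#' model from observed EpCAM-lo fraction time courses started from each pure
#' state, with the growth rates fixed at externally estimated doubling times
#' (two-stage fitting: growth first, switching second). The objective is the
#' unweighted sum of squared residuals between observed and model
#' `fraction_lo`, pooled over both starting conditions and all time points;
#' it is minimized by bounded Levenberg-Marquardt with rates constrained to
#' `[0, 2]` per day and started at 0.01 per day.
#'
#' @param tc_hi,tc_lo Data frames with `time_days` and `fraction_lo`
#'   observed from a pure-hi and a pure-lo start.
#' @param T_hi,T_lo Fixed doubling times in days.
#' @return A list with `k_HL`, `k_LH` (per day), `p_HL`, `p_LH` (per-day
#'   transition probabilities `1 - exp(-k)`), `ratio = k_LH/k_HL`,
#'   `objective` (residual sum of squares), and `convergence` info from the
#'   optimizer.
#' @export
fit_transition_rates <- function(tc_hi, tc_lo, T_hi, T_lo) {
  for (tc in list(tc_hi, tc_lo)) {
    if (!all(c("time_days", "fraction_lo") %in% names(tc))) {
      stop("trajectories need columns time_days and fraction_lo")
    }
  }
  obs <- c(tc_hi$fraction_lo, tc_lo$fraction_lo)
  if (stats::sd(tc_hi$fraction_lo) < 1e-10 && stats::sd(tc_lo$fraction_lo) < 1e-10) {
    warning("fraction trajectories carry no time information (constant at equilibrium); ",
            "only a ridge of (k_HL, k_LH) combinations fits the data")
  }
  resid_fun <- function(k) {
    p <- state_params(T_hi, T_lo, k[1], k[2])
    m_hi <- simulate_deterministic(p, c(hi = 1, lo = 0), tc_hi$time_days)$fraction_lo
    m_lo <- simulate_deterministic(p, c(hi = 0, lo = 1), tc_lo$time_days)$fraction_lo
    c(m_hi, m_lo) - obs
  }
  fit <- minpack.lm::nls.lm(
    par = c(k_HL = 0.01, k_LH = 0.01), fn = resid_fun,
    lower = c(0, 0), upper = c(2, 2),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  if (!(fit$info %in% 1:4)) {
    stop(sprintf(
      "transition-rate optimizer did not converge (info %d: %s); best point k_HL=%.6g k_LH=%.6g, objective %.6g",
      fit$info, fit$message, fit$par[1], fit$par[2], fit$deviance
    ))
  }
  k <- fit$par
  list(
    k_HL = unname(k[1]), k_LH = unname(k[2]),
    p_HL = 1 - exp(-unname(k[1])), p_LH = 1 - exp(-unname(k[2])),
    ratio = unname(k[2] / k[1]),
    objective = fit$deviance,
    convergence = list(info = fit$info, message = fit$message, iterations = fit$niter)
  )
}

#' Deterministic competition between subclones
#'
#' Integrates the two-state dynamics of several subclones independently
#' (shared culture, no interaction terms) and reports each clone's share of
#' the total population over time. Because the asymptotic growth rate of the
#' two-state system (the dominant eigenvalue of the rate matrix) decreases
#' with the hi-to-lo switching rate whenever the hi state grows faster,
#' subclones with lower plasticity take over the culture within a few
#' months.
#'
#' @param clones A list of clones; each clone is a list with `clone_id`,
#'   `params` (a [state_params()]), and `init` (named counts `c(hi=, lo=)`).
#'   At least 2 clones.
#' @param horizon Positive horizon in days.
#' @param times Optional explicit sampling times (days); default daily from
#'   0 to `horizon`.
#' @return A data frame with `time_days`, one total-count column and one
#'   frequency column per clone (`freq_<clone_id>`).
#' @export
simulate_clonal_competition <- function(clones, horizon, times = NULL) {
  if (length(clones) < 2L) stop("competition needs >= 2 clones")
  if (is.null(times)) {
    if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be positive (days)")
    times <- seq(0, horizon, by = 1)
  }
  ids <- vapply(clones, function(cl) as.character(cl$clone_id), character(1))
  if (anyDuplicated(ids)) stop("clone_id values must be unique")
  totals <- sapply(clones, function(cl) {
    tc <- simulate_deterministic(cl$params, cl$init, times)
    tc$count_hi + tc$count_lo
  })
  totals <- matrix(totals, nrow = length(times))
  colnames(totals) <- paste0("total_", ids)
  freq <- totals / rowSums(totals)
  colnames(freq) <- paste0("freq_", ids)
  data.frame(time_days = times, totals, freq, check.names = FALSE)
}

#' Asymptotic growth rate of the two-state system
#'
#' Dominant eigenvalue of the 2x2 rate matrix; the long-run exponential
#' growth rate of a mixed culture at its state equilibrium.
#'
#' @param params A [state_params()] object.
#' @return Growth rate per day.
#' @export
asymptotic_growth_rate <- function(params) {
  stopifnot(inherits(params, "state_params"))
  max(eigen(state_rate_matrix(params), only.values = TRUE)$values)
}
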
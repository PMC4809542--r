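#' Myocyte model parameters
#'
#' Constructs the parameter set of the generalized FitzHugh-Nagumo (FHN)
#' myocyte model used throughout the package,
#' \deqn{\frac{dv_m}{dt} = \frac{k(v_m-v_1)(v_2-v_m)(v_m-v_3) - w + \nu h(t)}
#'   {\varepsilon_1 c_m}, \qquad
#'   \frac{dw}{dt} = \varepsilon_2(\beta v_m - \gamma w + \delta),}
#' where \eqn{v_m} is the transmembrane potential (V) and \eqn{w} a recovery
#' variable. Defaults are the published ionic-current parameter set for a
#' pregnant-uterus myocyte.
#'
#' @param c_m membrane capacitance per unit area (F/m^2)
#' @param eps1 time-scale factor of the fast (voltage) equation (Ohm m^2)
#' @param eps2 time-scale factor of the slow (recovery) equation (1/S)
#' @param v1,v2,v3 root potentials of the cubic ionic current (V); must
#'   satisfy `v3 < v2 < v1`
#' @param k gain of the cubic ionic current (1/V^2)
#' @param beta,gamma dimensionless recovery coefficients (`gamma > 0`)
#' @param delta recovery offset (V)
#' @return An object of class `fhn_params` (a named list).
#' @examples
#' p <- fhn_params()
#' resting_potential(p) # about -0.0557 V
#' @export
fhn_params <- function(c_m = 0.01, eps1 = 10, eps2 = 10,
                       v1 = -0.02, v2 = -0.04, v3 = -0.065,
                       k = 7000, beta = 1, gamma = 0.1, delta = 0.052) {
  stopifnot(c_m > 0, eps1 > 0, eps2 > 0, k > 0, gamma > 0)
  if (!(v3 < v2 && v2 < v1))
    stop("root potentials must be ordered v3 < v2 < v1")
  structure(list(c_m = c_m, eps1 = eps1, eps2 = eps2,
                 v1 = v1, v2 = v2, v3 = v3,
                 k = k, beta = beta, gamma = gamma, delta = delta),
            class = "fhn_params")
}

#' @exportS3Method base::print
print.fhn_params <- function(x, ...) {
  cat("Generalized FHN myocyte parameters\n")
  cat(sprintf("  c_m=%g F/m^2  eps1=%g Ohm.m^2  eps2=%g 1/S\n",
              x$c_m, x$eps1, x$eps2))
  cat(sprintf("  v1=%g  v2=%g  v3=%g V   k=%g 1/V^2\n", x$v1, x$v2, x$v3, x$k))
  cat(sprintf("  beta=%g  gamma=%g  delta=%g V\n", x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Pacemaker stimulus waveform
#'
#' The pacemaker drive enters the voltage equation as \eqn{\nu h(t)} with
#' \eqn{h} a unit-amplitude waveform. `amplitude` is the value that appears
#' literally in the voltage equation (the \eqn{1/\varepsilon_1} factor of the
#' tissue-level stimulus current is part of the equation, not of the stored
#' amplitude).
#'
#' @param kind one of `"none"`, `"constant"`, `"sinusoid"`,
#'   `"periodic_heaviside"`
#' @param amplitude stimulus amplitude \eqn{\nu}
#' @param period period T (s) for periodic kinds; the sinusoid frequency is
#'   `1/period`
#' @param duration on-time (s) within each period for `"periodic_heaviside"`;
#'   must not exceed `period`
#' @param phase time offset (s)
#' @return Object of class `stimulus` with an evaluation function `h(t)`.
#' @examples
#' s <- stimulus("periodic_heaviside", amplitude = 0.11,
#'               period = 420, duration = 60)
#' stim_value(s, c(0, 30, 61, 420.5))
#' @export
stimulus <- function(kind = c("none", "constant", "sinusoid",
                              "periodic_heaviside"),
                     amplitude = 0, period = Inf, duration = period,
                     phase = 0) {
  kind <- match.arg(kind)
  if (kind %in% c("sinusoid", "periodic_heaviside")) {
    stopifnot(is.finite(period), period > 0)
    if (kind == "periodic_heaviside") stopifnot(duration <= period)
  }
  structure(list(kind = kind, amplitude = amplitude, period = period,
                 duration = duration, phase = phase),
            class = "stimulus")
}

#' Evaluate the stimulus drive
#'
#' Returns \eqn{\nu h(t)} for a [stimulus()] object at times `t`.
#'
#' @param stim a [stimulus()] object
#' @param t numeric vector of times (s)
#' @return numeric vector of stimulus values.
#' @export
stim_value <- function(stim, t) {
  tt <- t - stim$phase
  switch(stim$kind,
    none = rep(0, length(t)),
    constant = rep(stim$amplitude, length(t)),
    sinusoid = stim$amplitude * sin(2 * pi * tt / stim$period),
    periodic_heaviside =
      stim$amplitude * as.numeric(tt >= 0 & (tt %% stim$period) < stim$duration)
  )
}

#' Right-hand side of the myocyte ODE system
#'
#' Evaluates the time derivatives of the generalized FHN system at a state.
#'
#' @param state numeric length-2 vector `c(v_m, w)` (V)
#' @param t time (s)
#' @param params an [fhn_params()] object
#' @param stim a [stimulus()] object (default: none)
#' @return numeric length-2 vector `c(dv_m/dt, dw/dt)`.
#' @export
fhn_rhs <- function(state, t = 0, params, stim = stimulus("none")) {
  if (!all(is.finite(state)))
    stop("non-finite state: integrator blow-up")
  v <- state[1]; w <- state[2]
  nu_h <- stim_value(stim, t)
  dv <- (params$k * (v - params$v1) * (params$v2 - v) * (v - params$v3) -
           w + nu_h) / (params$eps1 * params$c_m)
  dw <- params$eps2 * (params$beta * v - params$gamma * w + params$delta)
  c(dv, dw)
}

#' Stimulus amplitude sustaining a given equilibrium
#'
#' At an equilibrium \eqn{v_m^*} the recovery nullcline gives
#' \eqn{w^* = (\beta v_m^* + \delta)/\gamma}, and the constant stimulus
#' holding the system there is
#' \deqn{\nu(v_m^*) = -k(v_m^*-v_1)(v_2-v_m^*)(v_m^*-v_3) +
#'   (\beta v_m^* + \delta)/\gamma.}
#'
#' @param vm_star equilibrium potential(s) (V); vectorized
#' @param params an [fhn_params()] object
#' @return stimulus amplitude(s) \eqn{\nu}.
#' @export
equilibrium_stimulus <- function(vm_star, params) {
  -params$k * (vm_star - params$v1) * (params$v2 - vm_star) *
    (vm_star - params$v3) +
    (params$beta * vm_star + params$delta) / params$gamma
}

#' Bifurcation discriminants
#'
#' Two discriminants govern the equilibrium structure of the myocyte model as
#' the stimulus amplitude \eqn{\nu} varies:
#' \deqn{\Delta_1 = (v_1+v_2+v_3)^2 - 3(v_1v_2+v_1v_3+v_2v_3) -
#'   3\beta/(k\gamma),}
#' \deqn{\Delta_2 = (v_1+v_2+v_3)^2 - 3(v_1v_2+v_1v_3+v_2v_3) -
#'   3\varepsilon_1\varepsilon_2 c_m \gamma / k.}
#' `Delta1 < 0` guarantees a unique equilibrium for every \eqn{\nu};
#' `Delta2 > 0` is required for a non-empty window of stimulus amplitudes with
#' an unstable equilibrium surrounded by a limit cycle. Both hold together iff
#' \eqn{\beta > \varepsilon_1\varepsilon_2 c_m \gamma^2}.
#'
#' @param params an [fhn_params()] object
#' @return named numeric vector `c(Delta1=, Delta2=)` (V^2).
#' @export
discriminants <- function(params) {
  S <- params$v1 + params$v2 + params$v3
  P <- params$v1 * params$v2 + params$v1 * params$v3 + params$v2 * params$v3
  c(Delta1 = S^2 - 3 * P - 3 * params$beta / (params$k * params$gamma),
    Delta2 = S^2 - 3 * P -
      3 * params$eps1 * params$eps2 * params$c_m * params$gamma / params$k)
}

#' Stimulus-amplitude window producing a limit cycle
#'
#' When \eqn{\Delta_1 < 0 < \Delta_2}, equilibria with
#' \deqn{\frac{v_1+v_2+v_3-\sqrt{\Delta_2}}{3} < v_m^* <
#'   \frac{v_1+v_2+v_3+\sqrt{\Delta_2}}{3}}
#' are unstable and surrounded by a limit cycle (Hopf mechanism). Mapping the
#' two bounds through [equilibrium_stimulus()] yields the interval of constant
#' stimulus amplitudes \eqn{\nu} that sustain spiking.
#'
#' @param params an [fhn_params()] object
#' @return numeric `c(nu_low, nu_high)` sorted ascending, or a zero-length
#'   numeric when `Delta2 <= 0` (empty window).
#' @examples
#' limit_cycle_range(fhn_params()) # about (0.012, 0.207)
#' @export
limit_cycle_range <- function(params) {
  d <- discriminants(params)
  if (d[["Delta1"]] >= 0)
    stop("Delta1 >= 0: multiple equilibria possible, analysis invalid")
  if (d[["Delta2"]] <= 0) return(numeric(0))
  S <- params$v1 + params$v2 + params$v3
  vm <- (S + c(-1, 1) * sqrt(d[["Delta2"]])) / 3
  sort(equilibrium_stimulus(vm, params))
}

# Unique real equilibrium potential for a given constant stimulus.
# nu(vm) is a cubic with positive leading coefficient; Delta1 < 0 makes it
# strictly monotone, so exactly one real root exists.
fhn_equilibrium <- function(nu, params) {
  d <- discriminants(params)
  if (d[["Delta1"]] >= 0)
    stop("Delta1 >= 0: multiple equilibria possible, analysis invalid")
  # nu(v) = k v^3 - k S v^2 + k P v - k v1 v2 v3 + (beta v + delta)/gamma
  S <- params$v1 + params$v2 + params$v3
  P <- params$v1 * params$v2 + params$v1 * params$v3 + params$v2 * params$v3
  co <- c(-params$k * params$v1 * params$v2 * params$v3 +
            params$delta / params$gamma - nu,
          params$k * P + params$beta / params$gamma,
          -params$k * S,
          params$k)
  r <- polyroot(co)
  real <- r[order(abs(Im(r)))][1]
  if (abs(Im(real)) > 1e-9 * max(1, abs(Re(real))))
    stop("root finding failed: no real equilibrium found")
  Re(real)
}

# Jacobian of the FHN system at (v, w); w does not enter any derivative.
fhn_jacobian <- function(v, params) {
  fp <- params$k *
    ((params$v2 - v) * (v - params$v3) -
     (v - params$v1) * (v - params$v3) +
     (v - params$v1) * (params$v2 - v))
  matrix(c(fp / (params$eps1 * params$c_m), -1 / (params$eps1 * params$c_m),
           params$eps2 * params$beta, -params$eps2 * params$gamma),
         nrow = 2, byrow = TRUE)
}

#' Classify the cell response to a constant stimulus
#'
#' Finds the unique equilibrium for stimulus amplitude `nu` and inspects the
#' eigenvalues of the 2x2 Jacobian there: an unstable equilibrium (positive
#' real part) implies sustained spiking on a limit cycle, a stable one implies
#' a plateau-type (excitable) response.
#'
#' @param nu constant stimulus amplitude
#' @param params an [fhn_params()] object
#' @return `"limit_cycle"` or `"stable_equilibrium"`.
#' @export
classify_stimulus <- function(nu, params) {
  v <- fhn_equilibrium(nu, params)
  ev <- eigen(fhn_jacobian(v, params), only.values = TRUE)$values
  if (max(Re(ev)) > 0) "limit_cycle" else "stable_equilibrium"
}

#' Resting potential of the myocyte model
#'
#' The unique equilibrium with zero stimulus, verified stable.
#'
#' @param params an [fhn_params()] object
#' @return resting potential (V).
#' @export
resting_potential <- function(params) {
  v <- fhn_equilibrium(0, params)
  ev <- eigen(fhn_jacobian(v, params), only.values = TRUE)$values
  if (max(Re(ev)) > 0)
    warning("zero-stimulus equilibrium is unstable for these parameters")
  v
}

#' Linearized oscillation frequency at an equilibrium
#'
#' Angular frequency of the oscillatory linearization at the equilibrium held
#' by stimulus `nu`: the imaginary part of the complex-conjugate eigenvalue
#' pair of the Jacobian. It scales as
#' \eqn{\sqrt{\varepsilon_2/(\varepsilon_1 c_m)}} times a function of the
#' remaining parameters, so spiking can be sped up by lowering
#' \eqn{\varepsilon_1} or raising \eqn{\varepsilon_2}.
#'
#' @param params an [fhn_params()] object
#' @param nu constant stimulus amplitude
#' @return angular frequency \eqn{\omega} (rad/s).
#' @export
hopf_frequency <- function(params, nu) {
  v <- fhn_equilibrium(nu, params)
  ev <- eigen(fhn_jacobian(v, params), only.values = TRUE)$values
  om <- max(Im(ev))
  if (om <= 1e-12 * max(1, max(abs(ev))))
    stop("no oscillatory linearization at this nu (real eigenvalues)")
  om
}

#' Integrate the myocyte model
#'
#' Numerically integrates the two-variable system with `deSolve::lsoda`
#' (adaptive, with automatic switching to an implicit method when the system
#' becomes stiff, as it does for small `eps1`).
#'
#' @param params an [fhn_params()] object
#' @param stim a [stimulus()] object
#' @param duration integration length (s)
#' @param initial initial state `c(v_m, w)`; default is the resting state
#' @param dt output sampling interval (s)
#' @param rtol,atol solver tolerances
#' @return Object of class `cell_trace`: a list with `time`, `vm`, `w`.
#' @examples
#' tr <- simulate_cell(fhn_params(), stimulus("constant", 0.15), duration = 30)
#' spike_frequency(tr)
#' @export
simulate_cell <- function(params, stim = stimulus("none"), duration,
                          initial = NULL, dt = 0.002,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(duration > 0)
  if (is.null(initial)) {
    v0 <- resting_potential(params)
    initial <- c(v0, (params$beta * v0 + params$delta) / params$gamma)
  }
  deriv <- function(t, y, parms) list(fhn_rhs(y, t, params, stim))
  out <- deSolve::ode(y = initial, times = seq(0, duration, by = dt),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || !all(is.finite(out[, 2:3])))
    stop("cell integration failed (solver istate ",
         attr(out, "istate")[1], ")")
  structure(list(time = out[, 1], vm = out[, 2], w = out[, 3]),
            class = "cell_trace")
}

#' @exportS3Method base::print
print.cell_trace <- function(x, ...) {
  cat(sprintf("cell_trace: %d samples over %.3g s, v_m in [%.4g, %.4g] V\n",
              length(x$time), max(x$time), min(x$vm), max(x$vm)))
  invisible(x)
}

# Upward threshold-crossing times with a refractory lockout.
spike_times <- function(time, vm, threshold = -0.035, refractory = 0.2) {
  idx <- which(vm[-1] >= threshold & vm[-length(vm)] < threshold) + 1
  tt <- time[idx]
  keep <- numeric(0); last <- -Inf
  for (t in tt) {
    if (t - last >= refractory) { keep <- c(keep, t); last <- t }
  }
  keep
}

#' Steady-state spike rate of a trace
#'
#' Counts upward crossings of the detection threshold (with a 0.2 s refractory
#' lockout) inside the steady-state window -- by default the final 80% of the
#' trace -- and divides by the window length. Returns 0 for a quiescent trace.
#'
#' @param trace a `cell_trace` from [simulate_cell()]
#' @param threshold detection threshold (V)
#' @param discard fraction of the trace discarded as transient
#' @param refractory minimum spike separation (s)
#' @return spikes per second.
#' @export
spike_frequency <- function(trace, threshold = -0.035, discard = 0.2,
                            refractory = 0.2) {
  t0 <- discard * max(trace$time)
  st <- spike_times(trace$time, trace$vm, threshold, refractory)
  st <- st[st >= t0]
  if (length(st) < 2) return(0)
  length(st) / (max(trace$time) - t0)
}

#' Burst onset times and inter-burst intervals
#'
#' Groups detected spikes into bursts separated by quiescent gaps longer than
#' `gap` and reports the onset time of each burst.
#'
#' @param trace a `cell_trace`
#' @param threshold detection threshold (V)
#' @param gap minimum inter-burst quiescence (s)
#' @return list with `onsets` (s) and `intervals` (s, successive differences).
#' @export
burst_intervals <- function(trace, threshold = -0.035, gap = 60) {
  st <- spike_times(trace$time, trace$vm, threshold)
  if (length(st) == 0)
    return(list(onsets = numeric(0), intervals = numeric(0)))
  onsets <- st[c(TRUE, diff(st) > gap)]
  list(onsets = onsets, intervals = diff(onsets))
}

#' Bifurcation diagram over a stimulus grid
#'
#' For each stimulus amplitude reports the unique equilibrium and its
#' stability; for unstable amplitudes, optionally integrates to the attractor
#' and records the extrema of the limit cycle.
#'
#' @param params an [fhn_params()] object
#' @param nu_grid numeric vector of stimulus amplitudes
#' @param cycles if `TRUE`, integrate unstable cases to measure cycle extrema
#' @param t_settle,t_measure integration lengths (s) for transient and
#'   measurement when `cycles = TRUE`
#' @return data.frame with columns `nu`, `vm_eq`, `stable`, `cycle_min`,
#'   `cycle_max` (`NA` where not applicable).
#' @export
bifurcation_diagram <- function(params, nu_grid, cycles = FALSE,
                                t_settle = 60, t_measure = 60) {
  rows <- lapply(nu_grid, function(nu) {
    v <- fhn_equilibrium(nu, params)
    stable <- classify_stimulus(nu, params) == "stable_equilibrium"
    cmin <- NA_real_; cmax <- NA_real_
    if (!stable && cycles) {
      tr <- simulate_cell(params, stimulus("constant", nu),
                          duration = t_settle + t_measure,
                          initial = c(v + 1e-4,
                                      (params$beta * v + params$delta) /
                                        params$gamma))
      sel <- tr$time >= t_settle
      cmin <- min(tr$vm[sel]); cmax <- max(tr$vm[sel])
    }
    data.frame(nu = nu, vm_eq = v, stable = stable,
               cycle_min = cmin, cycle_max = cmax)
  })
  do.call(rbind, rows)
}
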
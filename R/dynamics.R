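#' One forward-Euler step of the adaptive-threshold variable
#'
#' Integrates `da/dt = (alpha - 1) * a + beta * (S_f + S_r)` for one step:
#' `a + dt * ((alpha - 1) * a + beta * spikes_total)`. Vectorised over `a`
#' and `spikes_total`.
#'
#' @param a Current adaptation value(s); must be finite.
#' @param spikes_total Total spikes emitted this step on both channels
#'   (0, 1 or 2).
#' @param adapt An [adapt_params()] object.
#' @param dt Integration step (ms).
#' @return Updated adaptation value(s). Non-negative whenever `a >= 0`,
#'   `beta >= 0` and `dt * (1 - alpha) <= 1`.
#' @export
#' @examples
#' threshold_step(0, 1, adapt_params(0.9, 0.1), dt = 1) # 0.1
#' threshold_step(1, 1, adapt_params(0.9, 0.1), dt = 1) # fixed point: 1
threshold_step <- function(a, spikes_total, adapt, dt = 1) {
  stopifnot(inherits(adapt, "adapt_params"), dt > 0,
            all(spikes_total %in% c(0, 1, 2)))
  if (!all(is.finite(a)))
    stop("non-finite adaptation variable: numerical divergence upstream")
  a + dt * ((adapt$alpha - 1) * a + adapt$beta * spikes_total)
}

#' Closed-form equilibrium of the adaptive threshold
#'
#' Setting `da/dt = 0` gives `a* = beta / (1 - alpha) * spikes_total` — the
#' value the adaptation variable converges to under a constant spike drive.
#' With `alpha = 0.9`, `beta = 0.1` this is 0, 1 and 2 for 0, 1 and 2
#' sustained spikes per step.
#'
#' @inheritParams threshold_step
#' @return The equilibrium value `a*` (exact, no simulation).
#' @export
threshold_equilibrium <- function(adapt, spikes_total) {
  stopifnot(inherits(adapt, "adapt_params"))
  if (adapt$alpha >= 1)
    stop("no stable equilibrium for alpha >= 1")
  adapt$beta / (1 - adapt$alpha) * spikes_total
}

#' Effective firing threshold with adaptation
#'
#' The firing threshold of an adapting neuron is raised from the base value
#' to `V_th + gamma * a`. With `gamma = 0` the threshold is static
#' (neuronal-plasticity ablation).
#'
#' @param a Adaptation variable value(s), or a [neuron_state()] object.
#' @param params A [neuron_params()] object.
#' @return Effective threshold(s) in mV.
#' @export
effective_threshold <- function(a, params) {
  stopifnot(inherits(params, "neuron_params"))
  if (inherits(a, "neuron_state")) a <- a$a
  params$V_th + params$gamma * a
}

#' State of a single two-channel LIF neuron
#'
#' Holds the feedforward and recurrent membrane potentials, the adaptation
#' variable, the binary spike flags of the current step, and the last spike
#' time of each channel (`-Inf` meaning "never fired").
#'
#' @param V_f,V_r Feedforward / recurrent membrane potentials (mV).
#' @param a Adaptation variable (dimensionless, non-negative).
#' @param S_f,S_r Spike flags of the current step (0 or 1).
#' @param t_last_f,t_last_r Last spike time per channel (ms; `-Inf` = never).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V_f = 0, V_r = 0, a = 0, S_f = 0, S_r = 0,
                         t_last_f = -Inf, t_last_r = -Inf) {
  stopifnot(S_f %in% c(0, 1), S_r %in% c(0, 1), a >= 0 || !is.finite(a))
  structure(list(V_f = V_f, V_r = V_r, a = a, S_f = S_f, S_r = S_r,
                 t_last_f = t_last_f, t_last_r = t_last_r),
            class = "neuron_state")
}

# Internal batched layer state: each field a (n_batch x n_neurons) matrix.
.layer_state <- function(n_batch, n, params) {
  z <- matrix(0, n_batch, n)
  list(V_f = z + params$V_rest, V_r = z, a = z, S_f = z, S_r = z,
       t_last_f = z - Inf, t_last_r = z - Inf)
}

# Core integration step for one layer, vectorised over a batch of
# independent neurons. The step has two sub-phases: the feedforward channel
# is integrated first and tested against the effective threshold; the
# recurrent channel is then integrated and the (updated) total potential is
# tested again, so one time step can yield S_f + S_r = 2.
#
# st        list of (n_batch x n) matrices (.layer_state)
# I_ff/I_rec weighted input currents, (n_batch x n)
# gamma_eff  adaptation coupling actually applied (0 under ablation)
# Returns st plus h_pre, the pre-reset total potential used at the
# feedforward crossing test (the quantity the surrogate gradient gates on).
.layer_step <- function(st, I_ff, I_rec, params, adapt, gamma_eff, t_now) {
  if (!all(is.finite(I_ff)) || !all(is.finite(I_rec)))
    stop("non-finite input currents")
  dtC <- params$dt / params$C
  # leak gate (1 - S) from the previous step's flags, clamped at 0 because
  # S can reach 2 and the leak must never reverse sign
  gate <- pmax(0, 1 - (st$S_f + st$S_r))
  th <- params$V_th + gamma_eff * st$a

  # --- feedforward sub-step ---
  # a channel is refractory through the full period: it may fire again only
  # strictly later than t_spike + tau_ref (so tau_ref = dt blocks exactly
  # the next step)
  refr_f <- (t_now - st$t_last_f) <= params$tau_ref & params$tau_ref > 0
  V_f <- st$V_f + dtC * (-params$g * (st$V_f - params$V_rest) * gate + I_ff)
  V_f[refr_f] <- params$V_reset  # clamp: refractory channel discards input
  h_pre <- V_f + st$V_r
  fire_f <- (h_pre >= th) & !refr_f
  S_f <- fire_f * 1
  V_f[fire_f] <- params$V_reset
  t_last_f <- st$t_last_f
  t_last_f[fire_f] <- t_now

  # --- recurrent sub-step ---
  refr_r <- (t_now - st$t_last_r) <= params$tau_ref & params$tau_ref > 0
  # the recurrent channel carries deviations from rest, so its leak pulls
  # toward 0 (the resting offset lives on the feedforward channel)
  V_r <- st$V_r + dtC * (-params$g * st$V_r * gate + I_rec)
  V_r[refr_r] <- params$V_reset
  fire_r <- ((V_f + V_r) >= th) & !refr_r
  S_r <- fire_r * 1
  V_r[fire_r] <- params$V_reset
  t_last_r <- st$t_last_r
  t_last_r[fire_r] <- t_now

  a <- threshold_step(st$a, S_f + S_r, adapt, params$dt)
  list(V_f = V_f, V_r = V_r, a = a, S_f = S_f, S_r = S_r,
       t_last_f = t_last_f, t_last_r = t_last_r, h_pre = h_pre)
}

#' One integration step of a single two-channel LIF neuron
#'
#' Advances a [neuron_state()] by one step of length `dt`: Euler integration
#' of both membrane channels (leak toward `V_rest` gated by the previous
#' step's spikes, adaptation applied as a raised threshold
#' `V_th + gamma * a`), refractory clamping at `V_reset`, threshold crossing
#' on the total potential `V_f + V_r`, per-channel reset, and the adaptive
#' threshold update.
#'
#' @param state A [neuron_state()].
#' @param ff_current Weighted feedforward input for this step.
#' @param rec_current Weighted recurrent input for this step.
#' @param params A [neuron_params()].
#' @param adapt An [adapt_params()].
#' @param t_now Current time (ms), used for refractory bookkeeping.
#' @return The updated `neuron_state`.
#' @export
#' @examples
#' st <- neuron_state()
#' membrane_step(st, ff_current = 0.6, rec_current = 0,
#'               neuron_params(), adapt_params(), t_now = 1)
membrane_step <- function(state, ff_current, rec_current, params, adapt,
                          t_now) {
  stopifnot(inherits(state, "neuron_state"), t_now >= 0)
  if (!all(is.finite(unlist(state[c("V_f", "V_r", "a")]))))
    stop("non-finite neuron state")
  st <- lapply(state[c("V_f", "V_r", "a", "S_f", "S_r",
                       "t_last_f", "t_last_r")],
               function(x) matrix(x, 1, 1))
  out <- .layer_step(st, matrix(ff_current, 1, 1), matrix(rec_current, 1, 1),
                     params, adapt, params$gamma, t_now)
  neuron_state(V_f = out$V_f[1], V_r = out$V_r[1], a = out$a[1],
               S_f = out$S_f[1], S_r = out$S_r[1],
               t_last_f = out$t_last_f[1], t_last_r = out$t_last_r[1])
}

#' Simulate a single neuron and return its state trace
#'
#' Drives one two-channel LIF neuron with the given current time series and
#' records the full trajectory — the trace behind single-neuron diagnostic
#' plots and the `simulate-neuron` command-line mode.
#'
#' @param ff_current Numeric vector of feedforward currents, one per step.
#' @param rec_current Numeric vector of recurrent currents (recycled to the
#'   length of `ff_current` if scalar).
#' @param params A [neuron_params()].
#' @param adapt An [adapt_params()].
#' @return A data frame with columns `time_ms`, `V_f`, `V_r`, `a`, `S_f`,
#'   `S_r`, one row per step.
#' @export
simulate_neuron <- function(ff_current, rec_current = 0,
                            params = neuron_params(),
                            adapt = adapt_params()) {
  n <- length(ff_current)
  rec_current <- rep_len(rec_current, n)
  st <- neuron_state(V_f = params$V_rest)
  out <- matrix(0, n, 6,
                dimnames = list(NULL, c("time_ms", "V_f", "V_r", "a",
                                        "S_f", "S_r")))
  for (t in seq_len(n)) {
    t_now <- t * params$dt
    st <- membrane_step(st, ff_current[t], rec_current[t], params, adapt,
                        t_now)
    out[t, ] <- c(t_now, st$V_f, st$V_r, st$a, st$S_f, st$S_r)
  }
  as.data.frame(out)
}
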
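#' Membrane and integration parameters of a two-channel LIF neuron
#'
#' Bundles the scalar constants of the leaky integrate-and-fire membrane
#' equation together with the integration step and the adaptation coupling.
#' Defaults are the values used for the spectrogram classification tasks:
#' `C` = 1 uF/cm^2, `g` = 0.2 nS, thresholds and potentials in mV, times in
#' ms, and forward-Euler integration at `dt` = 1 ms.
#'
#' @param C Membrane capacitance (uF/cm^2). Must be positive.
#' @param g Leak conductance (nS). The leak drives the membrane toward
#'   `V_rest` at rate `g/C` per ms.
#' @param V_rest Resting potential (mV).
#' @param V_reset Reset potential after a spike (mV). Must not exceed `V_th`.
#' @param V_th Base firing threshold (mV). The effective threshold is
#'   `V_th + gamma * a` where `a` is the adaptation variable.
#' @param tau_ref Refractory period (ms); during it the spiking channel is
#'   clamped at `V_reset` and cannot fire again.
#' @param dt Integration step (ms).
#' @param gamma Coupling between the adaptation variable and the firing
#'   threshold (dimensionless). `gamma = 0` disables neuronal plasticity.
#' @return An object of class `neuron_params`.
#' @seealso [adapt_params()], [membrane_step()]
#' @export
#' @examples
#' neuron_params()
#' neuron_params(gamma = 0) # static threshold (plasticity ablation)
neuron_params <- function(C = 1, g = 0.2, V_rest = 0, V_reset = 0,
                          V_th = 0.5, tau_ref = 1, dt = 1, gamma = 1) {
  stopifnot(
    is.numeric(C), C > 0,
    is.numeric(g), g >= 0,
    is.numeric(dt), dt > 0,
    is.numeric(tau_ref), tau_ref >= 0,
    V_reset <= V_th,
    is.numeric(gamma), gamma >= 0
  )
  structure(
    list(C = C, g = g, V_rest = V_rest, V_reset = V_reset, V_th = V_th,
         tau_ref = tau_ref, dt = dt, gamma = gamma),
    class = "neuron_params"
  )
}

#' Adaptive-threshold dynamics parameters
#'
#' The adaptation variable `a` of each neuron follows
#' `da/dt = (alpha - 1) * a + beta * (S_f + S_r)`, i.e. it decays at rate
#' `1 - alpha` and is driven up by the neuron's own spikes on the feedforward
#' and recurrent channels. With the defaults `alpha = 0.9`, `beta = 0.1` the
#' stable equilibria are 0, 1 and 2 for 0, 1 and 2 sustained spikes per step.
#'
#' @param alpha Decay coefficient, `0 <= alpha < 1` (strictly below 1 so a
#'   stable equilibrium exists).
#' @param beta Spike-drive coefficient, non-negative.
#' @return An object of class `adapt_params`.
#' @seealso [threshold_step()], [threshold_equilibrium()]
#' @export
adapt_params <- function(alpha = 0.9, beta = 0.1) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha < 1,
            is.numeric(beta), beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "adapt_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters:\n")
  cat(sprintf("  C = %g uF/cm^2, g = %g nS, dt = %g ms\n", x$C, x$g, x$dt))
  cat(sprintf("  V_rest = %g, V_reset = %g, V_th = %g mV\n",
              x$V_rest, x$V_reset, x$V_th))
  cat(sprintf("  tau_ref = %g ms, gamma = %g\n", x$tau_ref, x$gamma))
  invisible(x)
}

#' @export
print.adapt_params <- function(x, ...) {
  cat(sprintf("Adaptive threshold: alpha = %g, beta = %g (a* = %g per spike/step)\n",
              x$alpha, x$beta, x$beta / (1 - x$alpha)))
  invisible(x)
}
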
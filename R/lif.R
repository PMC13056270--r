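#' Leaky integrate-and-fire neuron model
#'
#' Constructs a single leaky integrate-and-fire (LIF) neuron with alpha-shaped
#' excitatory post-synaptic currents and a constant drive current. Driven by a
#' constant supra-rheobase current and no input spikes, the neuron is an
#' isochronous oscillator whose period has the closed form
#' `t_ref + tau_m * log((Vinf - V_reset) / (Vinf - V_th))` with
#' `Vinf = E_L + tau_m * I_e / C_m`; excitatory input spikes can only advance
#' the next firing (a Type I oscillator).
#'
#' Either `I_e` or `rate` must be given; `rate` sets the drive current so the
#' unforced neuron fires at that frequency (see [current_for_rate()]).
#'
#' @param rate intrinsic firing rate in Hz (alternative to `I_e`).
#' @param I_e constant drive current in pA.
#' @param C_m membrane capacitance (pF).
#' @param tau_m membrane time constant (ms).
#' @param E_L resting (leak) potential (mV).
#' @param V_th firing threshold (mV); must exceed `V_reset`.
#' @param V_reset post-spike reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param weight connection weight: the peak amplitude, in pA, of the
#'   alpha-shaped current elicited by one input event.
#' @param tau_syn synaptic rise time (ms): time from input event to the peak
#'   of its post-synaptic current.
#' @param dt integration step (ms); spike times are reported on this grid.
#' @return An object of class `lif_neuron`.
#' @examples
#' nrn <- lif_neuron(rate = 40)
#' intrinsic_period(nrn)  # 25 ms
#' @export
lif_neuron <- function(rate = NULL, I_e = NULL, C_m = 250, tau_m = 10,
                       E_L = -70, V_th = -55, V_reset = -70, t_ref = 2,
                       weight = 1000, tau_syn = 2, dt = 0.1) {
  if (C_m <= 0 || tau_m <= 0 || tau_syn <= 0 || dt <= 0)
    stop("lif_neuron: C_m, tau_m, tau_syn and dt must be positive")
  if (t_ref < 0) stop("lif_neuron: t_ref must be >= 0")
  if (t_ref > 0 && dt > t_ref)
    stop("lif_neuron: dt must not exceed t_ref when t_ref > 0")
  if (V_th <= V_reset) stop("lif_neuron: V_th must exceed V_reset")
  obj <- structure(
    list(C_m = C_m, tau_m = tau_m, E_L = E_L, V_th = V_th,
         V_reset = V_reset, t_ref = t_ref, I_e = NA_real_,
         weight = weight, tau_syn = tau_syn, dt = dt),
    class = "lif_neuron")
  if (!is.null(rate)) {
    if (!is.null(I_e)) stop("lif_neuron: give either 'rate' or 'I_e', not both")
    obj$I_e <- current_for_rate(rate, obj)
  } else if (!is.null(I_e)) {
    obj$I_e <- I_e
  } else {
    stop("lif_neuron: one of 'rate' or 'I_e' is required")
  }
  obj
}

#' @export
print.lif_neuron <- function(x, ...) {
  cat("<lif_neuron> leaky integrate-and-fire with alpha-shaped input currents\n")
  cat(sprintf("  membrane: C_m=%g pF, tau_m=%g ms, E_L=%g mV, V_th=%g mV, V_reset=%g mV, t_ref=%g ms\n",
              x$C_m, x$tau_m, x$E_L, x$V_th, x$V_reset, x$t_ref))
  cat(sprintf("  drive:    I_e=%.4g pA", x$I_e))
  p <- tryCatch(intrinsic_period(x), error = function(e) NA_real_)
  if (is.finite(p)) cat(sprintf("  (intrinsic period %.4g ms, %.4g Hz)", p, 1000 / p))
  cat("\n")
  cat(sprintf("  synapse:  weight=%g pA (alpha peak), tau_syn=%g ms, dt=%g ms\n",
              x$weight, x$tau_syn, x$dt))
  invisible(x)
}

#' Alpha-shaped post-synaptic current kernel
#'
#' The current elicited `t` ms after an input event:
#' `w * e * (t/tau_syn) * exp(-t/tau_syn)` for `t >= 0` and 0 before the
#' event. It peaks at exactly `w` pA at `t = tau_syn`.
#'
#' @param t_since_spike time since the input event (ms); vectorised.
#' @param w peak amplitude (pA).
#' @param tau_syn synaptic rise time (ms).
#' @return Current in pA.
#' @export
alpha_current <- function(t_since_spike, w, tau_syn) {
  if (tau_syn <= 0) stop("alpha_current: tau_syn must be positive")
  ifelse(t_since_spike >= 0,
         w * exp(1) * (t_since_spike / tau_syn) * exp(-t_since_spike / tau_syn),
         0)
}

#' Closed-form free-run period of the unforced neuron
#'
#' With no input events the membrane charges from `V_reset` toward the steady
#' state `Vinf = E_L + tau_m * I_e / C_m`; the inter-spike interval is
#' `t_ref + tau_m * log((Vinf - V_reset) / (Vinf - V_th))`. Below rheobase
#' (`Vinf <= V_th`) the neuron never fires and an error is raised.
#'
#' @param object a [lif_neuron()].
#' @return Period in ms.
#' @export
intrinsic_period <- function(object) {
  stopifnot(inherits(object, "lif_neuron"))
  v_inf <- object$E_L + object$tau_m * object$I_e / object$C_m
  if (v_inf <= object$V_th)
    stop("intrinsic_period: drive below rheobase; the neuron never fires")
  object$t_ref + object$tau_m *
    log((v_inf - object$V_reset) / (v_inf - object$V_th))
}

#' Drive current for a target intrinsic rate
#'
#' Inverts the closed-form free-run period: returns the constant current
#' `I_e` at which the unforced neuron fires at `target_rate` Hz. The period
#' formula is solved exactly for `Vinf` and hence `I_e`.
#'
#' @param target_rate desired intrinsic firing rate in Hz.
#' @param object a [lif_neuron()] supplying the membrane constants (its own
#'   `I_e` is ignored).
#' @return Drive current in pA.
#' @examples
#' nrn <- lif_neuron(I_e = 400)
#' I <- current_for_rate(40, nrn)
#' intrinsic_period(lif_neuron(I_e = I))  # 25 ms
#' @export
current_for_rate <- function(target_rate, object) {
  stopifnot(inherits(object, "lif_neuron"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("current_for_rate: 'target_rate' must be positive (Hz)")
  period <- 1000 / target_rate
  if (period <= object$t_ref)
    stop("current_for_rate: requested period does not exceed the refractory period")
  # period = t_ref + tau_m * log((Vinf - V_reset)/(Vinf - V_th))
  # => with g = exp((period - t_ref)/tau_m):  Vinf = V_th + (V_th - V_reset)/(g - 1)
  gm1 <- expm1((period - object$t_ref) / object$tau_m)
  v_inf <- object$V_th + (object$V_th - object$V_reset) / gm1
  if (v_inf <= object$V_th)
    stop(paste0("current_for_rate: requested rate is too slow to represent ",
                "in double precision with these membrane constants ",
                "(the steady-state potential would be indistinguishable ",
                "from the threshold)"))
  (v_inf - object$E_L) * object$C_m / object$tau_m
}

#' Simulate the forced neuron
#'
#' Integrates the neuron under an external excitatory event train until the
#' requested number of output inter-spike intervals exists. The subthreshold
#' system (membrane plus alpha-current state) is propagated exactly on a fixed
#' grid of step `dt`; input events are snapped to the nearest grid point;
#' on a threshold crossing the spike is reported at that grid point, the
#' potential resets and is clamped for `t_ref` ms while the synaptic currents
#' keep evolving.
#'
#' @param object a [lif_neuron()].
#' @param nsim number of output inter-spike intervals to produce (the output
#'   has `nsim + 1` spikes).
#' @param seed ignored (the forced neuron is deterministic given its input);
#'   present for compatibility with the [stats::simulate()] generic.
#' @param input an `event_seq` of stimulus times (may be `NULL` for a free
#'   run).
#' @param max_duration maximum simulated time in ms before a silent neuron
#'   raises a timeout error. Default: 100 times `nsim` intrinsic periods
#'   (or 1e7 ms below rheobase).
#' @param ... unused.
#' @return An `event_seq` of kind `"spike"`.
#' @examples
#' nrn <- lif_neuron(rate = 40)
#' spikes <- simulate(nrn, nsim = 10)
#' diff(spikes)  # all approx 25 ms
#' @export
simulate.lif_neuron <- function(object, nsim = 100, seed = NULL, input = NULL,
                                max_duration = NULL, ...) {
  n_spikes <- as.integer(nsim) + 1L
  if (n_spikes < 2L) stop("simulate.lif_neuron: 'nsim' must be >= 1")
  steps <- integer(0)
  if (!is.null(input)) {
    if (!inherits(input, "event_seq")) input <- event_seq(input)
    steps <- as.integer(round(as.numeric(input) / object$dt))
    steps <- sort(steps[steps >= 1L])
  }
  if (is.null(max_duration)) {
    p <- tryCatch(intrinsic_period(object), error = function(e) NA_real_)
    max_duration <- if (is.finite(p)) 100 * n_spikes * p else 1e6
  }
  times <- lif_simulate_cpp(object$E_L, object$V_th, object$V_reset,
                            object$tau_m, object$C_m, object$I_e,
                            object$t_ref, object$tau_syn, object$weight,
                            object$dt, steps, n_spikes, max_duration)
  if (length(times) < n_spikes)
    stop(sprintf(paste0("simulate.lif_neuron: only %d of %d spikes produced ",
                        "within max_duration = %g ms (neuron effectively silent)"),
                 length(times), n_spikes, max_duration))
  event_seq(times, kind = "spike")
}
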
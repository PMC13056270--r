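#' Phase response curves for the cricket model
#'
#' A Type II phase response curve (PRC) maps the phase `phi` in `[0, 1)` at
#' which a stimulus falls within the current chirp cycle to a fractional
#' change of that cycle's period: positive values lengthen the period (a
#' stimulus shortly after a chirp delays the next chirp), negative values
#' shorten it (a stimulus shortly before the next chirp advances it).
#'
#' Two parametric shapes are provided. `prc_piecewise()` is a continuous
#' tent-shaped curve with knots `(0, 0) -> (phi_star/2, a) -> (phi_star, 0)
#' -> (1, -b)`: a delay lobe peaking at `a`, a zero crossing exactly at the
#' breakpoint `phi_star`, and an advance lobe reaching `-b` as `phi -> 1`.
#' `prc_sine()` is a smooth alternative built from two half-sine lobes with
#' the same amplitudes and breakpoint. Both satisfy `PRC(0) = 0`, so a
#' stimulus coinciding with a chirp leaves the cycle untouched, and both keep
#' the perturbed period positive for `b < 1`.
#'
#' @param a peak fractional period extension (delay lobe amplitude).
#' @param b peak fractional period contraction (advance lobe amplitude);
#'   must be < 1 so the perturbed period stays positive.
#' @param phi_star breakpoint phase in (0, 1) where delay turns to advance.
#' @param noise_sd standard deviation of additive Gaussian noise applied to
#'   the PRC value at evaluation time (0 = deterministic).
#' @return An object of class `prc_spec`.
#' @export
prc_piecewise <- function(a = 0.5, b = 0.5, phi_star = 0.6, noise_sd = 0) {
  new_prc("piecewise", a, b, phi_star, noise_sd)
}

#' @rdname prc_piecewise
#' @export
prc_sine <- function(a = 0.5, b = 0.5, phi_star = 0.6, noise_sd = 0) {
  new_prc("sine", a, b, phi_star, noise_sd)
}

new_prc <- function(shape, a, b, phi_star, noise_sd) {
  if (a < 0 || b < 0) stop("prc: amplitudes 'a' and 'b' must be >= 0")
  if (b >= 1) stop("prc: 'b' must be < 1 (perturbed period must stay positive)")
  if (phi_star <= 0 || phi_star >= 1) stop("prc: 'phi_star' must lie in (0, 1)")
  if (noise_sd < 0) stop("prc: 'noise_sd' must be >= 0")
  structure(list(shape = shape, a = a, b = b, phi_star = phi_star,
                 noise_sd = noise_sd), class = "prc_spec")
}

#' @export
print.prc_spec <- function(x, ...) {
  cat(sprintf("<prc_spec> Type II (%s): delay peak a=%g, advance peak b=%g, zero crossing phi*=%g, noise sd=%g\n",
              x$shape, x$a, x$b, x$phi_star, x$noise_sd))
  invisible(x)
}

#' Evaluate a phase response curve
#'
#' Returns the fractional period change for stimuli arriving at the given
#' phases, plus (if `noise_sd > 0`) additive Gaussian noise truncated below
#' at -0.95 so the perturbed period always stays positive.
#'
#' @param phase phase(s) in `[0, 1)`.
#' @param spec a `prc_spec` from [prc_piecewise()] or [prc_sine()].
#' @return Fractional period change(s); `> 0` lengthens the period.
#' @export
prc_value <- function(phase, spec) {
  stopifnot(inherits(spec, "prc_spec"))
  if (any(phase < 0 | phase >= 1))
    stop("prc_value: 'phase' must lie in [0, 1)")
  ps <- spec$phi_star
  base <- if (spec$shape == "piecewise") {
    ifelse(phase < ps,
           spec$a * (1 - abs(phase - ps / 2) / (ps / 2)),
           -spec$b * (phase - ps) / (1 - ps))
  } else {
    ifelse(phase < ps,
           spec$a * sin(pi * phase / ps),
           -spec$b * sin(0.5 * pi * (phase - ps) / (1 - ps)))
  }
  if (spec$noise_sd > 0)
    base <- pmax(base + stats::rnorm(length(base), sd = spec$noise_sd), -0.95)
  base
}

#' Cricket stridulation model
#'
#' A generative model of cricket chirping under external stimulation. The
#' cricket chirps with current period `T_cur` (initially the natural period
#' `T0`). A stimulus heard at phase `phi` of the current cycle reschedules
#' this cycle's period to `T_cur * (1 + PRC(phi))`; if several stimuli fall
#' in the same cycle, only the most recent one counts. At every chirp the
#' period carried into the next cycle relaxes toward the natural period by
#' the relaxation rate `rho`: `T_cur <- T + rho * (T0 - T)` where `T` is the
#' period of the cycle just completed (perturbed or not). `rho = 1` restores
#' `T0` immediately after a perturbed period; `rho = 0.2` moves 20% closer to
#' `T0` at each chirp.
#'
#' @param T0 natural chirp period in ms.
#' @param rho relaxation rate in `[0, 1]`.
#' @param prc a `prc_spec`; defaults to [prc_piecewise()] with no noise.
#' @return An object of class `cricket`.
#' @examples
#' ck <- cricket(T0 = 2000, rho = 0.2)
#' chirps <- simulate(ck, nsim = 10)
#' diff(chirps)  # all exactly 2000 ms without stimuli
#' @export
cricket <- function(T0 = 2000, rho = 0.5, prc = prc_piecewise()) {
  if (!is.numeric(T0) || T0 <= 0) stop("cricket: 'T0' must be positive (ms)")
  if (!is.numeric(rho) || rho < 0 || rho > 1)
    stop("cricket: 'rho' must lie in [0, 1]")
  stopifnot(inherits(prc, "prc_spec"))
  structure(list(T0 = T0, rho = rho, prc = prc), class = "cricket")
}

#' @export
print.cricket <- function(x, ...) {
  cat(sprintf("<cricket> stridulation model: natural period T0=%g ms (%.3g Hz), relaxation rho=%g\n",
              x$T0, 1000 / x$T0, x$rho))
  print(x$prc)
  invisible(x)
}

#' Simulate the cricket model
#'
#' Runs the event loop described in [cricket()] and returns the chirp times.
#' The first chirp is emitted at time 0. Stimuli falling exactly on a chirp
#' (phase 0) belong to the new cycle; since `PRC(0) = 0` they leave it
#' unperturbed. If a perturbation would schedule the chirp before the stimulus
#' that caused it, the chirp is emitted immediately after the stimulus
#' (causality guard). Phases of stimuli arriving after the nominal period of
#' an already-delayed cycle are clamped just below 1.
#'
#' @param object a [cricket()].
#' @param nsim number of chirp intervals to produce (output has `nsim + 1`
#'   chirps).
#' @param seed optional integer seed (only relevant when the PRC has noise).
#' @param input an `event_seq` of stimulus times, or `NULL` for a free run.
#' @param ... unused.
#' @return An `event_seq` of kind `"chirp"`.
#' @export
simulate.cricket <- function(object, nsim = 100, seed = NULL, input = NULL, ...) {
  n_chirps <- as.integer(nsim) + 1L
  if (n_chirps < 2L) stop("simulate.cricket: 'nsim' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  stim <- if (is.null(input)) numeric(0) else as.numeric(input)
  T0 <- object$T0
  rho <- object$rho
  guard_eps <- 1e-9 * T0

  chirps <- numeric(n_chirps)
  chirps[1] <- 0
  c_last <- 0
  T_cur <- T0
  j <- 1L
  n_stim <- length(stim)
  for (k in 2:n_chirps) {
    T_sched <- T_cur
    # consume stimuli that fall before the (re)scheduled next chirp;
    # each reschedules the cycle, so later ones overwrite earlier ones
    repeat {
      next_chirp <- c_last + T_sched
      if (j > n_stim || stim[j] >= next_chirp) break
      if (stim[j] >= c_last) {
        phi <- min((stim[j] - c_last) / T_cur, 1 - 1e-12)
        delta <- prc_value(phi, object$prc)
        T_sched <- T_cur * (1 + delta)
        if (c_last + T_sched <= stim[j])          # causality guard
          T_sched <- (stim[j] - c_last) + guard_eps
      }
      j <- j + 1L
    }
    chirps[k] <- c_last + T_sched
    if (chirps[k] <= c_last)
      stop("simulate.cricket: non-positive chirp period (PRC guard violated)")
    # relaxation toward the natural period, applied at every chirp to the
    # period of the cycle just completed
    T_cur <- T_sched + rho * (T0 - T_sched)
    c_last <- chirps[k]
  }
  event_seq(chirps, kind = "chirp")
}
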
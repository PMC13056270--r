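#' @keywords internal
cell_seed <- function(seed, ix, iy) {
  as.integer((as.numeric(seed) * 10007 + ix * 1009 + iy * 7) %% 2147483629)
}

# Number of input events needed to cover a simulation of expected duration
# `dur_ms` at input rate `f_in` (Hz), with generous safety margin.
input_count <- function(f_in, dur_ms, poisson) {
  base <- f_in * dur_ms / 1000
  if (poisson) ceiling(base * 1.6) + 100 else ceiling(base * 1.2) + 10
}

run_sweep_cells <- function(x, y, cell_fun, keep_ratios) {
  nx <- length(x); ny <- length(y)
  entropy <- matrix(NA_real_, nx, ny)
  input_entropy <- matrix(NA_real_, nx, ny)
  bins <- build_bins()
  fractions <- lapply(seq_len(nrow(bins)), function(i) matrix(NA_real_, nx, ny))
  names(fractions) <- bins$label
  status <- matrix("ok", nx, ny)
  seeds <- matrix(NA_integer_, nx, ny)
  ratios <- if (keep_ratios) matrix(vector("list", nx * ny), nx, ny) else NULL
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      res <- tryCatch(cell_fun(ix, iy), error = function(e) e)
      if (inherits(res, "error")) {
        status[ix, iy] <- paste("failed:", conditionMessage(res))
        next
      }
      entropy[ix, iy] <- differential_entropy(res$ratios)
      input_entropy[ix, iy] <- res$input_entropy
      for (lab in bins$label)
        fractions[[lab]][ix, iy] <-
          on_integer_fraction(res$ratios, lab, bins)
      seeds[ix, iy] <- res$seed
      if (keep_ratios) ratios[[ix, iy]] <- res$ratios
    }
  }
  list(entropy = entropy, input_entropy = input_entropy,
       fractions = fractions, status = status, seeds = seeds,
       ratios = ratios)
}

new_rhythm_sweep <- function(experiment, model, x, y, xname, yname,
                             cells, config) {
  structure(c(list(experiment = experiment, model = model, x = x, y = y,
                   xname = xname, yname = yname, config = config), cells),
            class = "rhythm_sweep")
}

#' @export
print.rhythm_sweep <- function(x, ...) {
  fin <- x$entropy[is.finite(x$entropy)]
  cat(sprintf("<rhythm_sweep> experiment %s, %s model: %d x %d grid (%s x %s)\n",
              x$experiment, x$model, length(x$x), length(x$y),
              x$xname, x$yname))
  cat(sprintf("  entropy: %d finite cells in [%.3f, %.3f], %d at -Inf, %d failed\n",
              length(fin), if (length(fin)) min(fin) else NA,
              if (length(fin)) max(fin) else NA,
              sum(is.infinite(x$entropy), na.rm = TRUE),
              sum(x$status != "ok")))
  invisible(x)
}

#' Long-format view of a sweep result
#'
#' One row per grid cell per metric, with columns
#' `x_value,y_value,metric,value,status,seed`. `-Inf` entropies are preserved.
#'
#' @param x a `rhythm_sweep`.
#' @param row.names,optional,... ignored (signature of the generic).
#' @return A data.frame.
#' @export
as.data.frame.rhythm_sweep <- function(x, row.names = NULL, optional = FALSE, ...) {
  mats <- c(list(entropy = x$entropy),
            if (!all(is.na(x$input_entropy))) list(input_entropy = x$input_entropy),
            stats::setNames(x$fractions,
                            paste0("frac_", gsub(":", "_", names(x$fractions)))))
  grid <- expand.grid(ix = seq_along(x$x), iy = seq_along(x$y))
  do.call(rbind, lapply(names(mats), function(m) {
    data.frame(x_value = x$x[grid$ix], y_value = x$y[grid$iy], metric = m,
               value = mats[[m]][cbind(grid$ix, grid$iy)],
               status = x$status[cbind(grid$ix, grid$iy)],
               seed = x$seeds[cbind(grid$ix, grid$iy)])
  }))
}

neuron_cell <- function(ratio, rate, weight, tau_syn, n_intervals, discard,
                        seed, input_type, dt = 0.1, input_ratio_override = NULL) {
  nrn <- lif_neuron(rate = rate, weight = weight, tau_syn = tau_syn, dt = dt)
  period <- intrinsic_period(nrn)
  f_in <- if (is.null(input_ratio_override)) input_rate_for_ratio(ratio, rate)
          else input_ratio_override
  dur <- (n_intervals + discard) * period * 1.5
  if (input_type == "poisson") {
    inp <- generate_poisson(f_in, input_count(f_in, dur, TRUE), seed = seed)
  } else {
    inp <- generate_isochronous(f_in, max(input_count(f_in, dur, FALSE), 2),
                                start = 500 / f_in)
  }
  out <- simulate(nrn, nsim = n_intervals + discard, input = inp)
  r <- event_ratios(unclass(out)[(discard + 1):length(out)])
  ie <- if (input_type == "poisson" && length(inp) >= 12)
    differential_entropy(event_ratios(inp)) else NA_real_
  list(ratios = r, input_entropy = ie, seed = seed)
}

cricket_cell <- function(ratio, rho, T0, prc, n_intervals, discard, seed,
                         input_type) {
  ck <- cricket(T0 = T0, rho = rho, prc = prc)
  f_model <- 1000 / T0
  f_in <- input_rate_for_ratio(ratio, f_model)
  dur <- (n_intervals + discard) * T0 * (1 + prc$a) * 1.5
  if (input_type == "poisson") {
    inp <- generate_poisson(f_in, input_count(f_in, dur, TRUE), seed = seed)
  } else {
    inp <- generate_isochronous(f_in, max(input_count(f_in, dur, FALSE), 2),
                                start = 500 / f_in)
  }
  out <- simulate(ck, nsim = n_intervals + discard, seed = seed, input = inp)
  r <- event_ratios(unclass(out)[(discard + 1):length(out)])
  ie <- if (input_type == "poisson" && length(inp) >= 12)
    differential_entropy(event_ratios(inp)) else NA_real_
  list(ratios = r, input_entropy = ie, seed = seed)
}

#' Experiment 1: random (Poisson) forcing
#'
#' Sweeps the input-frequency-ratio axis against the neuron's intrinsic
#' firing rate (or the cricket's relaxation rate), forcing each cell with a
#' Poisson stimulus train whose mean rate realises the cell's frequency
#' ratio. Each cell records the differential entropy and the seven
#' on-integer fractions of the output rhythm ratios, plus the entropy of the
#' (maximally random) input for the entropy-reduction comparison.
#'
#' @param model `"neuron"` or `"cricket"`.
#' @param ratios input-frequency-ratio grid in (0, 1); the default spans
#'   input:model frequency relations from 1:5 to 5:1.
#' @param rates neuron intrinsic firing-rate grid (Hz); y-axis for the
#'   neuron model.
#' @param rhos cricket relaxation-rate grid in (0, 1]; y-axis for the
#'   cricket model.
#' @param n_intervals output intervals analysed per cell (>= 100).
#' @param discard output intervals dropped as transient before analysis
#'   (default 0: the full sequence is analysed).
#' @param seed top-level seed; per-cell seeds are derived deterministically
#'   from it and the grid indices.
#' @param weight,tau_syn neuron connection weight (pA) and synaptic rise
#'   time (ms).
#' @param T0,prc cricket natural period (ms) and PRC specification.
#' @param keep_ratios if `TRUE`, store each cell's rhythm-ratio vector in the
#'   result (list-matrix `$ratios`), e.g. for density panels.
#' @return A `rhythm_sweep` object.
#' @export
run_experiment1 <- function(model = c("neuron", "cricket"),
                            ratios = seq(1 / 6, 5 / 6, length.out = 21),
                            rates = seq(10, 100, length.out = 21),
                            rhos = seq(0.1, 1, length.out = 21),
                            n_intervals = 150, discard = 0, seed = 1,
                            weight = 1000, tau_syn = 2,
                            T0 = 2000, prc = prc_piecewise(),
                            keep_ratios = FALSE) {
  model <- match.arg(model)
  stopifnot(n_intervals >= 100)
  y <- if (model == "neuron") rates else rhos
  cell_fun <- function(ix, iy) {
    s <- cell_seed(seed, ix, iy)
    if (model == "neuron")
      neuron_cell(ratios[ix], y[iy], weight, tau_syn, n_intervals, discard,
                  s, "poisson")
    else
      cricket_cell(ratios[ix], y[iy], T0, prc, n_intervals, discard,
                   s, "poisson")
  }
  cells <- run_sweep_cells(ratios, y, cell_fun, keep_ratios)
  new_rhythm_sweep("1 (random input)", model, ratios, y,
                   "input frequency ratio",
                   if (model == "neuron") "firing rate (Hz)" else "relaxation rate",
                   cells,
                   list(n_intervals = n_intervals, discard = discard,
                        seed = seed, weight = weight, tau_syn = tau_syn,
                        T0 = T0, prc = prc))
}

#' Experiment 2: isochronous forcing
#'
#' As [run_experiment1()] but each cell is forced with a perfectly
#' isochronous stimulus train at the frequency realising the cell's
#' input-frequency ratio; the first stimulus falls half an input period
#' after time zero so that forcing at ratio 0.5 is not phase-degenerate.
#' Mode locking shows up as entropy minima at small-integer frequency
#' ratios (Arnold-tongue-like stripes).
#'
#' @inheritParams run_experiment1
#' @return A `rhythm_sweep` object.
#' @export
run_experiment2 <- function(model = c("neuron", "cricket"),
                            ratios = seq(1 / 6, 5 / 6, length.out = 21),
                            rates = seq(10, 100, length.out = 21),
                            rhos = seq(0.1, 1, length.out = 21),
                            n_intervals = 150, discard = 0, seed = 1,
                            weight = 1000, tau_syn = 2,
                            T0 = 2000, prc = prc_piecewise(),
                            keep_ratios = FALSE) {
  model <- match.arg(model)
  stopifnot(n_intervals >= 100)
  y <- if (model == "neuron") rates else rhos
  cell_fun <- function(ix, iy) {
    s <- cell_seed(seed, ix, iy)
    if (model == "neuron")
      neuron_cell(ratios[ix], y[iy], weight, tau_syn, n_intervals, discard,
                  s, "isochronous")
    else
      cricket_cell(ratios[ix], y[iy], T0, prc, n_intervals, discard,
                   s, "isochronous")
  }
  cells <- run_sweep_cells(ratios, y, cell_fun, keep_ratios)
  new_rhythm_sweep("2 (isochronous input)", model, ratios, y,
                   "input frequency ratio",
                   if (model == "neuron") "firing rate (Hz)" else "relaxation rate",
                   cells,
                   list(n_intervals = n_intervals, discard = discard,
                        seed = seed, weight = weight, tau_syn = tau_syn,
                        T0 = T0, prc = prc))
}

#' Experiment 3: connection-strength sweep (neuron only)
#'
#' Fixes the isochronous input frequency to the neuron's intrinsic firing
#' rate and sweeps the connection weight against the synaptic rise time.
#'
#' @inheritParams run_experiment1
#' @param weights connection-weight grid (pA, alpha-current peak).
#' @param tau_syns synaptic rise-time grid (ms).
#' @param rate fixed intrinsic firing rate (Hz).
#' @return A `rhythm_sweep` object.
#' @export
run_experiment3 <- function(weights = seq(500, 10000, length.out = 21),
                            tau_syns = seq(2, 8, length.out = 21),
                            rate = 40, n_intervals = 150, discard = 0,
                            seed = 1, keep_ratios = FALSE) {
  stopifnot(n_intervals >= 100)
  cell_fun <- function(ix, iy) {
    s <- cell_seed(seed, ix, iy)
    neuron_cell(ratio = 0.5, rate = rate, weight = weights[ix],
                tau_syn = tau_syns[iy], n_intervals = n_intervals,
                discard = discard, seed = s, input_type = "isochronous",
                input_ratio_override = rate)
  }
  cells <- run_sweep_cells(weights, tau_syns, cell_fun, keep_ratios)
  new_rhythm_sweep("3 (connection strength)", "neuron", weights, tau_syns,
                   "connection weight (pA)", "synaptic rise time (ms)",
                   cells,
                   list(n_intervals = n_intervals, discard = discard,
                        seed = seed, rate = rate))
}

#' Heatmap of a sweep metric
#'
#' Draws the grid of one metric as a filled image. `-Inf` entropy estimates
#' are clipped to the minimum finite value so degenerate (fully locked)
#' cells share the lowest colour.
#'
#' @param x a `rhythm_sweep`.
#' @param metric `"entropy"`, `"input_entropy"`, or a category label such as
#'   `"1:1"` for its on-integer fraction map.
#' @param ... passed to [graphics::image()].
#' @export
plot.rhythm_sweep <- function(x, metric = "entropy", ...) {
  z <- sweep_metric(x, metric)
  fin <- z[is.finite(z)]
  if (length(fin) == 0) stop("plot.rhythm_sweep: no finite values to plot")
  z[z == -Inf] <- min(fin)
  graphics::image(x$x, x$y, z, xlab = x$xname, ylab = x$yname,
                  main = sprintf("experiment %s (%s): %s",
                                 x$experiment, x$model, metric),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

sweep_metric <- function(x, metric) {
  if (metric == "entropy") x$entropy
  else if (metric == "input_entropy") x$input_entropy
  else if (metric %in% names(x$fractions)) x$fractions[[metric]]
  else stop("unknown metric '", metric, "'")
}

#' Write sweep outputs to a directory
#'
#' Writes the long-format results CSV (`sweep.csv`) and, optionally, PNG
#' heatmaps of the entropy and each on-integer fraction map. Re-rendering
#' the same result produces byte-identical CSV output.
#'
#' @param x a `rhythm_sweep`.
#' @param dir output directory (created if missing).
#' @param figures also write PNG heatmaps.
#' @return The directory path, invisibly.
#' @export
write_sweep <- function(x, dir, figures = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(x), file.path(dir, "sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  if (figures) {
    for (m in c("entropy", names(x$fractions))) {
      fn <- file.path(dir, paste0("heatmap_", gsub(":", "-", m), ".png"))
      grDevices::png(fn, width = 900, height = 700, res = 120)
      tryCatch(plot(x, metric = m), finally = grDevices::dev.off())
    }
  }
  invisible(dir)
}
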
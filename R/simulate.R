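# Stochastic simulation of gating and the acquisition chain.

new_state_path <- function(state, class, start, duration, total, seed = NULL,
                           absorbed = FALSE, model_name = NULL) {
  structure(
    tibble::tibble(state = state, class = class, start = start,
                   duration = duration),
    total_duration = total, seed = seed, absorbed = absorbed,
    model_name = model_name,
    class = c("state_path", class(tibble::tibble()))
  )
}

#' Simulate a state path with the Gillespie direct method
#'
#' Draws a continuous-time trajectory of the gating model: the dwell in state
#' i is exponential with rate -q_ii and the next state is chosen with
#' probability proportional to q_ij. The path is truncated at `duration`.
#'
#' @param model A `gating_model`.
#' @param duration Total simulated time (s).
#' @param initial_state Starting state id; default draws from the stationary
#'   distribution.
#' @param seed Optional integer seed (recorded in the result).
#' @return A `state_path` tibble with columns `state`, `class`, `start`,
#'   `duration` (seconds), and attributes `total_duration`, `seed`,
#'   `absorbed` (TRUE if an absorbing state ended the path early).
#' @export
sample_path <- function(model, duration, initial_state = NULL, seed = NULL) {
  stopifnot(is_count(duration))
  q <- q_matrix(model)
  ids <- rownames(q)
  n <- length(ids)
  lambda <- -diag(q)
  targets <- vector("list", n)
  cum <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- which(q[i, ] > 0)
    targets[[i]] <- tg
    if (length(tg)) cum[[i]] <- cumsum(q[i, tg]) / sum(q[i, tg])
  }
  maxt <- max(1L, max(vapply(targets, length, integer(1))))
  cumm <- matrix(1, n, maxt)
  tgm <- matrix(0L, n, maxt)
  for (i in seq_len(n)) {
    tg <- targets[[i]]
    if (length(tg)) {
      cumm[i, seq_along(tg)] <- cum[[i]]
      tgm[i, seq_along(tg)] <- tg
    }
  }
  with_seed_if(seed, {
    if (is.null(initial_state)) {
      pi <- tryCatch(stationary_distribution(q), error = function(e) rep(1 / n, n))
      s <- sample.int(n, 1L, prob = pi)
    } else {
      s <- match(initial_state, ids)
      if (is.na(s)) stop_bad("initial_state not in model")
    }
    res <- .ssa_path(lambda, cumm, tgm, s, duration)
    cls <- model$states$class[match(ids, model$states$state)]
    new_state_path(ids[res$state], cls[res$state], res$start, res$dwell,
                   total = duration, seed = seed, absorbed = res$absorbed,
                   model_name = model$name)
  })
}

# ---------------------------------------------------------------------------
# Traces

new_trace <- function(current, fs, voltage, filter_history = list(),
                      seed = NULL) {
  structure(
    tibble::tibble(current = current),
    fs = fs, voltage = voltage, filter_history = filter_history, seed = seed,
    class = c("sc_trace", class(tibble::tibble()))
  )
}

#' Trace metadata accessors
#'
#' @param trace An `sc_trace`.
#' @return `trace_fs`: sampling rate (Hz); `trace_voltage`: holding potential
#'   (mV); `trace_history`: list of applied acquisition operations;
#'   `trace_time`: sample timestamps (s, left-closed convention: sample k
#'   sits at (k-1)/fs).
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' @rdname trace_fs
#' @export
trace_voltage <- function(trace) attr(trace, "voltage")

#' @rdname trace_fs
#' @export
trace_history <- function(trace) attr(trace, "filter_history")

#' @rdname trace_fs
#' @export
trace_time <- function(trace) (seq_len(nrow(trace)) - 1) / trace_fs(trace)

append_history <- function(trace, op, ...) {
  attr(trace, "filter_history") <- c(trace_history(trace), list(c(list(op = op), list(...))))
  trace
}

#' Render a state path as a sampled current trace
#'
#' The current at each sample instant is the conductance of the occupying
#' state's class times the holding potential (pA = pS * mV * 1e-3). Samples
#' are left-closed: a sample takes the state active at its timestamp.
#'
#' @param path A `state_path`.
#' @param model The generating `gating_model`.
#' @param voltage Holding potential (mV).
#' @param fs Sampling rate (Hz).
#' @return An `sc_trace` tibble with a `current` column (pA).
#' @export
render_trace <- function(path, model, voltage = model$voltage, fs = 1e5) {
  amps <- class_amplitudes(model, voltage)
  lv <- amps[path$class]
  n <- round(attr(path, "total_duration") * fs)
  tt <- (seq_len(n) - 1) / fs
  idx <- findInterval(tt, path$start)
  new_trace(unname(lv[idx]), fs = fs, voltage = voltage,
            filter_history = list(list(op = "render", fs = fs)),
            seed = attr(path, "seed"))
}

#' Gaussian low-pass filter
#'
#' Convolves the trace with a Gaussian kernel whose -3 dB cutoff is `fc`
#' (kernel SD in time sigma_t = 0.1325/fc, truncated at +/-4 sigma and
#' renormalized to unit sum, so the DC gain is exactly 1). Edges are padded
#' by replicating the first/last sample.
#'
#' @param trace An `sc_trace`.
#' @param fc Cutoff frequency (Hz); must be below Nyquist.
#' @return Filtered `sc_trace` with the operation appended to its history.
#' @export
gaussian_filter <- function(trace, fc) {
  fs <- trace_fs(trace)
  if (fc >= fs / 2) stop_bad("fc must be below the Nyquist frequency fs/2")
  sigma <- 0.1325 * fs / fc        # kernel SD in samples
  h <- ceiling(4 * sigma)
  w <- dnorm(seq(-h, h) / sigma)
  w <- w / sum(w)
  x <- trace$current
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  if (length(w) >= 40 && as.numeric(n) * length(w) > 2e7) {
    # FFT convolution for long traces; same kernel, same result
    m <- length(xp) + length(w) - 1L
    m2 <- stats::nextn(m, c(2, 3, 5))
    Y <- Re(stats::fft(stats::fft(c(xp, rep(0, m2 - length(xp)))) *
                         stats::fft(c(w, rep(0, m2 - length(w)))),
                       inverse = TRUE)) / m2
    y <- Y[(2 * h + 1):(2 * h + n)]
  } else {
    yf <- stats::filter(xp, w, sides = 2)
    y <- as.numeric(yf[(h + 1):(h + n)])
  }
  out <- new_trace(y, fs = fs,
                   voltage = trace_voltage(trace),
                   filter_history = trace_history(trace),
                   seed = attr(trace, "seed"))
  append_history(out, "gaussian_filter", fc = fc)
}

#' Resample a trace
#'
#' Downsampling keeps every (fs/fs_new)-th sample starting at the first
#' (decimation by sample picking; the preceding Gaussian stage acts as the
#' anti-alias filter). Upsampling repeats samples (sample-and-hold).
#'
#' @param trace An `sc_trace`.
#' @param fs_new Target sampling rate (Hz); the ratio to the current rate
#'   must be an integer in either direction.
#' @return Resampled `sc_trace`.
#' @export
resample_trace <- function(trace, fs_new) {
  fs <- trace_fs(trace)
  x <- trace$current
  if (isTRUE(all.equal(fs_new, fs))) {
    y <- x
  } else if (fs_new < fs) {
    fac <- fs / fs_new
    if (abs(fac - round(fac)) > 1e-9) stop_bad("fs/fs_new must be an integer for downsampling")
    y <- x[seq(1L, length(x), by = round(fac))]
  } else {
    fac <- fs_new / fs
    if (abs(fac - round(fac)) > 1e-9) stop_bad("fs_new/fs must be an integer for upsampling")
    y <- rep(x, each = round(fac))
  }
  out <- new_trace(y, fs = fs_new, voltage = trace_voltage(trace),
                   filter_history = trace_history(trace),
                   seed = attr(trace, "seed"))
  append_history(out, "resample", fs = fs_new)
}

#' Add Gaussian baseline noise
#'
#' Adds i.i.d. zero-mean Gaussian noise to every sample.
#'
#' @param trace An `sc_trace`.
#' @param sd Noise standard deviation (pA), >= 0.
#' @param seed Optional integer seed.
#' @return Noisy `sc_trace`.
#' @export
add_baseline_noise <- function(trace, sd, seed = NULL) {
  stopifnot(sd >= 0)
  y <- if (sd == 0) trace$current else
    with_seed_if(seed, trace$current + rnorm(nrow(trace), 0, sd))
  out <- new_trace(y, fs = trace_fs(trace), voltage = trace_voltage(trace),
                   filter_history = trace_history(trace),
                   seed = attr(trace, "seed"))
  append_history(out, "baseline_noise", sd = sd, seed = seed)
}

# Per-class extra open-channel noise (classes with fixed_noise and a nonzero
# noise multiplier, e.g. the merged substate): added sample-wise while the
# path dwells in such a class. The class SD is defined at the analysis
# bandwidth; `gain` is the attenuation of the later filter stage.
add_class_noise <- function(trace, path, model, gain = 1, seed = NULL) {
  cl <- model$classes
  cl <- cl[cl$fixed_noise & cl$noise_mult > 0, , drop = FALSE]
  if (!nrow(cl)) return(trace)
  amps <- class_amplitudes(model, trace_voltage(trace))
  tt <- trace_time(trace)
  idx <- findInterval(tt, path$start)
  scls <- path$class[idx]
  y <- trace$current
  with_seed_if(seed, {
    for (k in seq_len(nrow(cl))) {
      sel <- which(scls == cl$label[k])
      if (length(sel)) {
        sd_k <- cl$noise_mult[k] * abs(amps[cl$label[k]]) / gain
        y[sel] <- y[sel] + rnorm(length(sel), 0, sd_k)
      }
    }
  })
  out <- new_trace(y, fs = trace_fs(trace), voltage = trace_voltage(trace),
                   filter_history = trace_history(trace),
                   seed = attr(trace, "seed"))
  append_history(out, "class_noise", classes = cl$label)
}

# White-noise standard-deviation gain of the Gaussian filter stage: noise
# inserted at fs and filtered at fc keeps this fraction of its SD
# (decimation leaves the marginal SD unchanged).
gaussian_noise_gain <- function(fs, fc) {
  sigma <- 0.1325 * fs / fc
  h <- ceiling(4 * sigma)
  w <- dnorm(seq(-h, h) / sigma)
  w <- w / sum(w)
  sqrt(sum(w^2))
}

#' Pass a state path through the acquisition chain
#'
#' Reproduces the acquisition and analysis conditioning of experimental
#' recordings:
#' * `standard`: render at `fs_acquire` (100 kHz), add per-class fixed
#'   open-channel noise, add Gaussian baseline noise, Gaussian-filter at
#'   `fc` (1 kHz), resample at `fs_out` (10 kHz).
#' * `fast_gating`: render at `fs_sim` (400 kHz), filter at `fc_acquire`
#'   (10 kHz) and resample at 100 kHz to emulate digitization of unresolved
#'   flicker, then add baseline noise, filter at 1 kHz and resample at
#'   10 kHz as for acquired traces.
#'
#' @param path A `state_path`.
#' @param model The generating `gating_model`.
#' @param voltage Holding potential (mV).
#' @param mode `"standard"` or `"fast_gating"`.
#' @param noise_sd Baseline noise SD (pA) at the analysis bandwidth, i.e.
#'   measured after the final 1 kHz filter; default 0.05 x the full-open
#'   amplitude at this voltage, a level at which the four sublevels remain
#'   individually resolvable (their spacing is 0.14-0.3 x the full-open
#'   amplitude), as they are in the recordings this generator emulates.
#'   Noise is inserted as broadband Gaussian
#'   noise at the acquisition rate, inflated by the known attenuation of
#'   the subsequent filter stage, so the filtered trace carries the
#'   requested SD. Per-class fixed open-channel noise (e.g. the broad
#'   merged-substate class) is compensated the same way.
#' @param seed Optional integer seed (sub-seeds derived per noise stage).
#' @param fs_sim,fs_acquire,fc_acquire,fc,fs_out Chain parameters (Hz).
#' @return An `sc_trace` at `fs_out` with the complete filter history.
#' @export
acquisition_chain <- function(path, model, voltage = model$voltage,
                              mode = c("standard", "fast_gating"),
                              noise_sd = NULL, seed = NULL,
                              fs_sim = 4e5, fs_acquire = 1e5,
                              fc_acquire = 1e4, fc = 1e3, fs_out = 1e4) {
  mode <- match.arg(mode)
  amps <- class_amplitudes(model, voltage)
  if (is.null(noise_sd)) noise_sd <- 0.05 * max(abs(amps))
  gain <- gaussian_noise_gain(fs_acquire, fc)
  if (mode == "standard") {
    tr <- render_trace(path, model, voltage, fs = fs_acquire)
    tr <- add_class_noise(tr, path, model, gain = gain,
                          seed = child_seed(seed, 1L))
    tr <- add_baseline_noise(tr, noise_sd / gain, seed = child_seed(seed, 2L))
    tr <- gaussian_filter(tr, fc)
    resample_trace(tr, fs_out)
  } else {
    tr <- render_trace(path, model, voltage, fs = fs_sim)
    tr <- gaussian_filter(tr, fc_acquire)
    tr <- resample_trace(tr, fs_acquire)
    tr <- add_baseline_noise(tr, noise_sd / gain, seed = child_seed(seed, 2L))
    tr <- gaussian_filter(tr, fc)
    resample_trace(tr, fs_out)
  }
}

#' Simulate until the stationary amplitude distribution converges
#'
#' Appends simulation chunks until the 1-D Earth Mover's Distance between the
#' cumulative amplitude histograms of consecutive totals falls below `tol`
#' (on the amplitude axis normalized by the full-open current).
#'
#' @param model A `gating_model`.
#' @param voltage Holding potential (mV).
#' @param chunk Chunk duration (s).
#' @param tol Convergence tolerance (normalized EMD).
#' @param seed Optional integer seed.
#' @param max_chunks Error with diagnostics after this many chunks.
#' @param mode,noise_sd,... Passed to [acquisition_chain()].
#' @return An `sc_trace` with attribute `chunks` (number used).
#' @export
simulate_to_stationarity <- function(model, voltage = model$voltage,
                                     chunk = 10, tol = 0.01, seed = NULL,
                                     max_chunks = 30,
                                     mode = "standard", noise_sd = NULL, ...) {
  stopifnot(is_count(chunk), tol > 0)
  amps <- class_amplitudes(model, voltage)
  norm_by <- max(abs(amps))
  grid <- default_amp_grid()
  cur <- numeric(0)
  prev_hist <- NULL
  last_state <- NULL
  fs <- NULL
  last_d <- NA_real_
  for (i in seq_len(max_chunks)) {
    p <- sample_path(model, chunk, initial_state = last_state,
                     seed = child_seed(seed, i))
    last_state <- p$state[nrow(p)]
    tr <- acquisition_chain(p, model, voltage, mode = mode,
                            noise_sd = noise_sd,
                            seed = child_seed(seed, 1000L + i), ...)
    fs <- trace_fs(tr)
    cur <- c(cur, tr$current)
    h <- amplitude_histogram(new_trace(cur, fs, voltage), grid = grid,
                             normalize_by = norm_by)
    if (!is.null(prev_hist)) {
      d <- emd_1d(prev_hist, h)
      last_d <- d
      if (d < tol) {
        out <- new_trace(cur, fs, voltage,
                         filter_history = trace_history(tr), seed = seed)
        attr(out, "chunks") <- i
        return(out)
      }
    } else if (!is.finite(tol)) {
      out <- new_trace(cur, fs, voltage,
                       filter_history = trace_history(tr), seed = seed)
      attr(out, "chunks") <- i
      return(out)
    }
    prev_hist <- h
  }
  stop_bad("amplitude distribution did not converge after ", max_chunks,
           " chunks of ", chunk, " s (last EMD = ", signif(last_d, 3),
           ", tol = ", tol, ")")
}
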
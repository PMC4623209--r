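# Segmental k-means idealization and event-sequence analyses.

new_event_seq <- function(class, start, duration, amplitude, dead_time = 0,
                          voltage = NA_real_, fs = NA_real_,
                          classes = conductance_classes(), converged = TRUE,
                          flags = character(0)) {
  structure(
    tibble::tibble(class = class, start = start, duration = duration,
                   amplitude = amplitude),
    dead_time = dead_time, voltage = voltage, fs = fs,
    event_classes = classes, converged = converged, flags = flags,
    class = c("event_seq", class(tibble::tibble()))
  )
}

#' Convert a simulated state path to a ground-truth event sequence
#'
#' Aggregates the state path by conductance class (merging successive dwells
#' in states of the same class) and attaches the noise-free class amplitudes.
#'
#' @param path A `state_path`.
#' @param model The generating `gating_model`.
#' @param voltage Holding potential (mV).
#' @return An `event_seq` tibble.
#' @export
path_to_events <- function(path, model, voltage = model$voltage) {
  r <- rle(path$class)
  ends <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends, -1L) + 1L)
  st <- path$start[starts_idx]
  dur <- (path$start + path$duration)[ends] - st
  amps <- class_amplitudes(model, voltage)
  new_event_seq(r$values, st, dur, unname(amps[r$values]),
                voltage = voltage, classes = model$classes)
}

#' Idealize a trace by segmental k-means
#'
#' Alternates Viterbi segmentation of the samples under a Gaussian-emission
#' aggregated hidden Markov model (one emission class per conductance class)
#' with re-estimation of class mean amplitudes, class noise SDs (except for
#' classes flagged `fixed_noise`) and the class transition probabilities,
#' until the fraction of samples changing assignment drops below `tol` or
#' `max_iter` is reached. Emissions are treated as independent Gaussians;
#' the sample correlation induced by filtering is ignored in the likelihood,
#' as is standard for segmental k-means.
#'
#' Class identity is anchored by the initial amplitude ordering (means are
#' re-estimated but classes never swap), which prevents label switching.
#' Classes never visited by the Viterbi path keep their initial parameters
#' and are reported empty.
#'
#' @param trace An `sc_trace` (filtered/resampled).
#' @param model A `gating_model` supplying the classes, initial amplitudes
#'   and noise settings.
#' @param max_iter Maximum SKM iterations.
#' @param tol Convergence threshold on the fraction of reassigned samples.
#' @param fixed_mean If `TRUE`, class means are held at their initial values.
#' @param init_sd Optional initial noise SD (pA); default is a robust
#'   estimate (MAD) of the trace.
#' @return An `event_seq` with one row per dwell (class, start and duration
#'   in seconds, mean sample amplitude), dead time 0, and attributes
#'   `converged` and `class_params` (fitted means/SDs).
#' @export
skm_idealize <- function(trace, model, max_iter = 20, tol = 1e-3,
                         fixed_mean = FALSE, init_sd = NULL) {
  x <- trace$current
  fs <- trace_fs(trace)
  voltage <- trace_voltage(trace)
  cl <- model$classes[order(class_rank(model$classes$label)), , drop = FALSE]
  k <- nrow(cl)
  amps <- cl$conductance * voltage * 1e-3
  base_sd <- init_sd %||% max(mad(x), 1e-4)
  sds <- ifelse(cl$fixed_noise & cl$noise_mult > 0,
                pmax(cl$noise_mult * abs(amps), 1e-6), base_sd)
  mu <- amps
  A <- matrix(0.01 / max(k - 1, 1), k, k)
  diag(A) <- 0.99
  logpi <- rep(log(1 / k), k)
  prev_path <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    path <- .viterbi_gauss(x, mu, sds, log(A), logpi)
    if (!is.null(prev_path)) {
      changed <- mean(path != prev_path)
      if (changed < tol) { converged <- TRUE; prev_path <- path; break }
    }
    prev_path <- path
    for (j in seq_len(k)) {
      sel <- path == j
      nj <- sum(sel)
      if (nj > 1) {
        if (!fixed_mean) mu[j] <- mean(x[sel])
        if (!cl$fixed_noise[j]) sds[j] <- max(sd(x[sel]), 1e-6)
      }
    }
    tab <- matrix(0.5, k, k) # light prior keeps A positive
    from <- path[-length(path)]
    to <- path[-1]
    for (j in seq_len(k)) {
      sel <- from == j
      if (any(sel)) tab[j, ] <- tab[j, ] + tabulate(to[sel], nbins = k)
    }
    A <- tab / rowSums(tab)
  }
  path <- prev_path
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends, -1L) + 1L)
  amp_ev <- vapply(seq_along(ends), function(i)
    mean(x[starts_idx[i]:ends[i]]), numeric(1))
  flags <- character(0)
  if (!converged) flags <- c(flags, "not_converged")
  if (length(unique(path)) < k) flags <- c(flags, "empty_classes")
  ev <- new_event_seq(cl$label[r$values], (starts_idx - 1L) / fs,
                      r$lengths / fs, amp_ev, voltage = voltage, fs = fs,
                      classes = cl, converged = converged, flags = flags)
  attr(ev, "class_params") <- tibble::tibble(class = cl$label, mean = mu, sd = sds)
  ev
}

#' Impose a dead time on an event sequence
#'
#' Events shorter than `t_dead` are unresolvable and are merged left to
#' right into a neighbouring event; durations concatenate and amplitudes
#' combine as duration-weighted means. The scan repeats until all events are
#' at least `t_dead` long, then adjacent same-class events coalesce. The
#' operation is idempotent and never increases the event count.
#'
#' Two merge conventions are supported. `"nearest"` (the default) absorbs
#' the brief event into the neighbour whose class conductance is nearer,
#' ties going to the preceding neighbour — the natural rule for idealized
#' data, where a brief flanked event most plausibly belongs to the nearer
#' level, and the rule that pairs best with the missed-event-corrected
#' likelihood on chain topologies. `"preceding"` always extends the
#' preceding event (the classic apparent-dwell bookkeeping).
#'
#' @param events An `event_seq` with contiguous events.
#' @param t_dead Dead time (s); default 0.6 ms.
#' @param rule Merge convention, `"nearest"` or `"preceding"`.
#' @return An `event_seq` with `dead_time` recorded.
#' @export
apply_dead_time <- function(events, t_dead = 6e-4,
                            rule = c("nearest", "preceding")) {
  rule <- match.arg(rule)
  cls <- events$class
  dur <- events$duration
  amp <- events$amplitude
  cond <- setNames(attr(events, "event_classes")$conductance,
                   attr(events, "event_classes")$label)
  n <- length(cls)
  flags <- attr(events, "flags")
  if (sum(dur) < t_dead) {
    # whole record unresolvable: single event of the dominant class
    j <- which.max(tapply(dur, cls, sum))
    lab <- names(tapply(dur, cls, sum))[j]
    out <- new_event_seq(lab, events$start[1], sum(dur),
                         sum(amp * dur) / sum(dur), dead_time = t_dead,
                         voltage = attr(events, "voltage"),
                         fs = attr(events, "fs"),
                         classes = attr(events, "event_classes"),
                         converged = attr(events, "converged"),
                         flags = c(flags, "shorter_than_dead_time"))
    return(out)
  }
  # doubly-linked list so each merge is O(1)
  nxt <- c(seq_len(n)[-1], 0L)
  prv <- c(0L, seq_len(n)[-n])
  alive <- rep(TRUE, n)
  starts <- events$start
  merge_into <- function(i, j) {
    # event i absorbed by neighbour j
    tot <- dur[i] + dur[j]
    amp[j] <<- (amp[i] * dur[i] + amp[j] * dur[j]) / tot
    dur[j] <<- tot
    if (prv[i] == j) {            # j precedes i
      nxt[j] <<- nxt[i]
      if (nxt[i]) prv[nxt[i]] <<- j
    } else {                      # j follows i
      prv[j] <<- prv[i]
      if (prv[i]) nxt[prv[i]] <<- j
      starts[j] <<- starts[i]     # j now begins where i did
    }
    alive[i] <<- FALSE
  }
  repeat {
    changed <- FALSE
    i <- which(alive)[1]
    while (i) {
      if (dur[i] < t_dead) {
        p <- prv[i]; s <- nxt[i]
        if (p == 0L && s == 0L) break
        if (p == 0L) j <- s
        else if (s == 0L) j <- p
        else if (rule == "preceding") j <- p
        else {
          dp <- abs(cond[cls[p]] - cond[cls[i]])
          ds <- abs(cond[cls[s]] - cond[cls[i]])
          j <- if (ds < dp) s else p   # tie -> preceding neighbour
        }
        merge_into(i, j)
        changed <- TRUE
        i <- j
      } else {
        i <- nxt[i]
      }
    }
    if (!changed) break
  }
  keep <- which(alive)
  cls2 <- cls[keep]; dur2 <- dur[keep]; amp2 <- amp[keep]; st2 <- starts[keep]
  # coalesce adjacent same-class events
  r <- rle(cls2)
  ends <- cumsum(r$lengths)
  sidx <- c(1L, head(ends, -1L) + 1L)
  dur3 <- vapply(seq_along(ends), function(i) sum(dur2[sidx[i]:ends[i]]), numeric(1))
  amp3 <- vapply(seq_along(ends), function(i) {
    w <- dur2[sidx[i]:ends[i]]
    sum(amp2[sidx[i]:ends[i]] * w) / sum(w)
  }, numeric(1))
  new_event_seq(r$values, st2[sidx], dur3, amp3, dead_time = t_dead,
                voltage = attr(events, "voltage"), fs = attr(events, "fs"),
                classes = attr(events, "event_classes"),
                converged = attr(events, "converged"), flags = flags)
}

#' Per-class open probability of an event sequence
#'
#' Po of a class is the fraction of the total idealized record duration
#' spent in that class. With `by = "merged"` all substate classes (S1-S4 and
#' the merged S) are pooled into a single `S` class.
#'
#' @param events An `event_seq`.
#' @param by `"class"` or `"merged"`.
#' @return Tibble with columns `class` and `po` (sums to 1).
#' @export
compute_po <- function(events, by = c("class", "merged")) {
  by <- match.arg(by)
  stopifnot(nrow(events) > 0)
  cls <- events$class
  if (by == "merged") cls <- ifelse(grepl("^S", cls), "S", cls)
  tb <- tibble::tibble(class = cls, duration = events$duration) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(po = sum(.data$duration), .groups = "drop")
  tb$po <- tb$po / sum(events$duration)
  tb[order(class_rank(tb$class)), ]
}

#' Open-probability diary
#'
#' Po per class computed in consecutive non-overlapping windows, mirroring
#' diary plots used to check gating stability over a recording.
#'
#' @param events An `event_seq`.
#' @param window Window length (s).
#' @return Tibble with `window_start`, `class`, `po`.
#' @export
po_diary <- function(events, window = 5) {
  stopifnot(is_count(window))
  t0 <- events$start
  t1 <- events$start + events$duration
  total <- max(t1)
  edges <- seq(0, total, by = window)
  if (max(edges) < total) edges <- c(edges, total)
  out <- purrr::map_dfr(seq_len(length(edges) - 1L), function(w) {
    a <- edges[w]; b <- edges[w + 1]
    ov <- pmin(t1, b) - pmax(t0, a)
    sel <- ov > 0
    tibble::tibble(window_start = a, class = events$class[sel], dur = ov[sel]) |>
      dplyr::group_by(.data$window_start, .data$class) |>
      dplyr::summarise(po = sum(.data$dur) / (b - a), .groups = "drop")
  })
  out[order(out$window_start, class_rank(out$class)), ]
}

#' Mean class currents of a record
#'
#' For each conductance class: the mean sample amplitude while dwelling in
#' the class, the class Po, and the class's mean contribution to the
#' whole-record current (dwell-weighted mean amplitude x Po).
#'
#' @param trace The `sc_trace` the events were idealized from.
#' @param events The aligned `event_seq`.
#' @return Tibble with `class`, `mean_amp_dwelling` (pA), `po`, and
#'   `mean_current` (pA contribution over the whole record).
#' @export
mean_class_currents <- function(trace, events) {
  tt <- trace_time(trace)
  idx <- findInterval(tt, events$start)
  cls <- events$class[idx]
  po <- compute_po(events)
  amp <- tibble::tibble(class = cls, current = trace$current) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_amp_dwelling = mean(.data$current), .groups = "drop")
  out <- dplyr::left_join(po, amp, by = "class")
  out$mean_amp_dwelling[is.na(out$mean_amp_dwelling)] <- 0
  out$mean_current <- out$mean_amp_dwelling * out$po
  out[, c("class", "mean_amp_dwelling", "po", "mean_current")]
}

#' Apparent conductance of a single-sublevel record
#'
#' For a record that consists of one sojourn in a single (possibly
#' flicker-generated) sublevel — e.g. the output of an isolated fast
#' closed/open couplet — the idealization is used to verify that one
#' substate class dominates, and the apparent amplitude is then the mean
#' current over the whole sojourn. Averaging over the full sojourn rather
#' than over sublevel-classified samples only avoids the boundary-truncation
#' bias that class-masked means suffer when noise excursions longer than the
#' dead time are captured by neighbouring amplitude classes.
#'
#' @param trace The `sc_trace`.
#' @param events Dead-time-processed idealization of `trace`.
#' @param voltage Holding potential (mV); default from the trace.
#' @param min_po Minimum time fraction the dominant substate class must
#'   cover for the record to count as a single sublevel sojourn.
#' @return Apparent conductance in pS.
#' @export
apparent_sublevel_conductance <- function(trace, events,
                                          voltage = trace_voltage(trace),
                                          min_po = 0.5) {
  po <- compute_po(events)
  dom <- po$class[which.max(po$po)]
  if (!grepl("^S", dom))
    stop_bad("dominant class is '", dom, "', not a sublevel: the record is ",
             "not a single sublevel sojourn")
  if (max(po$po) < min_po)
    stop_bad("dominant sublevel class covers only ",
             signif(100 * max(po$po), 3), "% of the record")
  1000 * mean(trace$current) / voltage
}

#' Transition counts between conductance classes
#'
#' Counts adjacent-event class pairs of a dead-time-processed event
#' sequence. The result is the matrix form of the transition-frequency chord
#' diagrams used to identify preferred gating routes.
#'
#' @param events An `event_seq` (dead time applied).
#' @return A `transition_matrix`: integer class x class matrix with zero
#'   diagonal and attribute `exit_totals` (row sums).
#' @export
transition_counts <- function(events) {
  labs <- attr(events, "event_classes")$label
  labs <- labs[order(class_rank(labs))]
  m <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (nrow(events) > 1) {
    from <- events$class[-nrow(events)]
    to <- events$class[-1]
    for (i in seq_along(from)) m[from[i], to[i]] <- m[from[i], to[i]] + 1L
  }
  structure(m, exit_totals = rowSums(m), class = c("transition_matrix", "matrix"))
}

#' Export a transition matrix for chord-diagram tools
#'
#' Writes a tab-separated class x class count table with a label header,
#' directly consumable by chord-diagram software.
#'
#' @param x A `transition_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chord_matrix <- function(x, path) {
  df <- as.data.frame(unclass(x))
  df <- cbind(class = rownames(x), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
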
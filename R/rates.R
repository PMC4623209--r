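# Maximum interval likelihood (MIL) rate estimation with first-order
# missed-event correction of the generator matrix.

# Partition of a model's Q matrix by conductance class, in conductance order.
q_partition <- function(model) {
  q <- q_matrix(model)
  cls <- model$states$class
  labs <- unique(cls)
  labs <- labs[order(class_rank(labs))]
  idx <- lapply(labs, function(l) which(cls == l))
  names(idx) <- labs
  list(q = q, labels = labs, idx = idx)
}

# Dead-time-corrected within-class blocks and class-coupling matrices
# (first-order missed-event treatment in the Roux-Sauve style):
# * within-class generator: excursions out of class a that return within the
#   dead time are folded in,
#     Q'_aa = Q_aa + Q_a,ac (I - expm(Q_ac,ac t_d)) (-Q_ac,ac)^-1 Q_ac,a
#   with ac = complement of a;
# * coupling for an observed a -> b transition: the direct jump plus
#   unresolved excursions through the remaining classes R = complement of
#   {a, b} that end by entering b,
#     A_ab = (Q_ab + Q_a,R (I - expm(Q_RR t_d)) (-Q_RR)^-1 Q_R,b)
#            expm(Q_bb t_d);
# * the dwell factor is expm(Q'_aa (t - t_d)), so total time is conserved.
# integral_0^td expm(Q s) ds via the augmented exponential (no inverse, so
# it is defined even when Q is singular)
expm_integral <- function(q, td) {
  n <- nrow(q)
  aug <- rbind(cbind(q, diag(n)), matrix(0, n, 2 * n))
  expm_small(aug * td)[seq_len(n), n + seq_len(n), drop = FALSE]
}

mil_blocks <- function(model, t_dead, correct = TRUE) {
  part <- q_partition(model)
  q <- part$q
  k <- length(part$labels)
  Qblocks <- vector("list", k)
  Amats <- vector("list", k * k)
  corrected <- correct && t_dead > 0
  for (a in seq_len(k)) {
    ia <- part$idx[[a]]
    Qaa <- q[ia, ia, drop = FALSE]
    if (corrected) {
      ic <- setdiff(seq_len(nrow(q)), ia)
      Qac <- q[ia, ic, drop = FALSE]
      Qcc <- q[ic, ic, drop = FALSE]
      Qca <- q[ic, ia, drop = FALSE]
      Qblocks[[a]] <- Qaa + Qac %*% expm_integral(Qcc, t_dead) %*% Qca
    } else {
      Qblocks[[a]] <- Qaa
    }
  }
  for (a in seq_len(k)) {
    ia <- part$idx[[a]]
    for (b in seq_len(k)) {
      if (a == b) { Amats[[(a - 1) * k + b]] <- matrix(0, 0, 0); next }
      ib <- part$idx[[b]]
      Qab <- q[ia, ib, drop = FALSE]
      if (corrected) {
        ir <- setdiff(seq_len(nrow(q)), c(ia, ib))
        if (length(ir)) {
          Qar <- q[ia, ir, drop = FALSE]
          Qrr <- q[ir, ir, drop = FALSE]
          Qrb <- q[ir, ib, drop = FALSE]
          Qab <- Qab + Qar %*% expm_integral(Qrr, t_dead) %*% Qrb
        }
        Qbb <- q[ib, ib, drop = FALSE]
        Qab <- Qab %*% expm_small(Qbb * t_dead)
      }
      Amats[[(a - 1) * k + b]] <- Qab
    }
  }
  list(Qblocks = Qblocks, Amats = Amats, labels = part$labels,
       idx = part$idx, q = q)
}

#' Interval log-likelihood of an event sequence under a gating model
#'
#' Aggregated-Markov likelihood of an idealized dwell sequence: the Q matrix
#' is partitioned by conductance class; a dwell of duration t in class a
#' propagates the state-probability vector through the within-class block
#' and each observed class transition applies the corresponding coupling
#' block. With `correct = TRUE` the within-class generator carries a
#' first-order dead-time correction that accounts for excursions too brief
#' to resolve, dwell durations are shortened by the dead time and couplings
#' carry the compensating `expm(Q_bb t_dead)` factor, so total time is
#' conserved and the corrected likelihood converges to the uncorrected one
#' as `t_dead -> 0`. Propagation is rescaled every step, so the returned
#' value is finite for any valid input.
#'
#' Entry probabilities for the first dwell are the stationary distribution
#' conditioned on the first event's class (records begin mid-activity).
#'
#' @param events An `event_seq` processed with the same dead time.
#' @param model A `gating_model` whose classes cover the event classes.
#' @param t_dead Dead time (s); defaults to the events' recorded dead time.
#' @param correct Apply the missed-event correction.
#' @return The log-likelihood (scalar).
#' @export
mil_loglikelihood <- function(events, model, t_dead = NULL, correct = TRUE) {
  t_dead <- t_dead %||% attr(events, "dead_time") %||% 0
  bl <- mil_blocks(model, t_dead, correct = correct)
  cls <- match(events$class, bl$labels)
  if (anyNA(cls))
    stop_bad("event classes absent from model: ",
             paste(unique(events$class[is.na(cls)]), collapse = ", "))
  dur <- events$duration
  if (correct && t_dead > 0) dur <- pmax(dur - t_dead, 0)
  pi <- tryCatch(stationary_distribution(bl$q),
                 error = function(e) rep(1 / nrow(bl$q), nrow(bl$q)))
  ia <- bl$idx[[cls[1]]]
  entry <- pi[ia]
  if (sum(entry) <= 0) entry <- rep(1, length(ia))
  entry <- entry / sum(entry)
  .mil_loglik(bl$Qblocks, bl$Amats, as.integer(cls), dur, as.numeric(entry))
}

set_model_rates <- function(model, rates) {
  model$rates$rate <- rates
  model
}

# Moment-based initial rates: class-level transition counts over class time,
# split over the parallel edges; within-class edges start at the inverse
# mean class dwell.
moment_init_rates <- function(events, model) {
  st <- model$states
  cls_time <- tapply(events$duration, events$class, sum)
  n <- nrow(events)
  from <- events$class[-n]
  to <- events$class[-1]
  cnt <- table(factor(from, unique(st$class)), factor(to, unique(st$class)))
  init <- numeric(nrow(model$rates))
  for (e in seq_len(nrow(model$rates))) {
    ca <- st$class[match(model$rates$from[e], st$state)]
    cb <- st$class[match(model$rates$to[e], st$state)]
    Ta <- cls_time[ca]
    if (is.na(Ta) || Ta <= 0) { init[e] <- 1; next }
    if (ca == cb) {
      nd <- sum(events$class == ca)
      init[e] <- max(nd / Ta, 1e-2)
    } else {
      nab <- cnt[ca, cb]
      ne <- sum(st$class[match(model$rates$from, st$state)] == ca &
                  st$class[match(model$rates$to, st$state)] == cb)
      init[e] <- max(nab / Ta / max(ne, 1), 1e-2)
    }
  }
  init
}

#' Fit rate constants by maximum interval likelihood
#'
#' Maximizes [mil_loglikelihood()] over the model's directed rates in
#' log-rate space (box bounds, default 1e-3 to 1e6 s^-1) with L-BFGS-B from
#' a moment-based initialization plus the model's current rates, keeping the
#' better optimum. Edges between class pairs never observed to exchange in
#' the data are held at the lower bound and flagged unidentifiable.
#'
#' @param events An `event_seq` (dead time applied).
#' @param model A `gating_model` defining topology and starting rates.
#' @param t_dead Dead time (s); defaults to the events' recorded value.
#' @param correct Apply the missed-event correction.
#' @param bounds Rate bounds (s^-1).
#' @param compute_se Numerical-Hessian standard errors for the log-rates.
#' @param seed Unused placeholder for interface stability (the optimizer is
#'   deterministic given its starts).
#' @return A `rate_fit`: list with the fitted `model`, `loglik`, `t_dead`,
#'   `voltage`, `records_used`, `unidentifiable` edge labels, `converged`,
#'   and optionally `se` (per-edge SEs of log-rates).
#' @export
fit_rates <- function(events, model, t_dead = NULL, correct = TRUE,
                      bounds = c(1e-3, 1e6), compute_se = FALSE, seed = NULL) {
  fit_rates_global(list(events), model, t_dead = t_dead, correct = correct,
                   bounds = bounds, compute_se = compute_se, seed = seed)
}

#' Fit one shared rate set across several records (global fit)
#'
#' Maximizes the summed interval log-likelihood of a set of idealized
#' recordings over a single shared rate set; with one record this is
#' identical to [fit_rates()]. All records must share the holding voltage.
#'
#' @param event_sets List of `event_seq` objects.
#' @inheritParams fit_rates
#' @return A `rate_fit`.
#' @export
fit_rates_global <- function(event_sets, model, t_dead = NULL, correct = TRUE,
                             bounds = c(1e-3, 1e6), compute_se = FALSE,
                             seed = NULL) {
  stopifnot(length(event_sets) >= 1)
  volts <- vapply(event_sets, function(e) attr(e, "voltage") %||% NA_real_,
                  numeric(1))
  if (length(unique(volts[!is.na(volts)])) > 1)
    stop_bad("records have inconsistent voltages: ",
             paste(unique(volts), collapse = ", "))
  t_dead <- t_dead %||% attr(event_sets[[1]], "dead_time") %||% 0
  st <- model$states
  # identifiability: class pairs never adjacent in any record
  ulabs <- unique(st$class)
  seen_cls <- matrix(FALSE, length(ulabs), length(ulabs),
                     dimnames = list(ulabs, ulabs))
  any_cls <- character(0)
  for (ev in event_sets) {
    n <- nrow(ev)
    if (n > 1) {
      f <- ev$class[-n]; t2 <- ev$class[-1]
      for (i in seq_along(f)) seen_cls[f[i], t2[i]] <- TRUE
    }
    any_cls <- union(any_cls, ev$class)
  }
  edge_from_cls <- st$class[match(model$rates$from, st$state)]
  edge_to_cls <- st$class[match(model$rates$to, st$state)]
  unident <- edge_from_cls != edge_to_cls &
    !seen_cls[cbind(edge_from_cls, edge_to_cls)]
  # within-class edges of classes never observed are also unidentifiable
  unident <- unident | (edge_from_cls == edge_to_cls &
                          !(edge_from_cls %in% any_cls))
  free <- which(!unident)
  base <- model$rates$rate
  base[unident] <- bounds[1]
  obj <- function(logr) {
    r <- base
    r[free] <- exp(logr)
    m <- set_model_rates(model, r)
    ll <- sum(vapply(event_sets, function(ev)
      mil_loglikelihood(ev, m, t_dead = t_dead, correct = correct),
      numeric(1)))
    if (!is.finite(ll)) ll <- -1e300
    -ll
  }
  init1 <- Reduce(`+`, lapply(event_sets, moment_init_rates, model = model)) /
    length(event_sets)
  init2 <- pmax(pmin(model$rates$rate, bounds[2]), bounds[1])
  starts <- list(log(pmax(pmin(init1[free], bounds[2]), bounds[1])),
                 log(init2[free]))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = log(bounds[1]), upper = log(bounds[2]),
            control = list(maxit = 300, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_bad("MIL optimization failed from all starts")
  r <- base
  r[free] <- exp(best$par)
  fitted <- set_model_rates(model, r)
  se <- NULL
  if (compute_se) {
    h <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
    if (!is.null(h)) {
      v <- tryCatch(diag(solve(h)), error = function(e) rep(NA_real_, length(free)))
      se <- rep(NA_real_, nrow(model$rates))
      se[free] <- sqrt(pmax(v, 0))
    }
  }
  structure(
    list(model = fitted, loglik = -best$value, t_dead = t_dead,
         voltage = volts[!is.na(volts)][1] %||% model$voltage,
         records_used = length(event_sets),
         unidentifiable = paste(model$rates$from[unident],
                                model$rates$to[unident], sep = "->"),
         converged = best$convergence == 0, se = se),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> ", x$model$name, " @ ", x$voltage, " mV; logLik = ",
      format(x$loglik), "; records = ", x$records_used, "\n", sep = "")
  print(x$model$rates, n = 8)
  if (length(x$unidentifiable))
    cat("unidentifiable edges:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate fitted rates across voltages
#'
#' Collects per-record rate fits (and optionally global fits) at two or more
#' voltages into an edge-by-voltage table with per-voltage mean and standard
#' error, for inspecting which transitions are voltage sensitive.
#'
#' @param fits List of `rate_fit` objects (per-record fits).
#' @param global Optional list of `rate_fit` objects from global fits, one
#'   per voltage.
#' @return Tibble with `from`, `to`, `voltage`, `n`, `mean_rate`, `se_rate`
#'   and (if supplied) `global_rate`.
#' @export
rates_vs_voltage <- function(fits, global = NULL) {
  stopifnot(length(fits) >= 1)
  tb <- purrr::map_dfr(fits, function(f)
    dplyr::mutate(f$model$rates, voltage = f$voltage))
  out <- tb |>
    dplyr::group_by(.data$from, .data$to, .data$voltage) |>
    dplyr::summarise(n = dplyr::n(), mean_rate = mean(.data$rate),
                     se_rate = ifelse(dplyr::n() > 1,
                                      sd(.data$rate) / sqrt(dplyr::n()),
                                      NA_real_),
                     .groups = "drop")
  if (!is.null(global)) {
    gb <- purrr::map_dfr(global, function(f)
      dplyr::mutate(f$model$rates, voltage = f$voltage)) |>
      dplyr::rename(global_rate = "rate")
    out <- dplyr::left_join(out, gb, by = c("from", "to", "voltage"))
  }
  out
}
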
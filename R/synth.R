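# Synthetic cohorts of single-channel recordings with the statistical
# structure the analysis pipeline assumes: strong inter-channel rate
# heterogeneity, voltage-dependent opening in most channels and a
# voltage-independent high-Po minority.

#' Specify a synthetic single-channel cohort
#'
#' @param n_channels Number of channels (default 8, matching the size of a
#'   typical single-channel study cohort).
#' @param voltages Holding potentials (mV) recorded per channel.
#' @param record_duration Duration of each record (s).
#' @param base_model Preset name the cohort gates by.
#' @param rate_heterogeneity SD of the log-normal multiplicative rate
#'   perturbation applied per channel and edge (0 = identical channels).
#' @param noise_sd Baseline noise SD (pA); `NULL` uses the acquisition-chain
#'   default (0.1 x full-open amplitude).
#' @param fraction_voltage_independent Probability that a channel gates in a
#'   voltage-independent, high-Po manner (default 0.11).
#' @param seed Integer seed; fixed seeds give byte-identical cohorts.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_channels = 8, voltages = c(-30, 10, 20, 30, 40, 50),
                        record_duration = 60,
                        base_model = "M2_adapted",
                        rate_heterogeneity = 0.3, noise_sd = NULL,
                        fraction_voltage_independent = 0.11, seed = 1) {
  stopifnot(n_channels >= 1, rate_heterogeneity >= 0,
            record_duration > 0, length(voltages) >= 1)
  structure(list(n_channels = n_channels, voltages = voltages,
                 record_duration = record_duration, base_model = base_model,
                 rate_heterogeneity = rate_heterogeneity, noise_sd = noise_sd,
                 fraction_voltage_independent = fraction_voltage_independent,
                 seed = seed),
            class = "cohort_spec")
}

# Voltage scaling of the sensitive transitions, relative to the +30 mV
# reference at which preset rates are defined. Closing-to-opening progress
# rates (towards C1 and into the first open-bearing class) increase ~10x
# from -30 mV to the +20 mV plateau; the O1 -> substate backward rate slows
# ~3x between +10 and +20 mV. Forms are exponential in V (plateau above
# +20 mV), a modelling choice: per-voltage fits constrain only the
# endpoints, not the functional shape.
voltage_rate_multipliers <- function(model, voltage) {
  r <- model$rates
  mult <- rep(1, nrow(r))
  st <- model$states
  cls_from <- st$class[match(r$from, st$state)]
  cls_to <- st$class[match(r$to, st$state)]
  ord <- class_rank(cls_from) < class_rank(cls_to)
  activating <- ord & cls_from == "C" # C->C progress and C->open-class entry
  vc <- pmin(voltage, 20)
  mult[activating] <- 10^((vc - 20) / 50)
  deactivating <- cls_from == "O" & grepl("^S", cls_to)
  vo <- pmin(pmax((voltage - 10) / 10, 0), 1)
  mult[deactivating] <- 3^(-vo) * 3 # reference +30 mV has the slowed rate
  mult
}

#' Generate a synthetic cohort of single-channel recordings
#'
#' Per channel: draws one log-normal rate multiplier per edge (inter-channel
#' heterogeneity), decides whether the channel is voltage independent, then
#' simulates a record at every voltage through the standard acquisition
#' chain. Voltage-dependent channels scale the activating closed-state
#' transitions up with voltage (plateauing above +20 mV) and slow the
#' full-open to substate return at depolarized potentials;
#' voltage-independent channels keep constant, high-Po kinetics.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per channel x voltage: `channel`, `voltage`,
#'   `voltage_independent`, and list-columns `model` (the per-record
#'   `gating_model` actually simulated), `path` (ground-truth `state_path`)
#'   and `trace` (`sc_trace`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- build_preset(spec$base_model, voltage = 30)
  ne <- nrow(base$rates)
  out <- purrr::map_dfr(seq_len(spec$n_channels), function(ch) {
    ch_seed <- child_seed(spec$seed, ch)
    draws <- with_seed_if(ch_seed, list(
      mult = exp(rnorm(ne, 0, spec$rate_heterogeneity)),
      vi = runif(1) < spec$fraction_voltage_independent))
    purrr::map_dfr(seq_along(spec$voltages), function(vi_idx) {
      v <- spec$voltages[vi_idx]
      r <- base$rates
      r$rate <- r$rate * draws$mult
      if (draws$vi) {
        # voltage independent and high-Po: activating rates pinned at the
        # plateau and boosted
        st <- base$states
        act <- st$class[match(r$from, st$state)] == "C" &
          class_rank(st$class[match(r$from, st$state)]) <
            class_rank(st$class[match(r$to, st$state)])
        r$rate[act] <- r$rate[act] * 5
      } else {
        r$rate <- r$rate * voltage_rate_multipliers(base, v)
      }
      m <- gating_model(base$states, r, voltage = v,
                        name = paste0(spec$base_model, "_ch", ch),
                        classes = conductance_classes())
      rec_seed <- child_seed(ch_seed, 100L + vi_idx)
      p <- sample_path(m, spec$record_duration, seed = rec_seed)
      tr <- acquisition_chain(p, m, voltage = v, mode = "standard",
                              noise_sd = spec$noise_sd,
                              seed = child_seed(rec_seed, 7L))
      tibble::tibble(channel = ch, voltage = v,
                     voltage_independent = draws$vi,
                     model = list(m), path = list(p), trace = list(tr))
    })
  })
  attr(out, "spec") <- spec
  out
}

#' Small deterministic worked fixtures
#'
#' Hand-constructed traces (< 2 s) reproducing the qualitative gating motifs
#' of subconductance-gating channels, with their ground truth:
#' * `opening_burst`: closed - substate train - full opening burst -
#'   substate train - closed.
#' * `substate_train`: substate gating that never visits the full open
#'   state.
#' * `fast_flicker`: an unresolved fast couplet (alpha = 50,000 s^-1,
#'   beta = 21,583 s^-1) whose filtered output dwells at the S4-like
#'   apparent sublevel.
#'
#' @param name Fixture name.
#' @param voltage Holding potential (mV).
#' @param noise_sd Baseline noise SD (pA).
#' @return List with `trace` (`sc_trace`) and `events` (ground-truth
#'   `event_seq`).
#' @export
worked_fixture <- function(name = c("opening_burst", "substate_train",
                                    "fast_flicker"),
                           voltage = 30, noise_sd = 0.2) {
  name <- match.arg(name)
  if (name == "fast_flicker") {
    betas <- fast_gating_betas()
    m <- gating_model(
      tibble::tibble(state = c("C_S4", "O_S4"), class = c("C", "O")),
      tibble::tibble(from = c("C_S4", "O_S4"), to = c("O_S4", "C_S4"),
                     rate = c(unname(betas["S4"]), 5e4)),
      voltage = voltage, name = "fast_flicker")
    p <- sample_path(m, 1, initial_state = "C_S4", seed = 42)
    tr <- acquisition_chain(p, m, voltage, mode = "fast_gating",
                            noise_sd = noise_sd, seed = 43)
    ev <- path_to_events(p, m, voltage)
    return(list(trace = tr, events = ev, model = m))
  }
  m1 <- build_preset("M1", voltage = voltage)
  durs <- if (name == "opening_burst") {
    tibble::tribble(
      ~state, ~dur,
      "C", 0.40, "S4", 0.002, "S3", 0.002, "S2", 0.003, "S1", 0.002,
      "O", 0.050, "S1", 0.002, "S2", 0.002, "O", 0.030, "S1", 0.003,
      "S3", 0.002, "S4", 0.002, "C", 0.40)
  } else {
    tibble::tribble(
      ~state, ~dur,
      "C", 0.30, "S4", 0.004, "S3", 0.003, "S4", 0.005, "C", 0.20,
      "S4", 0.003, "S3", 0.002, "S2", 0.004, "S3", 0.003, "S4", 0.002,
      "C", 0.30)
  }
  start <- cumsum(c(0, head(durs$dur, -1)))
  cls <- m1$states$class[match(durs$state, m1$states$state)]
  p <- new_state_path(durs$state, cls, start, durs$dur,
                      total = sum(durs$dur), seed = 0,
                      model_name = paste0("fixture_", name))
  tr <- acquisition_chain(p, m1, voltage, mode = "standard",
                          noise_sd = noise_sd, seed = 44)
  ev <- path_to_events(p, m1, voltage)
  list(trace = tr, events = ev, model = m1)
}
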
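test_that("SKM recovers a noiseless slow record exactly", {
  m2 <- build_preset("M2")
  durs <- c(0.05, 0.01, 0.03, 0.008, 0.05, 0.012, 0.04)
  states <- c("C", "S", "O", "S", "C", "O", "C")
  p <- subkinetics:::new_state_path(states, states, cumsum(c(0, head(durs, -1))),
                                    durs, total = sum(durs), seed = 0)
  tr <- render_trace(p, m2, voltage = 30, fs = 1e4)
  ev <- skm_idealize(tr, m2)
  expect_equal(ev$class, states)
  expect_lt(max(abs(ev$duration - durs)), 2.1e-4) # one-sample quantization
  # all-zero trace: single closed event spanning the trace
  z <- new_trace_for_test(rep(0, 5000), 1e4)
  evz <- skm_idealize(z, m2)
  expect_equal(nrow(evz), 1L)
  expect_equal(evz$class, "C")
  expect_equal(evz$duration, 0.5)
})

test_that("SKM classifies >= 95% of samples correctly under realistic noise", {
  m2 <- build_preset("M2")
  p <- sample_path(m2, 10, seed = 41)
  tr <- acquisition_chain(p, m2, 30, mode = "standard",
                          noise_sd = 0.1 * 199 * 30e-3, seed = 42)
  ev <- skm_idealize(tr, m2)
  # truth and estimate class per sample
  tt <- trace_time(tr)
  truth <- p$class[findInterval(tt, p$start)]
  est <- ev$class[findInterval(tt, ev$start)]
  expect_gt(mean(truth == est), 0.95)
})

test_that("dead-time application merges by conductance proximity and is idempotent", {
  mk <- function(cls, dur_ms) {
    subkinetics:::new_event_seq(cls, cumsum(c(0, head(dur_ms, -1))) / 1000,
                                dur_ms / 1000,
                                rep(0, length(cls)))
  }
  # sub-dead-time opening stripped and closures coalesced
  ev <- apply_dead_time(mk(c("C", "O", "C"), c(5, 0.4, 5)), 6e-4)
  expect_equal(ev$class, "C")
  expect_equal(ev$duration, 10.4e-3, tolerance = 1e-12)
  # all long events: unchanged
  ev2 <- apply_dead_time(mk(c("C", "S4", "O"), c(5, 2, 3)), 6e-4)
  expect_equal(ev2$class, c("C", "S4", "O"))
  # brief substate merges into the nearer-conductance neighbour (S3, not C)
  ev3 <- apply_dead_time(mk(c("C", "S4", "S3"), c(5, 0.3, 2)), 6e-4)
  expect_equal(ev3$class, c("C", "S3"))
  expect_equal(ev3$duration, c(5e-3, 2.3e-3), tolerance = 1e-12)
  # preceding rule: S4 extends the preceding closed event instead
  ev3p <- apply_dead_time(mk(c("C", "S4", "S3"), c(5, 0.3, 2)), 6e-4,
                          rule = "preceding")
  expect_equal(ev3p$class, c("C", "S3"))
  expect_equal(ev3p$duration, c(5.3e-3, 2e-3), tolerance = 1e-12)
  # idempotence and monotone event count on a random-ish sequence
  m <- build_preset("M1_reduced")
  p <- sample_path(m, 20, seed = 51)
  raw <- path_to_events(p, m)
  for (rule in c("nearest", "preceding")) {
    d1 <- apply_dead_time(raw, 6e-4, rule = rule)
    d2 <- apply_dead_time(d1, 6e-4, rule = rule)
    expect_lte(nrow(d1), nrow(raw))
    expect_true(all(d1$duration >= 6e-4))
    expect_equal(d2$class, d1$class)
    expect_equal(d2$duration, d1$duration, tolerance = 1e-12)
  }
  # whole sequence below the dead time collapses to one flagged event
  short <- apply_dead_time(mk(c("C", "O"), c(0.2, 0.1)), 6e-4)
  expect_equal(nrow(short), 1L)
  expect_true("shorter_than_dead_time" %in% attr(short, "flags"))
})

test_that("Po is a duration fraction, sums to one, and matches the stationary oracle", {
  mk <- function(cls, dur) {
    subkinetics:::new_event_seq(cls, cumsum(c(0, head(dur, -1))), dur,
                                rep(0, length(cls)))
  }
  po <- compute_po(mk(c("C", "O"), c(9, 1)))
  expect_equal(po$po[po$class == "O"], 0.1, tolerance = 1e-12)
  expect_lt(abs(sum(po$po) - 1), 1e-12)
  one <- compute_po(mk("O", 3))
  expect_equal(one$po, 1)
  # long M2 record: Po matches class_po within 3 sigma
  m2 <- build_preset("M2")
  p <- sample_path(m2, 120, seed = 61)
  po_hat <- compute_po(path_to_events(p, m2))
  po_true <- class_po(m2)
  for (cl in po_true$class) {
    n_dwell <- sum(p$class == cl)
    se <- po_true$po[po_true$class == cl] * sqrt(2 / max(n_dwell, 1))
    expect_lt(abs(po_hat$po[po_hat$class == cl] -
                    po_true$po[po_true$class == cl]), 3 * pmax(se, 0.01))
  }
  # merged pooling adds the substate classes
  pm <- compute_po(path_to_events(sample_path(build_preset("M1"), 20, seed = 1),
                                  build_preset("M1")), by = "merged")
  expect_true(all(pm$class %in% c("C", "S", "O")))
  expect_lt(abs(sum(pm$po) - 1), 1e-12)
})

test_that("Po diary computes windowed time fractions", {
  mk <- subkinetics:::new_event_seq(c("C", "O", "C"), c(0, 4, 6), c(4, 2, 4),
                                    c(0, 5, 0))
  d <- po_diary(mk, window = 5)
  expect_equal(d$po[d$window_start == 0 & d$class == "O"], 0.2)
  expect_equal(d$po[d$window_start == 5 & d$class == "O"], 0.2)
  expect_equal(sum(d$po[d$window_start == 0]), 1)
})

test_that("mean class currents weight dwell amplitudes by Po", {
  # Po(O) = 0.5 square wave of 4 pA: whole-record contribution 2 pA
  x <- rep(c(rep(4, 50), rep(0, 50)), 10)
  tr <- new_trace_for_test(x, 1e4)
  cls <- rep(rep(c("O", "C"), each = 50), 10)
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  ev <- subkinetics:::new_event_seq(r$values,
                                    (c(1, head(ends, -1) + 1) - 1) / 1e4,
                                    r$lengths / 1e4, rep(0, length(r$values)))
  mc <- mean_class_currents(tr, ev)
  expect_equal(mc$mean_current[mc$class == "O"], 2, tolerance = 1e-9)
  expect_equal(mc$mean_amp_dwelling[mc$class == "O"], 4, tolerance = 1e-9)
  expect_equal(mc$mean_current[mc$class == "C"], 0, tolerance = 1e-9)
})

test_that("transition counts tally adjacent class pairs and export a chord table", {
  ev <- subkinetics:::new_event_seq(c("C", "S4", "C", "S4", "O"),
                                    c(0, 1, 2, 3, 4), rep(1, 5), rep(0, 5))
  tc <- transition_counts(ev)
  expect_equal(tc["C", "S4"], 2L)
  expect_equal(tc["S4", "C"], 1L)
  expect_equal(tc["S4", "O"], 1L)
  expect_equal(sum(tc), 4L)
  expect_true(all(diag(unclass(tc)) == 0))
  one <- transition_counts(subkinetics:::new_event_seq("O", 0, 1, 5))
  expect_equal(sum(one), 0L)
  f <- tempfile(fileext = ".tsv")
  write_chord_matrix(tc, f)
  back <- utils::read.delim(f)
  expect_equal(back$S4[back$class == "C"], 2L)
  # count ratios of a long single-state-per-class record match the embedded
  # chain probabilities within 3 sigma
  m1 <- build_preset("M1")
  p <- sample_path(m1, 60, seed = 71)
  tc2 <- transition_counts(path_to_events(p, m1))
  q <- q_matrix(m1)
  for (a in rownames(q)) {
    n_a <- sum(tc2[a, ])
    if (n_a < 50) next
    p_hat <- tc2[a, ] / n_a
    p_true <- q[a, ] / -q[a, a]
    p_true[a] <- 0
    se <- sqrt(p_true * (1 - p_true) / n_a)
    expect_true(all(abs(p_hat - p_true) <= 3 * pmax(se, 0.01)), info = a)
  }
})

test_that("Po from merged idealization agrees with substates summed (M1 vs M2)", {
  mr <- build_preset("M1_reduced")
  p <- sample_path(mr, 25, seed = 81)
  tr <- acquisition_chain(p, mr, 30, mode = "standard",
                          noise_sd = 0.08 * 199 * 30e-3, seed = 82)
  m1 <- build_preset("M1")
  m2 <- build_preset("M2")
  ev1 <- apply_dead_time(skm_idealize(tr, m1), 6e-4)
  ev2 <- apply_dead_time(skm_idealize(tr, m2, fixed_mean = TRUE), 6e-4)
  po1 <- compute_po(ev1, by = "merged")
  po2 <- compute_po(ev2)
  for (cl in c("C", "S", "O")) {
    a <- po1$po[po1$class == cl]
    b <- po2$po[po2$class == cl]
    if (!length(a)) a <- 0
    if (!length(b)) b <- 0
    expect_lt(abs(a - b), 0.02)
  }
})
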
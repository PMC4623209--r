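test_that("interval likelihood matches the analytic two-state form and an R reference", {
  m <- two_state_model(100, 50)
  p <- sample_path(m, 10, seed = 91)
  ev <- path_to_events(p, m)
  ll <- mil_loglikelihood(ev, m, t_dead = 0, correct = FALSE)
  # analytic: alternating exponential dwells; entry probability 1 within the
  # first class (single state); last dwell has no coupling factor
  rate_of <- c(C = 100, O = 50)
  lam <- rate_of[ev$class]
  ll_ref <- sum(-lam * ev$duration) + sum(log(lam[-length(lam)]))
  expect_equal(ll, ll_ref, tolerance = 1e-8)
  # single dwell: log(pi_a^T expm(Q'_aa t) 1), here a scalar exponential
  # survival in whichever class the record begins
  one <- ev[1, ]
  attr(one, "dead_time") <- 0
  class(one) <- class(ev)
  attributes(one)$event_classes <- attr(ev, "event_classes")
  expect_equal(mil_loglikelihood(one, m, t_dead = 0, correct = FALSE),
               -rate_of[one$class] * one$duration, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("C++ propagation agrees with a plain R implementation of the same likelihood", {
  m <- build_preset("M2_adapted")
  p <- sample_path(m, 2, seed = 92)
  ev <- apply_dead_time(path_to_events(p, m), 6e-4, rule = "preceding")
  td <- 6e-4
  ll_cpp <- mil_loglikelihood(ev, m, t_dead = td, correct = TRUE)
  bl <- subkinetics:::mil_blocks(m, td, correct = TRUE)
  cls <- match(ev$class, bl$labels)
  pi <- stationary_distribution(bl$q)
  v <- pi[bl$idx[[cls[1]]]]
  v <- matrix(v / sum(v), nrow = 1)
  ll_r <- 0
  k <- length(bl$labels)
  for (i in seq_len(nrow(ev))) {
    v <- v %*% expm_ref(bl$Qblocks[[cls[i]]] * max(ev$duration[i] - td, 0))
    ll_r <- ll_r + log(sum(v))
    v <- v / sum(v)
    if (i < nrow(ev)) {
      v <- v %*% bl$Amats[[(cls[i] - 1) * k + cls[i + 1]]]
      ll_r <- ll_r + log(sum(v))
      v <- v / sum(v)
    }
  }
  expect_equal(ll_cpp, ll_r, tolerance = 1e-7)
})

test_that("the corrected likelihood converges to the uncorrected one as t_dead -> 0", {
  m <- build_preset("M2")
  p <- sample_path(m, 5, seed = 93)
  ev <- path_to_events(p, m)
  ll0 <- mil_loglikelihood(ev, m, t_dead = 0, correct = FALSE)
  ll1 <- mil_loglikelihood(ev, m, t_dead = 1e-9, correct = TRUE)
  expect_lt(abs(ll1 - ll0) / nrow(ev), 1e-6)
})

test_that("likelihood is invariant to relabeling states within a class", {
  m <- build_preset("M1_reduced")
  p <- sample_path(m, 5, seed = 94)
  ev <- apply_dead_time(path_to_events(p, m), 6e-4, rule = "preceding")
  swap <- c(C3 = "C2", C2 = "C3", O1 = "O1")
  st2 <- m$states
  r2 <- m$rates
  r2$from <- ifelse(r2$from %in% names(swap), swap[r2$from], r2$from)
  r2$to <- ifelse(r2$to %in% names(swap), swap[r2$to], r2$to)
  m2 <- gating_model(st2, r2, voltage = m$voltage)
  expect_equal(mil_loglikelihood(ev, m2, t_dead = 6e-4),
               mil_loglikelihood(ev, m, t_dead = 6e-4), tolerance = 1e-8)
})

test_that("two-state rates are recovered within 5% from 10^4 events", {
  m <- two_state_model(100, 50)
  p <- sample_path(m, 150, seed = 95)
  ev <- path_to_events(p, m)
  m0 <- two_state_model(30, 30)
  f <- fit_rates(ev, m0, t_dead = 0, correct = FALSE)
  expect_equal(f$model$rates$rate[1], 100, tolerance = 0.05)
  expect_equal(f$model$rates$rate[2], 50, tolerance = 0.05)
  expect_true(f$converged)
  expect_true(is.finite(f$loglik))
})

test_that("edges never observed at the class level are flagged unidentifiable", {
  m <- build_preset("M2_adapted")
  # closed/substate alternation only: O never appears
  ev <- subkinetics:::new_event_seq(rep(c("C", "S"), 30),
                                    seq(0, by = 0.01, length.out = 60),
                                    rep(0.01, 60), rep(0, 60),
                                    dead_time = 6e-4, voltage = 30)
  f <- fit_rates(ev, m, t_dead = 6e-4)
  expect_true("S->O1" %in% f$unidentifiable)
  expect_true("O1->S" %in% f$unidentifiable)
  expect_false("C1->S" %in% f$unidentifiable)
})

test_that("global fits pool records and reject mixed voltages", {
  m <- two_state_model(100, 50)
  evs <- lapply(1:3, function(i)
    path_to_events(sample_path(m, 40, seed = 95 + i), m))
  m0 <- two_state_model(30, 30)
  g <- fit_rates_global(evs, m0, t_dead = 0, correct = FALSE)
  expect_equal(g$records_used, 3)
  expect_equal(g$model$rates$rate[1], 100, tolerance = 0.06)
  # per-record fits bracket the global rates under heterogeneity
  mA <- two_state_model(60, 30)
  mB <- two_state_model(180, 90)
  evA <- path_to_events(sample_path(mA, 60, seed = 1), mA)
  evB <- path_to_events(sample_path(mB, 60, seed = 2), mB)
  gg <- fit_rates_global(list(evA, evB), m0, t_dead = 0, correct = FALSE)
  fA <- fit_rates(evA, m0, t_dead = 0, correct = FALSE)
  fB <- fit_rates(evB, m0, t_dead = 0, correct = FALSE)
  for (e in 1:2) {
    lo <- min(fA$model$rates$rate[e], fB$model$rates$rate[e])
    hi <- max(fA$model$rates$rate[e], fB$model$rates$rate[e])
    expect_gte(gg$model$rates$rate[e], lo * 0.95)
    expect_lte(gg$model$rates$rate[e], hi * 1.05)
  }
  bad <- evA
  attr(bad, "voltage") <- -30
  expect_error(fit_rates_global(list(evA, bad), m0), "voltage")
})

test_that("rates_vs_voltage tabulates edges across voltages", {
  m <- two_state_model(100, 50, voltage = 10)
  f1 <- fit_rates(path_to_events(sample_path(m, 30, seed = 1), m),
                  two_state_model(30, 30, voltage = 10), t_dead = 0,
                  correct = FALSE)
  m2 <- two_state_model(300, 50, voltage = 30)
  f2 <- fit_rates(path_to_events(sample_path(m2, 30, seed = 2), m2),
                  two_state_model(30, 30, voltage = 30), t_dead = 0,
                  correct = FALSE)
  tb <- rates_vs_voltage(list(f1, f2))
  expect_equal(sort(unique(tb$voltage)), c(10, 30))
  r_co <- tb[tb$from == "C" & tb$to == "O", ]
  expect_gt(r_co$mean_rate[r_co$voltage == 30],
            2 * r_co$mean_rate[r_co$voltage == 10])
  tb1 <- rates_vs_voltage(list(f1))
  expect_equal(unique(tb1$voltage), 10)
})
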
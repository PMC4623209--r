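test_that("q_matrix builds the generator with zero row sums", {
  m <- two_state_model(100, 50)
  q <- q_matrix(m)
  expect_equal(unname(q), matrix(c(-100, 50, 100, -50), 2))
  for (nm in c("M1", "M2", "M1_reduced", "M1_adapted", "M2_adapted",
               "fast_gating")) {
    qq <- q_matrix(build_preset(nm))
    expect_lt(max(abs(rowSums(qq))), 1e-9 * max(abs(qq)))
  }
})

test_that("presets have the documented topology and round-trip their rates", {
  sizes <- list(M1 = c(6, 30), M2 = c(3, 6), M1_reduced = c(9, 16),
                M1_adapted = c(9, 72), M2_adapted = c(6, 10),
                fast_gating = c(13, 24))
  for (nm in names(sizes)) {
    m <- build_preset(nm)
    expect_equal(nrow(m$states), sizes[[nm]][1], info = nm)
    expect_equal(nrow(m$rates), sizes[[nm]][2], info = nm)
    # rates fed back in round-trip exactly through the Q matrix
    q <- q_matrix(m)
    ii <- cbind(match(m$rates$from, m$states$state),
                match(m$rates$to, m$states$state))
    expect_identical(unname(q[ii]), m$rates$rate, info = nm)
    # and through build_preset itself
    m2 <- build_preset(nm, rates = m$rates)
    expect_equal(m2$rates, m$rates, info = nm)
  }
})

test_that("preset construction validates edges, rates and alpha", {
  m <- build_preset("M2")
  expect_error(build_preset("M2", rates = m$rates[-1, ]), "missing")
  bad <- rbind(m$rates, tibble::tibble(from = "C", to = "C", rate = 5))
  expect_error(build_preset("M2", rates = bad))
  neg <- m$rates
  neg$rate[1] <- -1
  expect_error(build_preset("M2", rates = neg), "egative")
  fg <- build_preset("fast_gating")
  uneven <- fg$rates
  uneven$rate[uneven$from == "O_S4"] <- 123
  expect_error(build_preset("fast_gating", rates = uneven), "alpha")
})

test_that("merged substate class sits midway between closed and full open", {
  cl <- conductance_classes()
  g <- function(l) cl$conductance[cl$label == l]
  expect_equal(g("S"), (g("C") + g("O")) / 2)
  expect_true(cl$fixed_noise[cl$label == "S"])
  expect_equal(cl$noise_mult[cl$label == "S"], 0.5)
  # conductance strictly increases over C, S4, S3, S2, S1, O
  ord <- c("C", "S4", "S3", "S2", "S1", "O")
  expect_true(all(diff(cl$conductance[match(ord, cl$label)]) > 0))
})

test_that("stationary distribution solves pi Q = 0 and matches oracles", {
  m <- two_state_model(100, 50)
  pi <- stationary_distribution(q_matrix(m))
  expect_equal(unname(pi), c(1 / 3, 2 / 3), tolerance = 1e-10)
  # symmetric ring: uniform by symmetry
  ring <- gating_model(
    tibble::tibble(state = c("C", "S", "O"), class = c("C", "S", "O")),
    tibble::tibble(from = c("C", "S", "O", "S", "O", "C"),
                   to = c("S", "O", "C", "C", "S", "O"),
                   rate = rep(7, 6)))
  expect_equal(unname(stationary_distribution(q_matrix(ring))), rep(1 / 3, 3),
               tolerance = 1e-10)
  for (sd in 1:5) {
    mod <- random_connected_model(6, seed = sd)
    q <- q_matrix(mod)
    pi <- stationary_distribution(q)
    expect_true(all(pi >= 0))
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_lt(max(abs(pi %*% q)), 1e-10 * max(abs(q)))
    # independent route: long-time propagator row
    expect_equal(unname(pi), stationary_by_expm(q), tolerance = 1e-6)
  }
  # SSA occupancy agreement within 3 sigma on one random model
  mod <- random_connected_model(6, seed = 11)
  o <- ssa_occupancy(mod, duration = 60, seed = 5)
  pi <- stationary_distribution(q_matrix(mod))
  expect_true(all(abs(o$occ - pi) <= 3 * pmax(o$se, 0.004)))
})

test_that("reducible generators are rejected with the disconnected block named", {
  q <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  q["a", "b"] <- 5
  q["b", "a"] <- 2
  diag(q) <- -rowSums(q)
  expect_error(stationary_distribution(q), "c")
})

test_that("class Po aggregates stationary occupancy and sums to one", {
  m <- two_state_model(100, 50)
  po <- class_po(m)
  expect_equal(po$po[po$class == "O"], 2 / 3, tolerance = 1e-10)
  expect_equal(sum(po$po), 1, tolerance = 1e-12)
  # isolated fast couplet: Po(O) = beta / (alpha + beta)
  beta <- 21583
  cp <- fast_couplet_model(beta)
  po <- class_po(cp)
  expect_equal(po$po[po$class == "O"], beta / (5e4 + beta), tolerance = 1e-10)
})

test_that("fast-gating couplet rates reproduce the sublevel conductances in closed form", {
  fg <- build_preset("fast_gating")
  alpha <- 5e4
  for (lv in c(S4 = 60, S3 = 93, S2 = 121, S1 = 161)) {
    nm <- names(which(c(S4 = 60, S3 = 93, S2 = 121, S1 = 161) == lv))
    beta <- fg$rates$rate[fg$rates$from == paste0("C_", nm) &
                            fg$rates$to == paste0("O_", nm)]
    expect_equal(199 * beta / (alpha + beta), lv, tolerance = 1e-9)
  }
})

test_that("model files round-trip through JSON", {
  m <- build_preset("M2_adapted", voltage = -30)
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$rates, m$rates)
  expect_equal(m2$states, m$states)
  expect_equal(m2$voltage, m$voltage)
})

test_that("lumped and fast-gating analogues preserve stationary structure", {
  mr <- build_preset("M1_reduced")
  ms <- as_merged_substate(mr)
  po_r <- compute_po_ref <- class_po(mr)
  po_m <- class_po(ms)
  expect_equal(po_m$po[po_m$class == "O"], po_r$po[po_r$class == "O"],
               tolerance = 1e-8)
  expect_equal(po_m$po[po_m$class == "S"],
               sum(po_r$po[grepl("^S", po_r$class)]), tolerance = 1e-8)
  fg <- as_fast_gating(mr)
  expect_equal(sort(fg$states$state), sort(build_preset("fast_gating")$states$state))
})
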
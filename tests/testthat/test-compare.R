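test_that("amplitude histograms are unit-mass densities on the shared grid", {
  # noiseless two-level trace: two bins with masses equal to time fractions
  full <- 199 * 30e-3
  x <- c(rep(0, 700), rep(full, 300))
  h <- amplitude_histogram(new_trace_for_test(x, 1e4), normalize_by = full)
  w <- h$bin_hi - h$bin_lo
  expect_equal(sum(h$density * w), 1, tolerance = 1e-9)
  expect_equal(sum(h$density[h$mid > 0.9] * w[h$mid > 0.9]), 0.3,
               tolerance = 1e-9)
  hz <- amplitude_histogram(new_trace_for_test(rep(0, 100), 1e4),
                            normalize_by = full)
  expect_equal(sum(hz$density[abs(hz$mid) < 0.02] * w[abs(hz$mid) < 0.02]), 1,
               tolerance = 1e-9)
  expect_error(amplitude_histogram(new_trace_for_test(numeric(0), 1e4),
                                   normalize_by = full))
})

test_that("an M1 simulation shows modes at the sublevel conductance ratios", {
  m1 <- build_preset("M1")
  p <- sample_path(m1, 20, seed = 111)
  tr <- acquisition_chain(p, m1, 30, mode = "standard",
                          noise_sd = 0.04 * 199 * 30e-3, seed = 112)
  h <- amplitude_histogram(tr)
  expected_modes <- c(0, 60, 93, 121, 161, 199) / 199
  po <- class_po(m1)
  for (i in seq_along(expected_modes)) {
    # enough dwell mass must exist for a local mode to be visible
    if (po$po[i] < 0.02) next
    sel <- abs(h$mid - expected_modes[i]) < 0.05
    near <- abs(h$mid - expected_modes[i]) < 0.12
    expect_gt(max(h$density[sel]), 0.5 * max(h$density[near]))
  }
})

test_that("1-D EMD equals the closed form on trivial cases and the LP oracle", {
  full <- 199 * 30e-3
  h0 <- amplitude_histogram(new_trace_for_test(rep(0, 100), 1e4),
                            normalize_by = full)
  expect_equal(emd_1d(h0, h0), 0)
  # unit masses separated by delta transport over delta
  h1 <- amplitude_histogram(new_trace_for_test(rep(full * 0.5, 100), 1e4),
                            normalize_by = full)
  d <- emd_1d(h0, h1)
  mid0 <- h0$mid[which.max(h0$density)]
  mid1 <- h1$mid[which.max(h1$density)]
  expect_equal(d, abs(mid1 - mid0), tolerance = 1e-9)
  # grid mismatch is an error
  h2 <- amplitude_histogram(new_trace_for_test(rep(0, 50), 1e4),
                            grid = seq(-0.2, 1.2, length.out = 51),
                            normalize_by = full)
  expect_error(emd_1d(h0, h2), "grid")
  # LP transport oracle on random 30-bin instances
  grid <- seq(0, 1, length.out = 31)
  centers <- (head(grid, -1) + grid[-1]) / 2
  for (sd in 1:3) {
    withr::with_seed(sd, {
      p1 <- stats::runif(30); p1 <- p1 / sum(p1)
      p2 <- stats::runif(30); p2 <- p2 / sum(p2)
    })
    mk <- function(p) {
      structure(tibble::tibble(bin_lo = head(grid, -1), bin_hi = grid[-1],
                               mid = centers, density = p / diff(grid)),
                grid = grid, n_samples = 1000, source = NULL,
                class = c("amp_hist", class(tibble::tibble())))
    }
    expect_equal(emd_1d(mk(p1), mk(p2)), lp_transport_cost(p1, p2, centers),
                 tolerance = 1e-8)
  }
})

test_that("EMD satisfies the metric axioms on random histogram triples", {
  grid <- default_amp_grid()
  centers <- (head(grid, -1) + grid[-1]) / 2
  mk <- function(p) {
    structure(tibble::tibble(bin_lo = head(grid, -1), bin_hi = grid[-1],
                             mid = centers, density = p / diff(grid)),
              grid = grid, n_samples = 1000, source = NULL,
              class = c("amp_hist", class(tibble::tibble())))
  }
  hs <- lapply(1:6, function(i) {
    withr::with_seed(i, {
      p <- stats::rgamma(length(centers), 0.5)
      mk(p / sum(p))
    })
  })
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    dij <- emd_1d(hs[[i]], hs[[j]])
    expect_gte(dij, 0)
    expect_equal(dij, emd_1d(hs[[j]], hs[[i]]), tolerance = 1e-12)
    expect_lte(dij, emd_1d(hs[[i]], hs[[k]]) + emd_1d(hs[[k]], hs[[j]]) + 1e-12)
  }
})

test_that("classical MDS reproduces Euclidean configurations", {
  # collinear points at 0, 1, 2
  d <- as.matrix(dist(matrix(c(0, 1, 2), ncol = 1)))
  emb <- mds_embed(d, dims = 2)
  xy <- as.matrix(emb[, c("dim1", "dim2")])
  expect_equal(as.matrix(dist(xy)), d, ignore_attr = TRUE, tolerance = 1e-9)
  # coincident duplicates
  d2 <- as.matrix(dist(matrix(c(0, 0, 3), ncol = 1)))
  emb2 <- mds_embed(d2)
  expect_lt(sum((emb2[1, -1] - emb2[2, -1])^2), 1e-12)
  # random 2-D configuration recovered up to rotation (Procrustes oracle)
  skip_if_not_installed("vegan")
  withr::with_seed(7, X <- matrix(stats::rnorm(20), ncol = 2))
  emb3 <- mds_embed(as.matrix(dist(X)), dims = 2)
  pr <- vegan::procrustes(X, as.matrix(emb3[, c("dim1", "dim2")]))
  expect_lt(max(abs(stats::residuals(pr))), 1e-6)
})

test_that("the discrimination report handles a single record and model", {
  m2 <- build_preset("M2")
  p <- sample_path(m2, 4, seed = 121)
  tr <- acquisition_chain(p, m2, 30, mode = "standard", seed = 122)
  rep <- model_discrimination_report(list(tr), list(M2 = m2), voltage = 30,
                                     tol = Inf, chunk = 4, seed = 123)
  expect_equal(nrow(rep$ranking), 1L)
  expect_equal(rep$ranking$model, "M2")
  expect_true(rep$ranking$mean_emd >= 0)
  expect_true(is.na(rep$inter_experimental))
  f <- tempfile(fileext = ".tsv")
  write_distance_table(rep$emd, f)
  expect_true(file.exists(f))
})
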
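# Shared fixtures and independent oracles, built in code.

new_trace_for_test <- function(x, fs, voltage = 30) {
  subkinetics:::new_trace(x, fs, voltage)
}

two_state_model <- function(k_co = 100, k_oc = 50, voltage = 30) {
  gating_model(
    tibble::tibble(state = c("C", "O"), class = c("C", "O")),
    tibble::tibble(from = c("C", "O"), to = c("O", "C"), rate = c(k_co, k_oc)),
    voltage = voltage, name = "two_state")
}

# Random strongly-connected model: a directed ring guarantees irreducibility,
# extra random edges decorate it.
random_connected_model <- function(n_states = 6, seed = 1) {
  withr::with_seed(seed, {
    ids <- paste0("s", seq_len(n_states))
    classes <- c("C", sample(c("C", "S4", "S3", "S2", "S1", "O"),
                             n_states - 1, replace = TRUE))
    ring <- tibble::tibble(from = ids, to = ids[c(2:n_states, 1)],
                           rate = stats::runif(n_states, 20, 400))
    extra <- tibble::tibble(
      from = sample(ids, n_states, replace = TRUE),
      to = sample(ids, n_states, replace = TRUE),
      rate = stats::runif(n_states, 5, 200))
    extra <- extra[extra$from != extra$to, ]
    rates <- rbind(ring, extra)
    rates <- rates[!duplicated(rates[c("from", "to")]), ]
    gating_model(tibble::tibble(state = ids, class = classes), rates,
                 name = "random")
  })
}

# Empirical state occupancy of an SSA path (time fractions), plus a rough
# 1-sigma error from splitting the path into segments.
ssa_occupancy <- function(model, duration, seed, n_seg = 10) {
  p <- sample_path(model, duration, seed = seed)
  ids <- model$states$state
  occ <- vapply(ids, function(s) sum(p$duration[p$state == s]), numeric(1)) /
    sum(p$duration)
  seg <- floor(seq_len(nrow(p)) * n_seg / (nrow(p) + 1))
  seg_occ <- sapply(ids, function(s) {
    tapply(p$duration * (p$state == s), seg, sum) /
      tapply(p$duration, seg, sum)
  })
  se <- apply(seg_occ, 2, stats::sd) / sqrt(n_seg)
  list(occ = occ, se = se)
}

# Stationary distribution by an independent route: propagate expm(Q T) from
# a point mass until it stops changing.
stationary_by_expm <- function(q, T0 = NULL) {
  rates <- abs(diag(q))
  if (is.null(T0)) T0 <- 50 / min(rates[rates > 0])
  p <- as.numeric(expm_ref(q * T0)[1, ])
  p / sum(p)
}

# Reference matrix exponential via scaling-and-squaring of a Taylor series
# (independent of the package's internal implementation). The scaling count
# adapts to the norm: over-squaring would amplify rounding error.
expm_ref <- function(m, k = 40) {
  n <- nrow(m)
  s <- max(0, ceiling(log2(max(1, norm(m, "1")))))
  a <- m / 2^s
  res <- diag(n)
  term <- diag(n)
  for (i in 1:k) {
    term <- term %*% a / i
    res <- res + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) res <- res %*% res
  res
}

# 1-D optimal transport cost via scipy's linear-programming solver, used as
# an independent oracle for the closed-form EMD (small instances only).
lp_transport_cost <- function(p1, p2, centers) {
  stopifnot(length(p1) == length(p2), length(p1) == length(centers))
  f <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".txt")
  jsonlite::write_json(list(p1 = p1, p2 = p2, c = centers), f, digits = NA)
  script <- sprintf("
import json, numpy as np
from scipy.optimize import linprog
d = json.load(open('%s'))
p1, p2, c = map(np.asarray, (d['p1'], d['p2'], d['c']))
n = len(p1)
cost = np.abs(c[:, None] - c[None, :]).ravel()
A_eq = []
for i in range(n):
    row = np.zeros((n, n)); row[i, :] = 1; A_eq.append(row.ravel())
for j in range(n):
    row = np.zeros((n, n)); row[:, j] = 1; A_eq.append(row.ravel())
b_eq = np.concatenate([p1, p2])
res = linprog(cost, A_eq=np.array(A_eq), b_eq=b_eq, bounds=(0, None), method='highs')
open('%s', 'w').write(repr(res.fun))
", f, out)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  val <- suppressWarnings(as.numeric(readLines(out)))
  if (!length(val) || is.na(val)) stop("LP oracle failed: ", paste(status, collapse = "\n"))
  val
}

# Draws from a k-component exponential mixture left-truncated at t_dead.
rtrunc_exp_mix <- function(n, taus, areas, t_dead = 0, seed = 1) {
  withr::with_seed(seed, {
    comp <- sample.int(length(taus), n, replace = TRUE, prob = areas)
    t_dead + stats::rexp(n, rate = 1 / taus[comp])
  })
}
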
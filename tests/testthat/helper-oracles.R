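# Independent oracles and tiny fixture builders shared across tests.

# elementary symmetric functions by explicit subset enumeration (n <= ~14)
esf_enumerate <- function(deltas) {
  eps <- exp(-deltas)
  n <- length(deltas)
  if (n == 0L) return(1)
  subs <- as.matrix(expand.grid(rep(list(0:1), n)))
  sz <- rowSums(subs)
  pr <- exp(subs %*% log(eps))
  vapply(0:n, function(r) sum(pr[sz == r]), numeric(1L))
}

# conditional log-likelihood built on the enumeration oracle
cml_loglik_enum <- function(deltas, s, nr) {
  g <- esf_enumerate(deltas)
  -sum(s * deltas) - sum(nr * log(g[seq_along(nr) + 1L]))
}

# derivative-free CML maximisation (gauge delta_1 = 0, then recentred)
cml_oracle <- function(scores) {
  n <- ncol(scores)
  r <- rowSums(scores)
  keep <- r > 0 & r < n
  s <- colSums(scores[keep, , drop = FALSE])
  nr <- tabulate(r[keep], nbins = n - 1L)
  negll <- function(free) -cml_loglik_enum(c(0, free), s, nr)
  o <- stats::optim(rep(0, n - 1L), negll, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 20000))
  o <- stats::optim(o$par, negll, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 20000))
  d <- c(0, o$par)
  stats::setNames(d - mean(d), colnames(scores))
}

# weighted-likelihood ability by coarse grid + golden-section refinement
# (maximises log L + 0.5 log I directly, independent of the root solver)
wle_oracle <- function(raw_score, deltas) {
  obj <- function(theta) {
    p <- plogis(theta - deltas)
    raw_score * theta - sum(log1p(exp(theta - deltas))) +
      0.5 * log(sum(p * (1 - p)))
  }
  grid <- seq(-8, 8, by = 0.01)
  vals <- vapply(grid, obj, numeric(1L))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

# small calibrated bank for layout tests
tiny_bank <- function() {
  item_bank(data.frame(
    item_id = c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6"),
    subject_cluster = c("PHYS", "PHYS", "DECEL", "DECEL", "BFHR", "BFHR"),
    answer_key = c(2L, 3L, 1L, 4L, 2L, 1L),
    difficulty = c(-1.5, -0.5, 0.4, 0.55, 1.0, 0.05),
    max_score = 1L), calibration_constraint = "anchored")
}

# one-candidate response matrix over the tiny bank
tiny_scores <- function(scores = c(1L, 1L, 0L, 0L, 1L, 0L)) {
  m <- matrix(scores, nrow = 1L,
              dimnames = list("CAND1", c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6")))
  response_matrix(m)
}

# the frozen fixture candidate used for golden-file renders: anchored true
# difficulties (no calibration in the path) keep the layout exactly
# reproducible
golden_layout <- function() {
  fx <- make_fsep_fixture(seed = 1)
  build_gim("C0007", fx$responses, fx$bank, pass_line = "75%")
}
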
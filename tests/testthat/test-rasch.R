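test_that("item characteristic curve matches its closed form", {
  expect_equal(icc_probability(0, 0), 0.5)
  expect_equal(icc_probability(log(3), 0), 0.75)
  expect_equal(icc_probability(0, log(3)), 0.25)
  # monotone in both arguments
  th <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(icc_probability(th, 0)) > 0))
  expect_true(all(diff(icc_probability(0, th)) < 0))
  expect_error(icc_probability(Inf, 0), "finite")
})

test_that("ESF recursion agrees with subset enumeration", {
  expect_equal(elementary_symmetric(c(0, 0, 0)), c(1, 3, 3, 1))
  expect_equal(elementary_symmetric(numeric(0)), 1)
  d <- c(-1, 0, 2)
  expect_equal(elementary_symmetric(d), esf_enumerate(d),
               tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:12, 1L)
    d <- stats::rnorm(n, sd = 1.5)
    g <- elementary_symmetric(d)
    expect_equal(g[1], 1)
    expect_true(all(g > 0))
    expect_equal(length(g), n + 1L)
    expect_lt(max(abs(g - esf_enumerate(d)) / esf_enumerate(d)), 1e-10)
  }
})

test_that("CML estimates are sign-symmetric for symmetric two-item data", {
  # counts symmetric under swapping the two items: pattern 10 and 01
  # equally frequent forces delta = (-d, +d) ... with equal frequencies,
  # d = 0; unbalanced frequencies give opposite-signed estimates
  x <- rbind(matrix(rep(c(1L, 0L), 30), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 10), ncol = 2, byrow = TRUE))
  dimnames(x) <- list(sprintf("P%02d", 1:40), c("A", "B"))
  cal <- calibrate_cml(response_matrix(x))
  expect_equal(unname(cal$difficulties["A"] + cal$difficulties["B"]), 0,
               tolerance = 1e-10)
  expect_lt(cal$difficulties["A"], 0)   # A answered correctly more often
})

test_that("permuting item columns permutes the difficulty estimates", {
  spec <- simulation_spec(150, 0, 1, c(a = -1, b = 0, c = 0.5, d = 1.2),
                          seed = 5)
  sim <- simulate_rasch(spec)
  cal <- calibrate_cml(sim$responses)
  perm <- c("c", "a", "d", "b")
  cal_p <- calibrate_cml(response_matrix(sim$responses$scores[, perm]))
  expect_equal(cal_p$difficulties[perm], cal$difficulties[perm],
               tolerance = 1e-9)
})

test_that("CML matches a derivative-free maximisation of its own objective", {
  deltas <- c(A = -1.2, B = -0.4, C = 0.1, D = 0.7, E = 1.5)
  sim <- simulate_rasch(simulation_spec(200, 0, 1, deltas, seed = 42))
  cal <- calibrate_cml(sim$responses)
  expect_true(cal$converged)
  oracle <- cml_oracle(sim$responses$scores)
  expect_lt(max(abs(cal$difficulties - oracle)), 1e-6)
  expect_equal(mean(cal$difficulties), 0, tolerance = 1e-10)
  expect_true(all(cal$se > 0))
})

test_that("degenerate items and extreme persons are excluded with a report", {
  set.seed(9)
  x <- matrix(rbinom(200, 1L, 0.6), 40, 5,
              dimnames = list(sprintf("P%02d", 1:40), paste0("I", 1:5)))
  x[, 3] <- 1L                      # answered correctly by everyone
  x[7, ] <- c(0L, 0L, 1L, 0L, 0L)  # extreme after item exclusion? keep mixed
  x[8, -3] <- 1L                    # perfect on retained items
  cal <- calibrate_cml(response_matrix(x))
  expect_true("I3" %in% cal$excluded_items)
  expect_true("P08" %in% cal$excluded_persons)
  expect_false("I3" %in% names(cal$difficulties))
  expect_equal(length(cal$difficulties), 4L)
})

test_that("translation gauge: shifting theta and delta together is invisible", {
  th <- 0.7; d <- c(-1, 0.2, 1.5); cc <- 0.9
  expect_equal(icc_probability(th + cc, d + cc), icc_probability(th, d))
  # and the mean-zero constraint fixes the gauge on reported estimates
  sim <- simulate_rasch(simulation_spec(100, 0, 1,
                                        c(u = -0.5, v = 0, w = 0.5),
                                        seed = 3))
  cal <- calibrate_cml(sim$responses)
  expect_equal(mean(cal$difficulties), 0, tolerance = 1e-10)
})

test_that("weighted likelihood ability is symmetric, sufficient and finite", {
  # symmetric item set, half marks -> ability 0
  est <- estimate_ability_wle(2L, c(-1, -1, 1, 1))
  expect_equal(est$ability, 0, tolerance = 1e-9)
  # depends on the raw score only
  e1 <- estimate_ability_wle(3L, c(-1, 0, 0.5, 1.2, 2))
  e2 <- estimate_ability_wle(3L, c(-1, 0, 0.5, 1.2, 2))
  expect_identical(e1$ability, e2$ability)
  expect_identical(e1$se, e2$se)
  # finite at the extremes
  expect_true(is.finite(estimate_ability_wle(0L, c(-1, 0, 2))$ability))
  expect_true(is.finite(estimate_ability_wle(3L, c(-1, 0, 2))$ability))
  expect_error(estimate_ability_wle(4L, c(-1, 0, 2)), "raw_score")
})

test_that("WLE matches a grid-search maximiser of the weighted likelihood", {
  deltas <- c(-1, 0, 2)
  for (r in 0:3) {
    est <- estimate_ability_wle(r, deltas)
    expect_equal(est$ability, wle_oracle(r, deltas), tolerance = 1e-6)
  }
})

test_that("test characteristic curve and its inverse are consistent", {
  expect_equal(expected_score(0, rep(0, 60)), 30)
  d <- c(-1, 0, 2)
  expect_equal(expected_score(1, d),
               plogis(1 - -1) + plogis(1 - 0) + plogis(1 - 2))
  th <- seq(-5, 5, by = 0.25)
  es <- vapply(th, expected_score, numeric(1L), deltas = d)
  expect_true(all(diff(es) > 0))
  for (t0 in c(-2, 0, 2)) {
    expect_equal(invert_tcc(expected_score(t0, d), d), t0,
                 tolerance = 1e-8)
  }
  expect_error(invert_tcc(0, d), "strictly inside")
  expect_error(invert_tcc(3, d), "strictly inside")
})

test_that("infit and outfit match direct hand evaluation on a tiny matrix", {
  x <- matrix(c(1L, 0L, 1L,
                0L, 1L, 1L), nrow = 3L,
              dimnames = list(c("P1", "P2", "P3"), c("A", "B")))
  theta <- c(-0.5, 0.2, 1.1)
  deltas <- c(A = -0.3, B = 0.4)
  abil <- data.frame(candidate_id = rownames(x), ability = theta)
  fit <- item_fit(response_matrix(x), deltas, abil)
  p <- plogis(outer(theta, deltas, `-`))
  w <- p * (1 - p)
  sq <- (x - p)^2
  expect_equal(fit$infit_ms, unname(colSums(sq) / colSums(w)))
  expect_equal(fit$outfit_ms, unname(colMeans(sq / w)))
})

test_that("model-conforming data has near-unit mean squares; a miskeyed item blows up outfit", {
  deltas <- seq(-2, 2, length.out = 20)
  names(deltas) <- sprintf("I%02d", 1:20)
  sim <- simulate_rasch(simulation_spec(2000, 0, 1, deltas, seed = 7))
  pers <- estimate_persons(sim$responses, deltas)
  fit <- item_fit(sim$responses, deltas, pers)
  in_band <- fit$infit_ms >= 0.8 & fit$infit_ms <= 1.2 &
    fit$outfit_ms >= 0.8 & fit$outfit_ms <= 1.2
  expect_gte(mean(in_band), 0.95)

  flipped <- sim$responses$scores
  flipped[, "I10"] <- 1L - flipped[, "I10"]
  pers_f <- estimate_persons(response_matrix(flipped), deltas)
  fit_f <- item_fit(response_matrix(flipped), deltas, pers_f)
  expect_gt(fit_f$outfit_ms[fit_f$item_id == "I10"], 1.5)
})
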
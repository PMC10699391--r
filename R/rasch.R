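#' Rasch item characteristic curve
#'
#' Probability of a correct response under the dichotomous Rasch model,
#' `P = exp(theta - delta) / (1 + exp(theta - delta))`. Vectorised over
#' both arguments with the usual recycling.
#'
#' @param theta person ability in logits.
#' @param delta item difficulty in logits.
#' @return Probability strictly in (0, 1).
#' @export
icc_probability <- function(theta, delta) {
  if (any(!is.finite(theta)) || any(!is.finite(delta))) {
    stop("theta and delta must be finite", call. = FALSE)
  }
  stats::plogis(theta - delta)
}

#' Elementary symmetric functions of item easiness terms
#'
#' For difficulties `deltas`, the easiness terms are `eps_i = exp(-delta_i)`
#' and `gamma_r` is the sum over all r-subsets of the products of their
#' easiness terms. These are the normalising constants of the conditional
#' (raw-score-given) response-pattern likelihood. Computed by the stable
#' summation recursion (one pass per item), not subset enumeration.
#'
#' @param deltas numeric vector of difficulties in logits.
#' @return Numeric vector `gamma_0 .. gamma_n` of length `length(deltas) + 1`.
#' @export
elementary_symmetric <- function(deltas) {
  if (any(!is.finite(deltas))) stop("deltas must be finite", call. = FALSE)
  esf_of_eps(exp(-deltas))
}

# summation recursion on easiness terms; returns gamma_0..gamma_n
esf_of_eps <- function(eps) {
  n <- length(eps)
  g <- c(1, numeric(n))
  for (i in seq_len(n)) {
    g[2:(i + 1L)] <- g[2:(i + 1L)] + eps[i] * g[1:i]
  }
  g
}

# leave-one-out ESFs: row i holds gamma^{(i)}_0..gamma^{(i)}_{n-1}
esf_loo <- function(eps) {
  n <- length(eps)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    out[i, ] <- esf_of_eps(eps[-i])
  }
  out
}

# conditional log-likelihood of item difficulties given raw scores.
# s = per-item correct counts, nr = counts of persons by raw score 1..n-1
cml_loglik <- function(deltas, s, nr) {
  g <- elementary_symmetric(deltas)
  r <- seq_along(nr)
  -sum(s * deltas) - sum(nr * log(g[r + 1L]))
}

# gradient and expected (Fisher) information of the CML log-likelihood.
# pi_ri = P(item i correct | raw score r) = eps_i * gamma^{(i)}_{r-1} / gamma_r
cml_score_info <- function(deltas, s, nr) {
  n <- length(deltas)
  eps <- exp(-deltas)
  g <- esf_of_eps(eps)
  gloo <- esf_loo(eps)
  rs <- seq_along(nr)                    # raw scores 1..n-1
  # pi[r, i]
  pi_ri <- t(eps * gloo[, rs, drop = FALSE]) / g[rs + 1L]
  grad <- -s + colSums(nr * pi_ri)
  info <- matrix(0, n, n)
  # off-diagonals need pair-deleted ESFs gamma^{(i,j)}_{r-2}:
  # pi_rij = E[x_i x_j | r] = eps_i eps_j gamma^{(i,j)}_{r-2} / gamma_r,
  # zero for r < 2; info_ij = sum_r n_r (pi_rij - pi_ri pi_rj)
  for (i in seq_len(n - 1L)) {
    sub <- esf_loo(eps[-i])              # row j': gamma^{(i,j')}_0..n-2
    jj <- (i + 1L):n
    for (j in jj) {
      jred <- j - 1L                     # index of j within eps[-i]
      pij <- numeric(length(rs))
      ok <- rs >= 2L
      pij[ok] <- eps[i] * eps[j] * sub[jred, rs[ok] - 1L] / g[rs[ok] + 1L]
      info[i, j] <- info[j, i] <-
        sum(nr * (pij - pi_ri[, i] * pi_ri[, j]))
    }
  }
  diag(info) <- colSums(nr * pi_ri * (1 - pi_ri))
  list(grad = grad, info = info, pi = pi_ri)
}

#' Calibrate item difficulties by conditional maximum likelihood
#'
#' Estimates dichotomous Rasch difficulties by maximising the conditional
#' likelihood of the response patterns given raw scores, which eliminates
#' the person parameters through elementary symmetric functions. Newton
#' iterations (with step halving) run until the gradient maximum norm
#' falls below `tol` or `max_iter` is reached. Persons with extreme raw
#' scores (0 or all retained items) carry no conditional information and
#' are excluded, as are items answered all-correctly or all-incorrectly
#' by the retained persons; both exclusions are reported, never silent.
#' The mean-zero identification constraint is applied to the estimates.
#'
#' @param responses a [response_matrix()] of dichotomous scores (`NA`
#'   cells are treated as not administered and scored 0 for raw-score
#'   purposes only if absent; calibration requires complete data).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#' @return A list of class `calibration_result` with components
#'   `difficulties` (named, mean zero), `se` (standard errors in logits),
#'   `converged`, `iterations`, `loglik`, `excluded_items`,
#'   `excluded_persons`.
#' @export
calibrate_cml <- function(responses, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(responses, "response_matrix"))
  x <- responses$scores
  if (anyNA(x)) {
    stop("calibration requires complete dichotomous responses", call. = FALSE)
  }
  if (any(responses$max_score != 1L)) {
    stop("calibrate_cml handles dichotomous items only", call. = FALSE)
  }
  if (ncol(x) < 2L) stop("calibration needs at least 2 items", call. = FALSE)

  excluded_items <- character(0)
  excluded_persons <- character(0)
  # alternate exclusions until stable: dropping extreme persons can
  # degenerate further items and vice versa
  repeat {
    keep_i <- !(colnames(x) %in% excluded_items)
    keep_p <- !(rownames(x) %in% excluded_persons)
    sub <- x[keep_p, keep_i, drop = FALSE]
    col_tot <- colSums(sub)
    bad_i <- colnames(sub)[col_tot == 0L | col_tot == nrow(sub)]
    if (length(bad_i) > 0L) {
      excluded_items <- c(excluded_items, bad_i)
      next
    }
    row_tot <- rowSums(sub)
    bad_p <- rownames(sub)[row_tot == 0L | row_tot == ncol(sub)]
    if (length(bad_p) > 0L) {
      excluded_persons <- c(excluded_persons, bad_p)
      next
    }
    break
  }
  n <- ncol(sub)
  if (n < 2L) {
    stop("fewer than 2 items remain after degenerate-item exclusion",
         call. = FALSE)
  }
  s <- colSums(sub)
  r_person <- rowSums(sub)
  nr <- tabulate(r_person, nbins = n - 1L)   # raw scores 1..n-1

  # gauge: optimise with delta_1 fixed at 0, recenter afterwards
  delta <- numeric(n)
  free <- 2:n
  converged <- FALSE
  iter <- 0L
  ll <- cml_loglik(delta, s, nr)
  si <- cml_score_info(delta, s, nr)
  while (iter < max_iter) {
    # the full gradient always sums to zero, so checking all of it is
    # equivalent to checking the identified (free) block
    if (max(abs(si$grad)) < tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    step <- solve(si$info[free, free, drop = FALSE], si$grad[free])
    # step halving on the conditional log-likelihood
    lam <- 1
    repeat {
      cand <- delta
      cand[free] <- delta[free] + lam * step
      ll_new <- cml_loglik(cand, s, nr)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    delta <- cand
    ll <- ll_new
    si <- cml_score_info(delta, s, nr)
  }
  if (max(abs(si$grad)) < tol) converged <- TRUE
  delta <- delta - mean(delta)
  names(delta) <- colnames(sub)
  # covariance of the free parameters (gauge delta_1 = 0), projected onto
  # the reported mean-centred scale: delta_tilde = M delta_free with
  # M = (I - 11'/n)[, -1]
  vcv <- solve(si$info[free, free, drop = FALSE])
  m <- (diag(n) - matrix(1 / n, n, n))[, -1L, drop = FALSE]
  se <- sqrt(diag(m %*% vcv %*% t(m)))
  names(se) <- colnames(sub)
  structure(list(difficulties = delta, se = se, converged = converged,
                 iterations = iter, loglik = ll,
                 excluded_items = excluded_items,
                 excluded_persons = excluded_persons),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d items, converged = %s in %d iterations\n",
              length(x$difficulties), x$converged, x$iterations))
  if (length(x$excluded_items) > 0L) {
    cat("  excluded items: ", paste(x$excluded_items, collapse = ", "), "\n")
  }
  if (length(x$excluded_persons) > 0L) {
    cat(sprintf("  excluded persons (extreme scores): %d\n",
                length(x$excluded_persons)))
  }
  invisible(x)
}

#' Warm's weighted likelihood ability estimate
#'
#' Solves `r - sum(p_i) + J/(2 I) = 0` for the ability `theta`, where
#' `p_i` is the Rasch correct-response probability, `I = sum p(1-p)` is
#' the test information and `J = sum p(1-p)(1-2p)` its derivative. The
#' weighted likelihood estimator is finite at raw scores 0 and n, so an
#' ability (and hence a map) exists for every candidate. Standard error
#' is `1/sqrt(I)` at the estimate.
#'
#' @param raw_score integer raw score, `0 <= r <= length(deltas)`.
#' @param deltas calibrated item difficulties in logits.
#' @param candidate_id optional id carried into the result.
#' @param tol residual tolerance of the root solve.
#' @return A list of class `person_estimate`: `candidate_id`, `raw_score`,
#'   `ability` (logits), `se`, `n_administered`.
#' @export
estimate_ability_wle <- function(raw_score, deltas, candidate_id = NA_character_,
                                 tol = 1e-10) {
  n <- length(deltas)
  if (!is.finite(raw_score) || raw_score < 0 || raw_score > n ||
      raw_score != round(raw_score)) {
    stop("raw_score must be an integer in [0, ", n, "]", call. = FALSE)
  }
  resid <- function(theta) {
    p <- icc_probability(theta, deltas)
    info <- sum(p * (1 - p))
    j <- sum(p * (1 - p) * (1 - 2 * p))
    raw_score - sum(p) + j / (2 * info)
  }
  # residual is decreasing in theta; bracket then safeguarded Newton/bisection
  lo <- -10; hi <- 10
  while (resid(lo) < 0) lo <- lo - 5
  while (resid(hi) > 0) hi <- hi + 5
  theta <- (lo + hi) / 2
  for (it in 1:200) {
    f <- resid(theta)
    if (abs(f) < tol) break
    if (f > 0) lo <- theta else hi <- theta
    p <- icc_probability(theta, deltas)
    dfdt <- -sum(p * (1 - p))   # dominant term; safeguards absorb the rest
    cand <- theta - f / dfdt
    theta <- if (is.finite(cand) && cand > lo && cand < hi) cand
             else (lo + hi) / 2
  }
  p <- icc_probability(theta, deltas)
  info <- sum(p * (1 - p))
  structure(list(candidate_id = candidate_id,
                 raw_score = as.integer(raw_score),
                 ability = theta, se = 1 / sqrt(info),
                 n_administered = n),
            class = "person_estimate")
}

#' @export
print.person_estimate <- function(x, ...) {
  cat(sprintf("<person_estimate> %s: r = %d/%d, theta = %.3f (SE %.3f)\n",
              x$candidate_id, x$raw_score, x$n_administered, x$ability, x$se))
  invisible(x)
}

#' Estimate abilities for every candidate in a response matrix
#'
#' By Rasch sufficiency the weighted likelihood estimate depends only on
#' the raw score, so each distinct score is solved once and shared.
#'
#' @param responses a [response_matrix()].
#' @param deltas calibrated difficulties named by item id (a calibrated
#'   [item_bank()] is also accepted).
#' @return A data frame: `candidate_id`, `raw_score`, `ability`, `se`.
#' @export
estimate_persons <- function(responses, deltas) {
  if (inherits(deltas, "item_bank")) {
    deltas <- stats::setNames(deltas$items$difficulty, deltas$items$item_id)
  }
  x <- responses$scores[, names(deltas), drop = FALSE]
  r <- rowSums(x, na.rm = TRUE)
  uniq <- sort(unique(r))
  lut <- lapply(uniq, estimate_ability_wle, deltas = deltas)
  idx <- match(r, uniq)
  data.frame(candidate_id = rownames(x),
             raw_score = as.integer(r),
             ability = vapply(lut, `[[`, numeric(1L), "ability")[idx],
             se = vapply(lut, `[[`, numeric(1L), "se")[idx],
             stringsAsFactors = FALSE)
}

#' Test characteristic curve: expected raw score at an ability
#'
#' @param theta ability in logits (scalar).
#' @param deltas item difficulties in logits.
#' @return Expected raw score `sum_i P(theta, delta_i)`, in `(0, n)`.
#' @export
expected_score <- function(theta, deltas) {
  sum(icc_probability(theta, deltas))
}

#' Invert the test characteristic curve
#'
#' Returns the ability whose expected raw score equals `target_score`,
#' by bisection on an expanding bracket. Used to convert a raw or
#' percentage pass mark into the logit pass line drawn on a map.
#'
#' @param target_score target expected raw score, strictly inside `(0, n)`.
#' @param deltas item difficulties in logits.
#' @param tol tolerance on the expected-score residual.
#' @return Ability in logits.
#' @export
invert_tcc <- function(target_score, deltas, tol = 1e-8) {
  n <- length(deltas)
  if (!is.finite(target_score) || target_score <= 0 || target_score >= n) {
    stop("target_score must lie strictly inside (0, ", n, ")", call. = FALSE)
  }
  lo <- -10; hi <- 10
  while (expected_score(lo, deltas) > target_score) lo <- lo - 5
  while (expected_score(hi, deltas) < target_score) hi <- hi + 5
  # bisect to interval width 1e-12 so the ability itself (not only the
  # expected score) is pinned well inside the tolerance
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (expected_score(mid, deltas) < target_score) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(expected_score(mid, deltas) - target_score) > tol) {
    stop("TCC inversion did not reach tolerance", call. = FALSE)
  }
  mid
}

#' Infit and outfit mean-square item fit statistics
#'
#' With standardised residuals `z = (x - p) / sqrt(p (1 - p))`, outfit is
#' the unweighted mean of `z^2` over persons and infit the information-
#' weighted ratio `sum (x - p)^2 / sum p (1 - p)`. Cells whose model
#' probability is numerically 0 or 1 are excluded from the sums and the
#' exclusion count reported. Both statistics have expectation near 1 for
#' model-conforming data; large outfit flags unexpected responses such as
#' a miskeyed item.
#'
#' @param responses a [response_matrix()].
#' @param deltas calibrated difficulties named by item id.
#' @param abilities data frame from [estimate_persons()] (or any with
#'   `candidate_id` and `ability`).
#' @return Data frame: `item_id`, `infit_ms`, `outfit_ms`, `n_excluded`.
#' @export
item_fit <- function(responses, deltas, abilities) {
  x <- responses$scores[abilities$candidate_id, names(deltas), drop = FALSE]
  theta <- abilities$ability
  p <- stats::plogis(outer(theta, deltas, `-`))
  eps <- .Machine$double.eps
  usable <- p > eps & p < 1 - eps & !is.na(x)
  w <- p * (1 - p)
  sq <- (x - p)^2
  infit <- colSums(sq * usable, na.rm = TRUE) /
    colSums(w * usable, na.rm = TRUE)
  outfit <- colSums((sq / w) * usable, na.rm = TRUE) / colSums(usable)
  res <- data.frame(item_id = names(deltas),
                    infit_ms = unname(infit),
                    outfit_ms = unname(outfit),
                    n_excluded = as.integer(colSums(!usable)),
                    stringsAsFactors = FALSE)
  total_excl <- sum(res$n_excluded)
  if (total_excl > 0L) {
    message(total_excl, " cell(s) with degenerate model probability excluded",
            " from fit sums")
  }
  res
}
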
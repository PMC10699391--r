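#' Simulation specification
#'
#' @param n_persons number of simulated candidates.
#' @param ability_mean,ability_sd parameters of the Normal ability
#'   distribution in logits.
#' @param difficulties item difficulties in logits; item ids are
#'   `I01, I02, ...` unless the vector is named.
#' @param seed integer seed; equal seeds give identical output.
#' @param model `"rasch"` or `"pcm"`.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_persons, ability_mean = 0, ability_sd = 1,
                            difficulties, seed = 1L,
                            model = c("rasch", "pcm")) {
  model <- match.arg(model)
  stopifnot(n_persons >= 1L, ability_sd >= 0)
  if (is.null(names(difficulties))) {
    names(difficulties) <- sprintf("I%02d", seq_along(difficulties))
  }
  structure(list(n_persons = as.integer(n_persons),
                 ability_mean = ability_mean, ability_sd = ability_sd,
                 difficulties = difficulties, seed = as.integer(seed),
                 model = model),
            class = "simulation_spec")
}

#' Simulate dichotomous Rasch responses
#'
#' Draws abilities from the configured Normal distribution and responses
#' as Bernoulli trials with success probability given by the Rasch item
#' characteristic curve. Fully reproducible under the spec's seed.
#'
#' @param spec a [simulation_spec()] with `model = "rasch"`.
#' @return List: `responses` (a [response_matrix()]), `abilities`
#'   (data frame `candidate_id`, `theta`).
#' @export
simulate_rasch <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), spec$model == "rasch")
  n <- spec$n_persons
  deltas <- spec$difficulties
  set.seed(spec$seed)
  theta <- stats::rnorm(n, spec$ability_mean, spec$ability_sd)
  p <- stats::plogis(outer(theta, deltas, `-`))
  x <- matrix(stats::rbinom(length(p), 1L, p), nrow = n)
  ids <- sprintf("C%04d", seq_len(n))
  dimnames(x) <- list(ids, names(deltas))
  list(responses = response_matrix(x),
       abilities = data.frame(candidate_id = ids, theta = theta,
                              stringsAsFactors = FALSE))
}

#' Simulate partial-credit responses
#'
#' Scores are drawn from the partial credit model category distribution
#' at each simulated ability. With single-threshold items this is the
#' dichotomous Rasch simulation in different clothing.
#'
#' @param spec a [simulation_spec()] with `model = "pcm"`; its
#'   `difficulties` entry is ignored in favour of `thresholds`.
#' @param thresholds list of per-item threshold vectors, named by item id.
#' @return List: `responses` (a [response_matrix()] of polytomous
#'   scores), `abilities` (data frame).
#' @export
simulate_pcm <- function(spec, thresholds) {
  stopifnot(inherits(spec, "simulation_spec"), spec$model == "pcm")
  n <- spec$n_persons
  if (is.null(names(thresholds))) {
    names(thresholds) <- sprintf("P%02d", seq_along(thresholds))
  }
  set.seed(spec$seed)
  theta <- stats::rnorm(n, spec$ability_mean, spec$ability_sd)
  x <- matrix(0L, n, length(thresholds),
              dimnames = list(sprintf("C%04d", seq_len(n)),
                              names(thresholds)))
  for (j in seq_along(thresholds)) {
    m <- length(thresholds[[j]])
    for (i in seq_len(n)) {
      pr <- pcm_category_probability(theta[i], thresholds[[j]])
      x[i, j] <- sample.int(m + 1L, 1L, prob = pr) - 1L
    }
  }
  list(responses = response_matrix(x,
                                   max_score = lengths(thresholds)),
       abilities = data.frame(candidate_id = rownames(x), theta = theta,
                              stringsAsFactors = FALSE))
}

#' FSEP-shaped synthetic fixture
#'
#' Emulates the shape of the operational assessment (whose item bank and
#' candidate data are confidential): a 60-item dichotomous bank with
#' true difficulties evenly spaced on \[-3, 3\] logits (the span visible
#' on published maps), subject clusters assigned round-robin over the
#' eight canonical FSEP labels, and 200 candidates with abilities drawn
#' from Normal(0.5, 1). Responses follow the Rasch model.
#'
#' @param seed integer seed.
#' @param n_persons cohort size (default 200).
#' @return List: `bank` (an [item_bank()] carrying the true difficulties,
#'   mean-centred), `responses`, `abilities` (with true `theta`), and
#'   `true_difficulties`.
#' @export
make_fsep_fixture <- function(seed = 1L, n_persons = 200L) {
  n_items <- 60L
  deltas <- seq(-3, 3, length.out = n_items)
  deltas <- deltas - mean(deltas)
  names(deltas) <- sprintf("Q%02d", seq_len(n_items))
  clusters <- rep_len(fsep_clusters, n_items)
  spec <- simulation_spec(n_persons = n_persons, ability_mean = 0.5,
                          ability_sd = 1, difficulties = deltas,
                          seed = seed, model = "rasch")
  sim <- simulate_rasch(spec)
  bank <- item_bank(data.frame(item_id = names(deltas),
                               subject_cluster = clusters,
                               answer_key = 1L,
                               difficulty = unname(deltas),
                               max_score = 1L,
                               stringsAsFactors = FALSE))
  list(bank = bank, responses = sim$responses, abilities = sim$abilities,
       true_difficulties = deltas)
}
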
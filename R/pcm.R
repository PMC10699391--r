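#' Partial credit model category probabilities
#'
#' Masters' partial credit model: for an item with adjacent-category
#' thresholds `delta_1 .. delta_m`, the probability of scoring `k` is
#' proportional to `exp(sum_{j <= k} (theta - delta_j))`, with an empty
#' sum (hence weight 1) for `k = 0`. With a single threshold the model
#' reduces exactly to the dichotomous Rasch item characteristic curve.
#'
#' @param theta ability in logits (scalar).
#' @param thresholds numeric vector of category thresholds in logits.
#' @return Probability vector over scores `0..m`, summing to 1.
#' @export
pcm_category_probability <- function(theta, thresholds) {
  if (!is.finite(theta) || any(!is.finite(thresholds))) {
    stop("theta and thresholds must be finite", call. = FALSE)
  }
  m <- length(thresholds)
  # cumulative exponents, stabilised by subtracting the maximum
  expo <- c(0, cumsum(theta - thresholds))
  w <- exp(expo - max(expo))
  p <- w / sum(w)
  names(p) <- as.character(0:m)
  p
}

#' Construct a partial-credit item
#'
#' @param item_id item id.
#' @param subject_cluster subject cluster label.
#' @param thresholds adjacent-category thresholds `delta_1..delta_m` in
#'   logits; `m` is the maximum score.
#' @return An object of class `pcm_item`.
#' @export
pcm_item <- function(item_id, subject_cluster, thresholds) {
  if (length(thresholds) < 1L || any(!is.finite(thresholds))) {
    stop("thresholds must be a non-empty finite vector", call. = FALSE)
  }
  structure(list(item_id = as.character(item_id),
                 subject_cluster = as.character(subject_cluster),
                 thresholds = as.numeric(thresholds),
                 max_score = length(thresholds)),
            class = "pcm_item")
}

#' Map a partial-credit item onto the graphical item map
#'
#' Each score category is placed at the vertical position of its own
#' threshold: categories up to and including the attained score go to
#' the left (attained) side, the remaining categories to the right
#' (not attained). A candidate who scored two of a possible three thus
#' sees categories 1 and 2 on the left and category 3 on the right.
#'
#' @param attained_score integer score in `0..m`.
#' @param item a [pcm_item()].
#' @return Data frame of class `pcm_placement`: `item_id`, `category`,
#'   `side` (`"left_attained"`/`"right_not_attained"`), `y` (logits).
#' @export
map_pcm_to_gim <- function(attained_score, item) {
  stopifnot(inherits(item, "pcm_item"))
  m <- item$max_score
  if (!is.finite(attained_score) || attained_score != round(attained_score) ||
      attained_score < 0 || attained_score > m) {
    stop("attained_score must be an integer in [0, ", m, "]", call. = FALSE)
  }
  out <- data.frame(
    item_id = rep(item$item_id, m),
    subject_cluster = rep(item$subject_cluster, m),
    category = seq_len(m),
    side = ifelse(seq_len(m) <= attained_score,
                  "left_attained", "right_not_attained"),
    y = item$thresholds,
    stringsAsFactors = FALSE)
  class(out) <- c("pcm_placement", "data.frame")
  out
}

#' Read a polytomous item bank from CSV
#'
#' Columns: `item_id,subject_cluster,max_score,threshold_1..threshold_m`.
#' Items may have differing `max_score`; unused threshold cells are blank.
#'
#' @param path file path.
#' @return List of [pcm_item()] objects, named by item id.
#' @export
read_pcm_bank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("item_id", "subject_cluster", "max_score")
  if (!all(needed %in% names(df))) {
    stop("polytomous bank needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  items <- lapply(seq_len(nrow(df)), function(i) {
    m <- df$max_score[i]
    cols <- paste0("threshold_", seq_len(m))
    if (!all(cols %in% names(df))) {
      stop("missing threshold column(s) for item ", df$item_id[i],
           call. = FALSE)
    }
    pcm_item(df$item_id[i], df$subject_cluster[i],
             as.numeric(unlist(df[i, cols], use.names = FALSE)))
  })
  names(items) <- df$item_id
  items
}
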
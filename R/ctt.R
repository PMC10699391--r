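#' Item facility (classical test theory)
#'
#' The percentage of respondents answering an item correctly. Responses
#' flagged missing (scored under `blank_policy = "missing"`) are excluded
#' from the denominator.
#'
#' @param responses a [response_matrix()] of dichotomous scores.
#' @param item_id item id, or `NULL` for all items.
#' @return Data frame: `item_id`, `facility` (percentage in \[0, 100\]),
#'   `n_respondents`.
#' @export
facility <- function(responses, item_id = NULL) {
  x <- responses$scores
  ids <- if (is.null(item_id)) colnames(x) else item_id
  missing_items <- setdiff(ids, colnames(x))
  if (length(missing_items) > 0L) {
    stop("item(s) not in response matrix: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  sub <- x[, ids, drop = FALSE]
  n_resp <- colSums(!is.na(sub))
  if (any(n_resp == 0L)) {
    stop("facility undefined (zero counted respondents) for: ",
         paste(ids[n_resp == 0L], collapse = ", "), call. = FALSE)
  }
  data.frame(item_id = ids,
             facility = 100 * colSums(sub == 1L, na.rm = TRUE) / n_resp,
             n_respondents = as.integer(n_resp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Facility-axis vertical position
#'
#' The classical-test-theory map variant places items on a 0-100 axis in
#' "percentage difficulty": `100 - facility`, so harder items sit higher,
#' matching the orientation of the logit axis.
#'
#' @param facility facility percentage in \[0, 100\].
#' @return Axis position `100 - facility`.
#' @export
facility_axis_position <- function(facility) {
  if (any(!is.finite(facility)) || any(facility < 0) || any(facility > 100)) {
    stop("facility must lie in [0, 100]", call. = FALSE)
  }
  100 - facility
}

#' Default FSEP practitioner level bands
#'
#' Level 1 spans 55-65% inclusive and level 3 requires strictly more
#' than 75%; level 2 fills the gap (65, 75\] and scores below 55% are
#' level 0 ("not yet at level 1"). The bands partition \[0, 100\].
#'
#' @return A list of class `level_bands` with the four band definitions.
#' @export
default_level_bands <- function() {
  structure(list(
    # upper bounds; closure: level 0 = [0, 55), 1 = [55, 65],
    # 2 = (65, 75], 3 = (75, 100]
    level1_lower = 55, level1_upper = 65, level3_lower = 75),
    class = "level_bands")
}

#' Classify a percentage score into an FSEP practitioner level
#'
#' @param score percentage score(s) in \[0, 100\].
#' @param bands a `level_bands` object; defaults to the operational
#'   bands (level 1: 55-65 inclusive, level 3: > 75).
#' @return Integer level(s) in `0:3`.
#' @export
classify_practitioner_level <- function(score, bands = default_level_bands()) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100)) {
    stop("score must lie in [0, 100]", call. = FALSE)
  }
  ifelse(score > bands$level3_lower, 3L,
         ifelse(score > bands$level1_upper, 2L,
                ifelse(score >= bands$level1_lower, 1L, 0L)))
}

#' Facility-axis map for a candidate
#'
#' Builds a graphical item map using classical facility indices instead
#' of Rasch difficulties: each item's vertical position is its
#' percentage difficulty (`100 - facility`) on a 0-100 axis. The layout
#' grammar (columns, sides, co-location, flags) is shared with the logit
#' map; the ability line is the candidate's percentage-incorrect level
#' (so it lives on the same percentage-difficulty axis) and the pass line
#' an optional percentage mark, similarly inverted.
#'
#' @param candidate_id candidate to map.
#' @param responses a [response_matrix()].
#' @param bank an [item_bank()] (difficulties not required).
#' @param pass_percent optional pass mark as a percentage score.
#' @param config a [layout_config()]; the co-location tolerance is
#'   interpreted in percentage-difficulty points (default 5).
#' @return A `gim_layout` whose `y` unit is percentage difficulty.
#' @export
build_gim_ctt <- function(candidate_id, responses, bank, pass_percent = NULL,
                          config = layout_config(cluster_tolerance = 5)) {
  fac <- facility(responses)
  bank_ctt <- bank
  bank_ctt$items$difficulty <-
    facility_axis_position(fac$facility[match(bank$items$item_id,
                                              fac$item_id)])
  bank_ctt$calibration_constraint <- "anchored"
  x <- responses$scores[candidate_id, , drop = FALSE]
  pct_correct <- 100 * sum(x == 1L, na.rm = TRUE) / sum(!is.na(x))
  ability <- 100 - pct_correct      # percentage-difficulty units
  pass <- if (is.null(pass_percent)) NULL else 100 - pass_percent
  build_gim(candidate_id, responses, bank_ctt,
            ability = ability, pass_line = pass, config = config)
}
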
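#' Layout configuration for graphical item maps
#'
#' @param cluster_tolerance single-linkage co-location threshold on the
#'   vertical axis (logits for Rasch maps; default 0.15, roughly a
#'   typical difficulty standard error at operational cohort sizes).
#' @param column_order cluster labels left-to-right; defaults to the
#'   canonical FSEP order, with unknown clusters appended alphabetically.
#' @param weakness_min_count minimum number of "easy misses" (incorrect
#'   items at or below the candidate's ability) for a weakness flag.
#' @param strength_min_items minimum cluster size for a strength flag.
#' @param pass_standard optional pass standard in logits, applied when
#'   [build_gim()] is not given one explicitly.
#' @return A list of class `layout_config`.
#' @export
layout_config <- function(cluster_tolerance = 0.15,
                          column_order = fsep_clusters,
                          weakness_min_count = 2L,
                          strength_min_items = 3L,
                          pass_standard = NULL) {
  stopifnot(cluster_tolerance >= 0, weakness_min_count >= 1L,
            strength_min_items >= 1L)
  structure(list(cluster_tolerance = cluster_tolerance,
                 column_order = column_order,
                 weakness_min_count = as.integer(weakness_min_count),
                 strength_min_items = as.integer(strength_min_items),
                 pass_standard = pass_standard),
            class = "layout_config")
}

#' Place one candidate's items left or right of the axis
#'
#' Each administered item is placed at the vertical position given by
#' its calibrated difficulty, to the left of the axis if the candidate
#' answered it correctly and to the right if not.
#'
#' @param candidate_scores named integer vector (or one-row matrix) of
#'   the candidate's dichotomous scores.
#' @param bank a calibrated [item_bank()].
#' @return Data frame: `item_id`, `subject_cluster`, `side`
#'   (`"left_correct"`/`"right_incorrect"`), `y` (difficulty, logits).
#' @export
place_items <- function(candidate_scores, bank) {
  if (is.matrix(candidate_scores)) {
    candidate_scores <- candidate_scores[1L, ]
  }
  ids <- names(candidate_scores)
  ids <- ids[!is.na(candidate_scores)]
  unknown <- setdiff(ids, bank$items$item_id)
  if (length(unknown) > 0L) {
    stop("scored item(s) not in bank: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(ids, bank$items$item_id)
  if (anyNA(bank$items$difficulty[idx])) {
    bad <- ids[is.na(bank$items$difficulty[idx])]
    stop("uncalibrated item(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(item_id = ids,
             subject_cluster = bank$items$subject_cluster[idx],
             side = ifelse(candidate_scores[ids] == 1L,
                           "left_correct", "right_incorrect"),
             y = bank$items$difficulty[idx],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group co-located items within each subject column
#'
#' Within each (cluster, side) cell, items whose difficulties fall
#' within `cluster_tolerance` of a neighbour are merged by single
#' linkage (transitive closure of the pairwise-within-tolerance
#' relation), so a chain of close items forms one group even when its
#' extremes are farther apart than the tolerance. A group's vertical
#' position is the mean difficulty of its members and its label carries
#' the member count in parentheses when it holds two or more items.
#'
#' @param placed data frame from [place_items()].
#' @param config a [layout_config()].
#' @return List with `groups` (data frame: `subject_cluster`, `side`,
#'   `count`, `y`, `label`) and `members` (list of item-id vectors,
#'   aligned with the rows of `groups`).
#' @export
group_colocated <- function(placed, config = layout_config()) {
  tol <- config$cluster_tolerance
  groups <- list()
  members <- list()
  cells <- unique(placed[, c("subject_cluster", "side")])
  cells <- cells[order(cells$subject_cluster, cells$side), , drop = FALSE]
  for (ci in seq_len(nrow(cells))) {
    cell <- placed[placed$subject_cluster == cells$subject_cluster[ci] &
                     placed$side == cells$side[ci], , drop = FALSE]
    cell <- cell[order(cell$y, cell$item_id), , drop = FALSE]
    # single linkage on a line: cut where the gap to the predecessor
    # exceeds the tolerance
    gap <- c(Inf, diff(cell$y))
    gid <- cumsum(gap > tol)
    for (g in unique(gid)) {
      mem <- cell[gid == g, , drop = FALSE]
      n <- nrow(mem)
      cl <- cells$subject_cluster[ci]
      groups[[length(groups) + 1L]] <- data.frame(
        subject_cluster = cl, side = cells$side[ci],
        count = n, y = mean(mem$y),
        label = if (n >= 2L) sprintf("%s (%d)", cl, n) else cl,
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- mem$item_id
    }
  }
  groups <- do.call(rbind, groups)
  # sort groups by vertical position within each column for stable output
  ord <- order(groups$subject_cluster, groups$side, groups$y)
  list(groups = groups[ord, , drop = FALSE],
       members = members[ord])
}

#' Assign pass/fail-by-correctness quadrants
#'
#' A finite pass line splits the map into four quadrants: above/below
#' the pass standard crossed with correct/incorrect. Items exactly on
#' the line fall in the lower quadrants (closed-below convention, so
#' borderline items count toward revision guidance). The lower-right
#' quadrant -- items below the pass standard answered incorrectly -- is
#' the priority revision zone.
#'
#' @param placed data frame from [place_items()].
#' @param pass_line pass standard in logits.
#' @return `placed` with a `quadrant` column (`upper_left`,
#'   `upper_right`, `lower_left`, `lower_right`).
#' @export
assign_quadrants <- function(placed, pass_line) {
  if (!is.finite(pass_line)) stop("pass_line must be finite", call. = FALSE)
  vert <- ifelse(placed$y > pass_line, "upper", "lower")
  horiz <- ifelse(placed$side == "left_correct", "left", "right")
  placed$quadrant <- paste(vert, horiz, sep = "_")
  placed
}

#' Flag subject clusters as strengths or weaknesses
#'
#' A cluster is a potential weakness when at least `weakness_min_count`
#' of its items were missed despite being no harder than the candidate's
#' ability ("easy misses"). It is a potential strength when it holds at
#' least `strength_min_items` items, none of them easy misses, and at
#' least one correctly answered item above the candidate's ability.
#' Weakness takes precedence when both rules fire. Difficulties exactly
#' at the ability line count as "at or below" it.
#'
#' @param placed data frame from [place_items()].
#' @param ability_line candidate ability in logits.
#' @param config a [layout_config()].
#' @return Named character vector over the clusters present:
#'   `"strength"`, `"weakness"` or `"none"`.
#' @export
flag_subjects <- function(placed, ability_line, config = layout_config()) {
  clusters <- unique(placed$subject_cluster)
  flags <- vapply(clusters, function(cl) {
    sub <- placed[placed$subject_cluster == cl, , drop = FALSE]
    easy_miss <- sub$side == "right_incorrect" & sub$y <= ability_line
    hard_hit <- sub$side == "left_correct" & sub$y > ability_line
    if (sum(easy_miss) >= config$weakness_min_count) return("weakness")
    if (nrow(sub) >= config$strength_min_items && sum(easy_miss) == 0L &&
        sum(hard_hit) >= 1L) {
      return("strength")
    }
    "none"
  }, character(1L))
  names(flags) <- clusters
  flags
}

new_gim_layout <- function(candidate_id, ability_line, pass_line, columns,
                           placed, groups, group_members, flags) {
  structure(list(candidate_id = candidate_id,
                 ability_line = ability_line,
                 pass_line = pass_line,
                 columns = columns,
                 placed = placed,
                 groups = groups,
                 group_members = group_members,
                 flags = flags),
            class = "gim_layout")
}

#' Build a graphical item map for one candidate
#'
#' Orchestrates the full construction: item placement (left = correct,
#' right = incorrect, vertical = difficulty), co-location grouping,
#' quadrant assignment when a pass standard is available, and subject
#' strength/weakness flagging against the candidate's ability line.
#' Columns follow the configured order (canonical FSEP order by
#' default); clusters absent from that order are appended alphabetically.
#'
#' @param candidate_id candidate to map.
#' @param responses a [response_matrix()].
#' @param bank a calibrated [item_bank()].
#' @param abilities optional data frame from [estimate_persons()]; the
#'   candidate's ability is looked up there. Ignored when `ability` is
#'   given directly. When both are absent the ability is estimated on
#'   the fly from the bank difficulties.
#' @param ability candidate ability in logits (overrides `abilities`).
#' @param pass_line pass standard. Either a number in logits, or a
#'   string like `"75%"` converted through [invert_tcc()] on the bank.
#'   `NULL` (with no `config$pass_standard`) omits the line and the
#'   quadrants.
#' @param config a [layout_config()].
#' @return An object of class `gim_layout`.
#' @export
build_gim <- function(candidate_id, responses, bank, abilities = NULL,
                      ability = NULL, pass_line = NULL,
                      config = layout_config()) {
  if (!candidate_id %in% rownames(responses$scores)) {
    stop("candidate not in responses: ", candidate_id, call. = FALSE)
  }
  row <- stats::setNames(responses$scores[candidate_id, ],
                         colnames(responses$scores))
  placed <- place_items(row, bank)
  if (is.null(ability)) {
    if (!is.null(abilities)) {
      hit <- match(candidate_id, abilities$candidate_id)
      if (is.na(hit)) {
        stop("candidate not in abilities table: ", candidate_id,
             call. = FALSE)
      }
      ability <- abilities$ability[hit]
    } else {
      deltas <- stats::setNames(bank$items$difficulty, bank$items$item_id)
      deltas <- deltas[placed$item_id]
      ability <- estimate_ability_wle(sum(row == 1L, na.rm = TRUE),
                                      deltas, candidate_id)$ability
    }
  }
  if (is.null(pass_line)) pass_line <- config$pass_standard
  if (is.character(pass_line)) {
    pct <- as.numeric(sub("%$", "", pass_line))
    if (!is.finite(pct) || pct <= 0 || pct >= 100) {
      stop("percentage pass standard must be inside (0, 100): ", pass_line,
           call. = FALSE)
    }
    deltas <- bank$items$difficulty[match(placed$item_id,
                                          bank$items$item_id)]
    pass_line <- invert_tcc(pct / 100 * nrow(placed), deltas)
  }
  if (!is.null(pass_line)) {
    placed <- assign_quadrants(placed, pass_line)
  } else {
    placed$quadrant <- NA_character_
  }
  grp <- group_colocated(placed, config)
  flags <- flag_subjects(placed, ability, config)
  present <- unique(placed$subject_cluster)
  columns <- c(intersect(config$column_order, present),
               sort(setdiff(present, config$column_order)))
  new_gim_layout(candidate_id = candidate_id,
                 ability_line = ability,
                 pass_line = pass_line,
                 columns = columns,
                 placed = placed,
                 groups = grp$groups,
                 group_members = grp$members,
                 flags = flags[columns])
}

#' @export
print.gim_layout <- function(x, ...) {
  cat(sprintf("<gim_layout> candidate %s: %d items in %d groups, theta = %.3f\n",
              x$candidate_id, nrow(x$placed), nrow(x$groups), x$ability_line))
  if (!is.null(x$pass_line)) {
    cat(sprintf("  pass line at %.3f logits; quadrant counts: %s\n",
                x$pass_line,
                paste(names(table(x$placed$quadrant)),
                      table(x$placed$quadrant), sep = "=", collapse = " ")))
  }
  flagged <- x$flags[x$flags != "none"]
  if (length(flagged) > 0L) {
    cat("  flags: ", paste(names(flagged), flagged, sep = ":",
                           collapse = " "), "\n")
  }
  invisible(x)
}
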
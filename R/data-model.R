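#' Canonical FSEP subject clusters
#'
#' The eight knowledge-domain abbreviations used by the FSEP assessment,
#' in their canonical display order: fetal heart rate physiology (PHYS),
#' utero-placental function including hyperstimulation (UPFH), the normal
#' CTG (NORM), baseline fetal heart rate and variability (BFHR),
#' decelerations (DECEL), maternal heart rate recording (MHR), uncommon
#' CTG patterns (UNCOM) and the governing clinical guideline (RANZ).
#'
#' @format Character vector of length 8.
#' @export
fsep_clusters <- c("PHYS", "UPFH", "NORM", "BFHR", "DECEL", "MHR",
                   "UNCOM", "RANZ")

#' Construct an item bank
#'
#' An item bank holds one row per item: a unique id, its subject cluster,
#' the numeric option code of the correct answer, an optional calibrated
#' difficulty in logits, and the maximum attainable score (1 for
#' dichotomous multiple-choice items).
#'
#' @param items data frame with columns `item_id`, `subject_cluster`,
#'   `answer_key`, and optionally `difficulty` (logits) and `max_score`.
#' @param calibration_constraint `"mean_zero"` (difficulties identified by
#'   a mean-zero constraint) or `"anchored"` (difficulties fixed from a
#'   previous calibration and reused as-is).
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, calibration_constraint = c("mean_zero", "anchored")) {
  calibration_constraint <- match.arg(calibration_constraint)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("item_id", "subject_cluster", "answer_key")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("item bank is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  items$item_id <- as.character(items$item_id)
  items$subject_cluster <- as.character(items$subject_cluster)
  dup <- unique(items$item_id[duplicated(items$item_id)])
  if (length(dup) > 0L) {
    stop("duplicate item_id in bank: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(items$subject_cluster)) || anyNA(items$subject_cluster)) {
    stop("subject_cluster must be non-empty for every item", call. = FALSE)
  }
  if (is.null(items$max_score)) items$max_score <- 1L
  items$max_score <- as.integer(items$max_score)
  if (any(items$max_score < 1L)) {
    stop("max_score must be >= 1 for every item", call. = FALSE)
  }
  if (is.null(items$difficulty)) items$difficulty <- NA_real_
  items$difficulty <- as.numeric(items$difficulty)
  bank <- structure(
    list(items = items[, c("item_id", "subject_cluster", "answer_key",
                           "difficulty", "max_score")],
         calibration_constraint = calibration_constraint),
    class = "item_bank")
  validate_item_bank(bank)
  bank
}

validate_item_bank <- function(bank) {
  d <- bank$items$difficulty
  if (bank$calibration_constraint == "mean_zero" && !anyNA(d) &&
      length(d) > 0L && abs(mean(d)) > 1e-8) {
    stop("mean_zero bank has difficulties with mean ", mean(d),
         " (expected 0 within 1e-8)", call. = FALSE)
  }
  invisible(bank)
}

#' @export
print.item_bank <- function(x, ...) {
  n <- nrow(x$items)
  cal <- if (anyNA(x$items$difficulty)) "uncalibrated" else "calibrated"
  cat(sprintf("<item_bank> %d items, %d clusters, %s (%s)\n",
              n, length(unique(x$items$subject_cluster)), cal,
              x$calibration_constraint))
  invisible(x)
}

#' Read an item bank from CSV or JSON
#'
#' CSV banks have columns `item_id,subject_cluster,answer_key` plus
#' optional `difficulty` and `max_score`. JSON banks are an object with
#' an `items` array of records and an optional `calibration_constraint`
#' key. Unknown columns are dropped with a warning.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension by
#'   default.
#' @param calibration_constraint constraint for CSV banks (JSON banks may
#'   carry their own).
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path, format = c("auto", "csv", "json"),
                           calibration_constraint = "mean_zero") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$items, stringsAsFactors = FALSE)
    if (!is.null(obj$calibration_constraint)) {
      calibration_constraint <- obj$calibration_constraint
    }
  }
  known <- c("item_id", "subject_cluster", "answer_key", "difficulty",
             "max_score")
  extra <- setdiff(names(df), known)
  if (length(extra) > 0L) {
    warning("ignoring unknown item bank column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[, intersect(names(df), known), drop = FALSE]
  }
  item_bank(df, calibration_constraint = calibration_constraint)
}

#' Write an item bank to CSV
#'
#' @param bank an [item_bank()].
#' @param path output file path.
#' @param extra optional data frame of per-item columns (e.g. fit
#'   statistics) merged on `item_id` before writing.
#' @export
write_item_bank <- function(bank, path, extra = NULL) {
  df <- bank$items
  if (!is.null(extra)) {
    df <- merge(df, extra, by = "item_id", sort = FALSE)
    df <- df[match(bank$items$item_id, df$item_id), ]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw response table
#'
#' The CSV has a `candidate_id` column followed by one column per item id
#' containing the raw option code chosen (integer) or blank.
#'
#' @param path file path.
#' @return A data frame with class `raw_response_table`: `candidate_id`
#'   plus one integer column per item; blanks are `NA`.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"candidate_id" %in% names(df)) {
    stop("response table must have a candidate_id column", call. = FALSE)
  }
  df$candidate_id <- as.character(df$candidate_id)
  if (anyDuplicated(df$candidate_id)) {
    stop("duplicate candidate_id in response table", call. = FALSE)
  }
  for (col in setdiff(names(df), "candidate_id")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  class(df) <- c("raw_response_table", "data.frame")
  df
}

#' Construct a scored response matrix
#'
#' @param scores integer matrix, candidates in rows and items in columns,
#'   with dimnames giving candidate and item ids. `NA` marks a response
#'   flagged missing (excluded from facility denominators).
#' @param max_score integer vector of per-item maxima (recycled).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(scores, max_score = 1L) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores must carry candidate and item ids as dimnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(scores)) || anyDuplicated(colnames(scores))) {
    stop("candidate and item ids must be unique", call. = FALSE)
  }
  max_score <- rep_len(as.integer(max_score), ncol(scores))
  storage.mode(scores) <- "integer"
  bad <- which(!is.na(scores) &
                 (scores < 0L | scores > rep(max_score, each = nrow(scores))))
  if (length(bad) > 0L) {
    stop("scores outside [0, max_score] at ", length(bad), " cell(s)",
         call. = FALSE)
  }
  structure(list(scores = scores, max_score = max_score),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d candidates x %d items (%d missing cells)\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$scores)

#' Score raw option responses against an item bank
#'
#' A response scores 1 when the chosen option code equals the item's
#' answer key, otherwise 0. Blank (empty) responses are scored according
#' to `blank_policy`: `"incorrect"` treats an unanswered item as wrong
#' (the operational convention for a supervised exam), `"missing"` keeps
#' it as `NA` so it is excluded from facility denominators.
#'
#' @param raw a `raw_response_table` from [read_responses()], or a data
#'   frame with the same shape.
#' @param bank an [item_bank()].
#' @param blank_policy `"incorrect"` (default) or `"missing"`.
#' @param option_range permissible raw option codes; codes outside it
#'   raise a validation error listing the offending cells.
#' @return A [response_matrix()] of dichotomous scores.
#' @export
score_responses <- function(raw, bank, blank_policy = c("incorrect", "missing"),
                            option_range = 1:9) {
  blank_policy <- match.arg(blank_policy)
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  item_cols <- setdiff(names(raw), "candidate_id")
  unknown <- setdiff(item_cols, bank$items$item_id)
  if (length(unknown) > 0L) {
    stop("response column(s) not in bank: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keys <- bank$items$answer_key[match(item_cols, bank$items$item_id)]
  opt <- as.matrix(raw[, item_cols, drop = FALSE])
  storage.mode(opt) <- "integer"
  out_of_range <- which(!is.na(opt) & !(opt %in% option_range), arr.ind = TRUE)
  if (nrow(out_of_range) > 0L) {
    cells <- apply(out_of_range, 1L, function(ix) {
      sprintf("%s/%s=%d", raw$candidate_id[ix[1L]], item_cols[ix[2L]],
              opt[ix[1L], ix[2L]])
    })
    stop("raw option code outside declared range at: ",
         paste(utils::head(cells, 10L), collapse = ", "),
         if (length(cells) > 10L) " ..." else "", call. = FALSE)
  }
  scored <- (opt == rep(keys, each = nrow(opt))) * 1L
  if (blank_policy == "incorrect") {
    scored[is.na(opt)] <- 0L
  }
  dimnames(scored) <- list(raw$candidate_id, item_cols)
  response_matrix(scored,
                  max_score = bank$items$max_score[
                    match(item_cols, bank$items$item_id)])
}

#' Write a GIM layout to a JSON report
#'
#' The report is a versioned JSON document (`"gim_schema": 1`) carrying
#' every placed item, co-location group, reference line, quadrant and
#' subject flag; [read_gim_report()] restores it losslessly.
#'
#' @param layout a `gim_layout` from [build_gim()].
#' @param path output file path.
#' @export
write_gim_report <- function(layout, path) {
  stopifnot(inherits(layout, "gim_layout"))
  doc <- list(
    gim_schema = 1L,
    candidate_id = layout$candidate_id,
    ability_line = layout$ability_line,
    pass_line = layout$pass_line,
    columns = as.list(layout$columns),
    placed = layout$placed,
    groups = lapply(seq_len(nrow(layout$groups)), function(i) {
      g <- layout$groups[i, ]
      list(subject_cluster = g$subject_cluster, side = g$side,
           member_ids = layout$group_members[[i]], count = g$count,
           y = g$y, label = g$label)
    }),
    flags = as.list(layout$flags)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::write_json(doc, con, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a GIM layout back from a JSON report
#'
#' @param path path to a report written by [write_gim_report()].
#' @return A `gim_layout` structurally identical to the one written.
#' @export
read_gim_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$gim_schema) || doc$gim_schema != 1L) {
    stop("not a gim_schema 1 report: ", path, call. = FALSE)
  }
  placed <- do.call(rbind, lapply(doc$placed, function(p) {
    data.frame(item_id = p$item_id, subject_cluster = p$subject_cluster,
               side = p$side, y = p$y,
               quadrant = if (is.null(p$quadrant)) NA_character_ else p$quadrant,
               stringsAsFactors = FALSE)
  }))
  groups <- do.call(rbind, lapply(doc$groups, function(g) {
    data.frame(subject_cluster = g$subject_cluster, side = g$side,
               count = as.integer(g$count), y = g$y, label = g$label,
               stringsAsFactors = FALSE)
  }))
  members <- lapply(doc$groups, function(g) {
    vapply(g$member_ids, identity, character(1L), USE.NAMES = FALSE)
  })
  flags <- vapply(doc$flags, identity, character(1L))
  new_gim_layout(
    candidate_id = doc$candidate_id,
    ability_line = doc$ability_line,
    pass_line = if (is.null(doc$pass_line)) NULL else doc$pass_line,
    columns = vapply(doc$columns, identity, character(1L)),
    placed = placed, groups = groups, group_members = members,
    flags = flags)
}
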
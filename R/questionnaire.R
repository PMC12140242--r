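#' The BDI-II severity bands
#'
#' Two banding conventions of the overall score exist in the literature. The
#' `"standard"` mapping (the one used throughout this package's evaluation,
#' and the one that defines the category-level squared error) is
#' Minimal 0-13, Mild 14-19, Moderate 20-28, Severe >= 29. The
#' `"screening"` alternative (Minimal 0-9, Mild 10-18, Moderate 19-29,
#' Severe 30-63) is exposed for completeness.
#' @keywords internal
severity_breaks <- function(scheme = c("standard", "screening")) {
  scheme <- match.arg(scheme)
  if (scheme == "standard") c(-1, 13, 19, 28, 63) else c(-1, 9, 18, 29, 63)
}

#' Severity category labels, in order of code 0..3
#' @export
severity_labels <- function() c("Minimal", "Mild", "Moderate", "Severe")

#' Load and validate a questionnaire definition
#'
#' Reads a JSON questionnaire file: a document with fields `name` and
#' `items`, each item carrying `item_id`, `name`, `description` and exactly
#' four `choices` (`score` in 0-3, `text`). The bundled BDI-II instrument is
#' at `system.file("extdata", "bdi2.json", package = "ensembert")`.
#'
#' @param path path to the questionnaire JSON file.
#' @return an object of class `questionnaire`: a list with `name` and
#'   `items` (a list of 21 validated items).
#' @export
load_questionnaire <- function(path) {
  if (!file.exists(path)) stop("questionnaire file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) stop("malformed questionnaire file: ", conditionMessage(e))
  )
  if (is.null(doc$items) || !length(doc$items)) {
    stop("malformed questionnaire file: no items")
  }
  items <- lapply(doc$items, validate_item)
  ids <- vapply(items, function(i) i$item_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate item_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  items <- items[order(ids)]
  ids <- sort(ids)
  if (!identical(ids, seq_along(ids))) {
    stop("item_ids must be 1..", length(ids), " without gaps")
  }
  structure(
    list(name = doc$name %||% "questionnaire", items = items),
    class = "questionnaire"
  )
}

validate_item <- function(item) {
  id <- item$item_id
  if (is.null(id) || !is.numeric(id)) stop("item without a numeric item_id")
  id <- as.integer(id)
  label <- item$name %||% paste0("item ", id)
  if (is.null(item$description) || !nzchar(trimws(item$description))) {
    stop("item ", id, " (", label, "): empty description")
  }
  ch <- item$choices
  if (length(ch) != 4L) {
    stop("item ", id, " (", label, "): expected 4 choices, got ", length(ch))
  }
  scores <- vapply(ch, function(c) as.integer(c$score), integer(1))
  if (!setequal(scores, 0:3) || anyDuplicated(scores)) {
    stop("item ", id, " (", label, "): choice scores must be exactly {0,1,2,3}")
  }
  texts <- vapply(ch, function(c) as.character(c$text), character(1))
  if (any(!nzchar(trimws(texts)))) {
    stop("item ", id, " (", label, "): empty choice text")
  }
  ch <- ch[order(scores)]
  list(
    item_id = id,
    name = label,
    description = item$description,
    choices = lapply(ch, function(c) list(score = as.integer(c$score), text = c$text))
  )
}

#' Bundled BDI-II questionnaire
#'
#' Convenience loader for the instrument file shipped with the package
#' (21 items, enriched descriptions, choice texts paraphrasing the standard
#' response options).
#' @return a `questionnaire` object with 21 items.
#' @export
bdi2 <- function() {
  load_questionnaire(system.file("extdata", "bdi2.json", package = "ensembert"))
}

#' @export
print.questionnaire <- function(x, ...) {
  cat("<questionnaire> ", x$name, ": ", length(x$items), " items\n", sep = "")
  invisible(x)
}

#' Overall questionnaire score from per-item scores
#'
#' The overall BDI-II score is the plain sum of the 21 item scores and lies
#' in 0-63.
#'
#' @param item_scores integer vector of length 21, entries in 0-3.
#' @param n_items expected number of items (default 21).
#' @return integer overall score.
#' @export
overall_from_items <- function(item_scores, n_items = 21L) {
  if (length(item_scores) != n_items) {
    stop("expected ", n_items, " item scores, got ", length(item_scores))
  }
  if (anyNA(item_scores) || !all(item_scores %in% 0:3)) {
    stop("item scores must all be in {0,1,2,3}")
  }
  as.integer(sum(item_scores))
}

#' Map an overall score to a depression severity category
#'
#' Uses the standard bands: 0-13 Minimal (0), 14-19 Mild (1),
#' 20-28 Moderate (2), >= 29 Severe (3). Vectorized.
#'
#' @param y integer overall score(s) in 0-63.
#' @param scheme `"standard"` (default) or the `"screening"` alternative
#'   banding (0-9/10-18/19-29/30-63).
#' @return integer category code(s) 0-3, with the label as a `"label"`
#'   attribute when `y` is scalar.
#' @export
categorize_overall <- function(y, scheme = c("standard", "screening")) {
  scheme <- match.arg(scheme)
  if (anyNA(y) || any(y < 0 | y > 63) || any(y != floor(y))) {
    stop("overall score must be an integer in [0, 63]")
  }
  code <- as.integer(cut(y, breaks = severity_breaks(scheme), labels = FALSE)) - 1L
  if (length(code) == 1L) attr(code, "label") <- severity_labels()[code + 1L]
  code
}
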
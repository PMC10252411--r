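#' Ordinal agreement between two dryness rating columns
#'
#' Counts samples whose candidate rating differs from the reference rating
#' (strict label inequality, no partial credit) and breaks the mismatches
#' down by ordinal distance on the dry (0) to sweet (3) scale — so a
#' "sweet vs dry" disagreement contributes at distance 3, "one level off"
#' at distance 1.
#'
#' @param reference reference ratings (labels, levels or ordered factor).
#' @param candidate candidate ratings.
#' @param ids sample identifiers; defaults to the names of `reference` or
#'   row positions. Both columns must cover the same id set.
#' @return list of class `"mismatch_report"`: `n_compared`, `n_mismatch`,
#'   `by_distance` (named counts at distances 1..3), `mismatched_ids`,
#'   `n_multi_level` (mismatches at distance 2 or more).
#' @examples
#' t7 <- load_fixture("table7")
#' compare_ratings(t7$sensory_rating, t7$nyca_rating, ids = t7$sample_id)
#' @export
compare_ratings <- function(reference, candidate, ids = NULL) {
  if (is.null(ids)) ids <- names(reference)
  if (is.null(ids)) ids <- as.character(seq_along(reference))
  cand_ids <- names(candidate)
  if (!is.null(cand_ids)) {
    extra <- setdiff(cand_ids, ids)
    missing <- setdiff(ids, cand_ids)
    if (length(extra) || length(missing))
      stop("rating columns cover different samples; only in candidate: [",
           paste(extra, collapse = ", "), "], only in reference: [",
           paste(missing, collapse = ", "), "]", call. = FALSE)
    candidate <- candidate[match(ids, cand_ids)]
  }
  if (length(candidate) != length(reference))
    stop("rating columns have different lengths", call. = FALSE)
  rl <- dryness_level(reference)
  cl <- dryness_level(candidate)
  if (anyNA(rl) || anyNA(cl)) stop("missing ratings", call. = FALSE)
  d <- abs(rl - cl)
  by_distance <- vapply(1:3, function(k) sum(d == k), integer(1))
  names(by_distance) <- 1:3
  out <- list(
    n_compared = length(d),
    n_mismatch = sum(d > 0),
    by_distance = by_distance,
    n_multi_level = sum(d >= 2),
    mismatched_ids = ids[d > 0]
  )
  class(out) <- "mismatch_report"
  out
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf("%d of %d ratings differ (distance 1/2/3: %d/%d/%d)\n",
              x$n_mismatch, x$n_compared,
              x$by_distance[["1"]], x$by_distance[["2"]], x$by_distance[["3"]]))
  if (x$n_mismatch)
    cat("  mismatched:", paste(x$mismatched_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Rank dryness scales and models against panel-evaluated dryness
#'
#' For a validation rating table (one reference sensory column plus one
#' column per candidate scale or model) computes a [compare_ratings()]
#' report per candidate and a summary ranked by mismatch count — the
#' comparison used to argue that multivariate calibration beats the
#' rule-based marketable scales.
#'
#' @param records data frame with `sample_id`, a `sensory_rating` column and
#'   one or more candidate rating columns (by default every other column
#'   ending in `_rating`).
#' @param reference name of the reference column.
#' @param candidates names of candidate columns.
#' @return list of class `"rating_comparison"`: `reports` (named
#'   `mismatch_report` list) and `summary` (data frame ranked by
#'   `n_mismatch`).
#' @examples
#' comparison_table(load_fixture("table7"))$summary
#' @export
comparison_table <- function(records, reference = "sensory_rating",
                             candidates = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            reference %in% names(records))
  if (is.null(candidates))
    candidates <- setdiff(grep("_rating$", names(records), value = TRUE),
                          reference)
  if (!length(candidates)) stop("no candidate rating columns", call. = FALSE)
  ids <- if ("sample_id" %in% names(records)) records$sample_id
         else as.character(seq_len(nrow(records)))
  reports <- lapply(candidates, function(cl)
    compare_ratings(records[[reference]], records[[cl]], ids = ids))
  names(reports) <- candidates
  summary <- data.frame(
    candidate = candidates,
    n_compared = vapply(reports, `[[`, integer(1), "n_compared"),
    n_mismatch = vapply(reports, `[[`, integer(1), "n_mismatch"),
    n_multi_level = vapply(reports, `[[`, integer(1), "n_multi_level"),
    row.names = NULL
  )
  summary <- summary[order(summary$n_mismatch), ]
  rownames(summary) <- NULL
  structure(list(reports = reports, summary = summary),
            class = "rating_comparison")
}

#' @export
print.rating_comparison <- function(x, ...) {
  cat("Rating agreement vs reference (best first):\n")
  print(x$summary)
  invisible(x)
}
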
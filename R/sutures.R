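# Fractional suture-fusion scoring.
#
# Each cranial suture is assessed visually in a fixed number of parts
# (coronal sutures in 3, lambdoid and sagittal in 5, posterior frontal in
# 2); a skull's score for a suture is the number of parts that are fused.
# A widely open suture with a gap defect is flagged separately and counts
# on the negative axis of the "animals affected" summary.

#' The part-count scheme of the scoring protocol
#'
#' @param frontonasal,accessory_occipital part counts for the two sutures
#'   the core scheme leaves open (package default 3, configurable).
#' @return Named integer vector: parts per suture.
#' @export
suture_scheme <- function(frontonasal = 3L, accessory_occipital = 3L) {
  c(coronal_left = 3L, coronal_right = 3L,
    lambdoid_left = 5L, lambdoid_right = 5L,
    sagittal = 5L, posterior_frontal = 2L,
    frontonasal = as.integer(frontonasal),
    accessory_occipital = as.integer(accessory_occipital))
}

#' Validate a suture score sheet
#'
#' A score sheet is a data frame with columns `skull_id`, `suture`,
#' `parts_fused`, `open_gap` and optionally `group`, `parts_total` and
#' `note`. Missing `parts_total` is filled from the scheme; present values
#' must match it. `0 <= parts_fused <= parts_total`, and a fully fused
#' suture cannot simultaneously carry the open-gap flag.
#'
#' @param scores score sheet data frame.
#' @param scheme part-count scheme, see [suture_scheme()].
#' @return The validated sheet (with `parts_total` filled in).
#' @export
validate_scores <- function(scores, scheme = suture_scheme()) {
  need <- c("skull_id", "suture", "parts_fused")
  if (!all(need %in% names(scores)))
    stop("score sheet must have columns ", paste(need, collapse = ", "))
  if (is.null(scores$open_gap)) scores$open_gap <- FALSE
  scores$open_gap <- as.logical(scores$open_gap)
  unknown <- setdiff(unique(scores$suture), names(scheme))
  if (length(unknown))
    stop("sutures not in the scheme: ", paste(unknown, collapse = ", "))
  expected <- unname(scheme[scores$suture])
  if (is.null(scores$parts_total)) {
    scores$parts_total <- expected
  } else if (any(scores$parts_total != expected)) {
    stop("parts_total inconsistent with the scoring scheme")
  }
  if (any(scores$parts_fused < 0 | scores$parts_fused > scores$parts_total))
    stop("parts_fused must lie in [0, parts_total]")
  if (any(scores$open_gap & scores$parts_fused == scores$parts_total))
    stop("a fully fused suture cannot be flagged as widely open")
  scores
}

#' Fused fraction of a suture score
#'
#' `parts_fused / parts_total`: the fraction of the suture length that is
#' prematurely ossified (the sagittal, for example, can be fused for 0-5
#' fifths of its length).
#'
#' @param scores a validated score sheet (or any data frame with
#'   `parts_fused` and `parts_total`).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
fused_fraction <- function(scores) {
  scores$parts_fused / scores$parts_total
}

#' Group-level suture-fusion summary
#'
#' For each suture: `pct_length_fused` is the mean fused fraction over the
#' group's animals times 100 (equivalently, total fused parts over total
#' parts); `pct_animals_affected` is signed, the share of animals with any
#' premature fusion (positive) minus the share with an open-gap defect
#' (negative). Internal arithmetic is exact on the integer part counts;
#' percentages are returned unrounded (report to one decimal).
#'
#' @param scores score sheet for one group; at most one record per animal
#'   and suture.
#' @param group group label attached to the output.
#' @param scheme part-count scheme.
#' @return Data frame `group, suture, n_animals, pct_length_fused,
#'   pct_animals_closed, pct_animals_open, pct_animals_affected`.
#' @export
summarize_sutures <- function(scores, group = "group",
                              scheme = suture_scheme()) {
  scores <- validate_scores(scores, scheme)
  if (nrow(scores) == 0) stop("empty score sheet")
  key <- paste(scores$skull_id, scores$suture)
  if (anyDuplicated(key)) {
    dup <- scores[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    agree <- all(tapply(paste(dup$parts_fused, dup$open_gap),
                        paste(dup$skull_id, dup$suture),
                        function(v) length(unique(v)) == 1))
    if (!agree) stop("conflicting duplicate scores for the same skull/suture")
    scores <- scores[!duplicated(key), ]
  }
  out <- lapply(split(scores, scores$suture), function(d) {
    n <- nrow(d)
    pt <- d$parts_total[1]
    data.frame(
      group = group,
      suture = d$suture[1],
      n_animals = n,
      pct_length_fused = 100 * sum(d$parts_fused) / (n * pt),
      pct_animals_closed = 100 * sum(d$parts_fused > 0) / n,
      pct_animals_open = 100 * sum(d$open_gap) / n,
      pct_animals_affected = 100 * (sum(d$parts_fused > 0) - sum(d$open_gap)) / n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$suture, names(scheme))), , drop = FALSE]
}

#' Compare the score sheets of two evaluators
#'
#' Scoring is performed genotype-blind by two evaluators; this tabulates
#' every record on which they disagree. Row order is irrelevant; the two
#' sheets must cover exactly the same skull/suture records.
#'
#' @param scores_a,scores_b score sheets with identical coverage.
#' @param scheme part-count scheme.
#' @return Data frame of discrepancies (`skull_id, suture, parts_fused_a,
#'   parts_fused_b, open_gap_a, open_gap_b, delta_parts`); zero rows means
#'   full concordance.
#' @export
compare_evaluators <- function(scores_a, scores_b, scheme = suture_scheme()) {
  a <- validate_scores(scores_a, scheme)
  b <- validate_scores(scores_b, scheme)
  ka <- paste(a$skull_id, a$suture); kb <- paste(b$skull_id, b$suture)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate skull/suture records within a sheet")
  if (!setequal(ka, kb)) stop("coverage mismatch between the two sheets")
  m <- merge(a[, c("skull_id", "suture", "parts_fused", "open_gap")],
             b[, c("skull_id", "suture", "parts_fused", "open_gap")],
             by = c("skull_id", "suture"), suffixes = c("_a", "_b"))
  m$delta_parts <- m$parts_fused_a - m$parts_fused_b
  m[m$delta_parts != 0 | m$open_gap_a != m$open_gap_b, , drop = FALSE]
}

#' Read/write suture score sheets
#' @param scores a score sheet data frame; `path` a CSV file.
#' @return `read_score_sheet` returns a validated data frame.
#' @export
write_score_sheet <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_sheet
#' @param path CSV file.
#' @param scheme part-count scheme used for validation.
#' @export
read_score_sheet <- function(path, scheme = suture_scheme()) {
  validate_scores(utils::read.csv(path), scheme)
}
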
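#' Default TAS-20 scoring key
#'
#' The standard published structure of the 20-item Toronto Alexithymia Scale:
#' items 4, 5, 10, 18 and 19 are reverse-keyed (response x scores 6 - x), and
#' the three subscales partition the items into Difficulty Identifying
#' Feelings (DIF, 7 items), Difficulty Describing Feelings (DDF, 5 items) and
#' Externally Oriented Thinking (EOT, 8 items).
#'
#' @return A list with integer vectors `dif`, `ddf`, `eot` (item indices) and
#'   `reverse` (indices of reverse-keyed items).
#' @export
tas_key <- function() {
  list(
    dif = c(1L, 3L, 6L, 7L, 9L, 13L, 14L),
    ddf = c(2L, 4L, 11L, 12L, 17L),
    eot = c(5L, 8L, 10L, 15L, 16L, 18L, 19L, 20L),
    reverse = c(4L, 5L, 10L, 18L, 19L)
  )
}

check_key <- function(key) {
  idx <- sort(c(key$dif, key$ddf, key$eot))
  if (!identical(idx, 1:20)) {
    stop("TAS key must partition items 1..20 into DIF/DDF/EOT", call. = FALSE)
  }
  if (length(key$reverse) && any(!key$reverse %in% 1:20)) {
    stop("reverse-keyed indices must lie in 1..20", call. = FALSE)
  }
  key
}

#' Reverse-key Likert responses
#'
#' Maps a response x on a 1..max scale to (max + 1) - x. Applying the map
#' twice restores the original responses.
#'
#' @param x integer responses.
#' @param scale_max maximum scale option (5 for the TAS-20).
#' @return reversed responses.
#' @export
reverse_items <- function(x, scale_max = 5L) {
  (scale_max + 1L) - x
}

check_item_range <- function(items, n, lo, hi, what) {
  if (length(items) != n) {
    stop(sprintf("%s: expected %d items, got %d", what, n, length(items)),
         call. = FALSE)
  }
  bad <- which(is.na(items) | items < lo | items > hi | items != round(items))
  if (length(bad)) {
    stop(sprintf("%s: item %d out of range [%d, %d] (value: %s)",
                 what, bad[1], lo, hi, as.character(items[bad[1]])),
         call. = FALSE)
  }
  as.integer(items)
}

#' Score the TAS-20
#'
#' Reverse-keyed items are inverted (x -> 6 - x) before summation; each
#' subscale sums its assigned items and the total sums all 20 keyed items.
#'
#' @param items integer vector of 20 responses in 1..5.
#' @param key scoring key as produced by [tas_key()].
#' @return A `tas_scores` list with `total` (20-100), `dif` (7-35),
#'   `ddf` (5-25) and `eot` (8-40).
#' @examples
#' score_tas(rep(3, 20))  # total 60: 3 is the reversal fixed point
#' @export
score_tas <- function(items, key = tas_key()) {
  key <- check_key(key)
  items <- check_item_range(items, 20L, 1L, 5L, "TAS-20")
  keyed <- items
  keyed[key$reverse] <- reverse_items(items[key$reverse], 5L)
  out <- list(
    total = sum(keyed),
    dif = sum(keyed[key$dif]),
    ddf = sum(keyed[key$ddf]),
    eot = sum(keyed[key$eot])
  )
  structure(out, class = "tas_scores")
}

#' @export
print.tas_scores <- function(x, ...) {
  cat(sprintf("TAS-20: total %d (DIF %d, DDF %d, EOT %d)\n",
              x$total, x$dif, x$ddf, x$eot))
  invisible(x)
}

#' Score the 5-item attentional-impulsiveness scale
#'
#' Keyed sum of five 1..4 responses, range 5-20. The instrument's published
#' key is not assumed; pass `reverse` if any administered items are
#' reverse-keyed.
#'
#' @param items integer vector of 5 responses in 1..4.
#' @param reverse indices (1..5) of reverse-keyed items; default none.
#' @return integer total in 5..20.
#' @export
score_ai <- function(items, reverse = integer(0)) {
  items <- check_item_range(items, 5L, 1L, 4L, "AI")
  if (length(reverse)) items[reverse] <- reverse_items(items[reverse], 4L)
  sum(items)
}

#' Score the Cognitive Reflection Test
#'
#' @param answers logical (or 0/1) vector of length 3; TRUE = correct.
#' @return integer count of correct answers, 0..3.
#' @export
score_crt <- function(answers) {
  if (length(answers) != 3L) {
    stop("CRT: expected 3 answers, got ", length(answers), call. = FALSE)
  }
  a <- as.logical(answers)
  if (any(is.na(a))) stop("CRT: answers must be TRUE/FALSE or 0/1", call. = FALSE)
  sum(a)
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of totals), with
#' sample variances (denominator n-1). For dichotomous 0/1 items this equals
#' KR-20. alpha is at most 1 but can be negative for degenerate data.
#'
#' @param item_matrix numeric matrix or data frame, respondents x items.
#' @return A `reliability_result` list with `alpha`, `n_items`,
#'   `n_respondents`.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L) stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  if (nrow(m) < 2L) stop("Cronbach's alpha needs at least 2 respondents", call. = FALSE)
  if (anyNA(m)) stop("Cronbach's alpha: missing responses not supported", call. = FALSE)
  totals <- rowSums(m)
  vt <- stats::var(totals)
  if (vt <= 0) stop("Cronbach's alpha undefined: zero total-score variance", call. = FALSE)
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
  structure(list(alpha = alpha, n_items = k, n_respondents = nrow(m)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d respondents)\n",
              x$alpha, x$n_items, x$n_respondents))
  invisible(x)
}

#' Apply the attention-check exclusion
#'
#' A participant passes only if the attention response equals the maximum
#' scale option (the instructed answer, "very much"). Records failing the
#' check, or whose id is listed in `manual_exclusions`, are removed; every
#' removal is logged with its reason.
#'
#' @param cohort cohort data frame with columns `pid` and `attn`.
#' @param manual_exclusions character vector of participant ids to drop
#'   regardless of the check (e.g. instruction misunderstandings).
#' @param scale_max maximum attention-scale option (default 5).
#' @return list with `cohort` (retained rows) and `log` (data frame
#'   `pid`, `reason`).
#' @export
filter_attention <- function(cohort, manual_exclusions = character(0),
                             scale_max = 5L) {
  stopifnot(is.data.frame(cohort), all(c("pid", "attn") %in% names(cohort)))
  manual <- cohort$pid %in% manual_exclusions
  failed <- !manual & (is.na(cohort$attn) | cohort$attn != scale_max)
  log <- data.frame(
    pid = c(cohort$pid[manual], cohort$pid[failed]),
    reason = c(rep("manual_exclusion", sum(manual)),
               rep("attention_check_failed", sum(failed))),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort[!(manual | failed), , drop = FALSE], log = log)
}

#' Assign alexithymia group from a TAS total
#'
#' Strict cutoffs: high if total > `threshold_high` (default 60), low if
#' total < `threshold_low` (default 52), otherwise unclassified (totals of
#' 52..60 inclusive fall in neither group).
#'
#' @param total TAS-20 total score(s), or a `tas_scores` object.
#' @param threshold_high,threshold_low group cutoffs in TAS points.
#' @return factor with levels `low`, `unclassified`, `high`.
#' @export
assign_group <- function(total, threshold_high = 60, threshold_low = 52) {
  if (inherits(total, "tas_scores")) total <- total$total
  if (threshold_low > threshold_high) {
    stop("threshold_low must not exceed threshold_high", call. = FALSE)
  }
  lab <- ifelse(total > threshold_high, "high",
                ifelse(total < threshold_low, "low", "unclassified"))
  factor(lab, levels = c("low", "unclassified", "high"))
}
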
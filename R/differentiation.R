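#' Differentiation score of a single picture
#'
#' For k ratings of one stimulus on k scales, the score is
#' (highest rating - mean of the other k-1 ratings) / mean of all k ratings.
#' Dividing the distance by the mean intensity makes the score invariant to
#' rescaling the ratings: 100 vs 80 separates less than 40 vs 20, although
#' both differ by 20 points. When the maximum is tied, the highest rating is
#' the maximum value and the "lower" set is the remaining k-1 entries, so an
#' all-equal picture scores exactly 0. A picture rated 0 on every scale has
#' no defined score (0/0) and returns NA.
#'
#' @param ratings numeric vector of k >= 2 non-negative ratings.
#' @return score in \[0, k\], or NA when all ratings are zero.
#' @examples
#' picture_differentiation(c(100, 80))     # 0.2222
#' picture_differentiation(c(40, 20))      # 0.6667 -- sharper
#' picture_differentiation(c(90, 30, 30, 30))  # 1.3333
#' @export
picture_differentiation <- function(ratings) {
  if (length(ratings) < 2L) {
    stop("picture_differentiation needs at least 2 ratings", call. = FALSE)
  }
  if (anyNA(ratings)) {
    stop("picture ratings must be complete; drop incomplete pictures upstream",
         call. = FALSE)
  }
  if (any(ratings < 0)) stop("ratings must be non-negative", call. = FALSE)
  m <- mean(ratings)
  if (m == 0) return(NA_real_)
  top <- which.max(ratings)
  (ratings[top] - mean(ratings[-top])) / m
}

#' Differentiation index over a ratings block
#'
#' The index is the arithmetic mean of the per-picture differentiation scores
#' over pictures where the score is defined; all-zero pictures are excluded
#' from the mean (not scored 0) and counted via `n_defined`. If no picture is
#' defined the index is NA.
#'
#' @param block numeric matrix, pictures in rows and rating scales in columns
#'   (a `ratings_block`), or anything coercible to such a matrix.
#' @return A `differentiation_result` list with `per_picture` (scores, NA for
#'   undefined pictures), `index` and `n_defined`.
#' @export
differentiation_index <- function(block) {
  m <- as.matrix(block)
  if (nrow(m) < 1L || ncol(m) < 2L) {
    stop("ratings block must have >= 1 picture and >= 2 scales", call. = FALSE)
  }
  per <- apply(m, 1, picture_differentiation)
  defined <- !is.na(per)
  structure(list(
    per_picture = per,
    index = if (any(defined)) mean(per[defined]) else NA_real_,
    n_defined = sum(defined)
  ), class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("differentiation index %.4f over %d defined picture(s)\n",
              x$index, x$n_defined))
  invisible(x)
}

#' Differentiation indices for a whole cohort
#'
#' Extracts each participant's pictures x scales ratings block from the wide
#' cohort table and computes the differentiation index.
#'
#' @param cohort cohort data frame in the wide CSV layout (see
#'   [write_cohort()]).
#' @return data frame `pid`, `diff_index`, `n_defined`.
#' @export
cohort_differentiation <- function(cohort) {
  cols <- grep("^rating_p[0-9]+_s[0-9]+$", names(cohort), value = TRUE)
  if (!length(cols)) stop("cohort has no rating_* columns", call. = FALSE)
  pics <- unique(sub("^rating_(p[0-9]+)_s[0-9]+$", "\\1", cols))
  scales <- unique(sub("^rating_p[0-9]+_(s[0-9]+)$", "\\1", cols))
  k <- length(scales)
  if (k < 2L) stop("ratings block must have >= 2 scales", call. = FALSE)
  n <- nrow(cohort)
  # per-picture scores, vectorised over participants
  per <- matrix(NA_real_, n, length(pics))
  for (j in seq_along(pics)) {
    m <- as.matrix(cohort[paste0("rating_", pics[j], "_", scales)])
    if (anyNA(m)) stop("rating columns contain missing values", call. = FALSE)
    if (any(m < 0)) stop("ratings must be non-negative", call. = FALSE)
    tot <- rowSums(m)
    top <- do.call(pmax, as.data.frame(m))
    ok <- tot > 0
    per[ok, j] <- (top[ok] - (tot[ok] - top[ok]) / (k - 1)) / (tot[ok] / k)
  }
  n_def <- rowSums(!is.na(per))
  idx <- ifelse(n_def > 0, rowMeans(per, na.rm = TRUE), NA_real_)
  data.frame(pid = cohort$pid, diff_index = idx, n_defined = n_def,
             stringsAsFactors = FALSE)
}
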
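#' Score every questionnaire in a cohort table
#'
#' Vectorised TAS-20 scoring over the wide cohort layout; AI and CRT totals
#' are added when their item columns are present.
#'
#' @param cohort cohort data frame.
#' @param key TAS scoring key, see [tas_key()].
#' @param ai_reverse reverse-keyed AI item indices (default none).
#' @return data frame `pid`, `tas_total`, `dif`, `ddf`, `eot`, and
#'   optionally `ai_total`, `crt_total`.
#' @export
score_cohort_tas <- function(cohort, key = tas_key(), ai_reverse = integer(0)) {
  key <- check_key(key)
  tas_cols <- paste0("tas_", 1:20)
  if (!all(tas_cols %in% names(cohort))) {
    stop("cohort is missing TAS item columns", call. = FALSE)
  }
  m <- as.matrix(cohort[tas_cols])
  if (anyNA(m) || any(m < 1 | m > 5)) {
    stop("TAS items must be complete and in 1..5", call. = FALSE)
  }
  m[, key$reverse] <- 6 - m[, key$reverse]
  out <- data.frame(pid = cohort$pid,
                    tas_total = rowSums(m),
                    dif = rowSums(m[, key$dif, drop = FALSE]),
                    ddf = rowSums(m[, key$ddf, drop = FALSE]),
                    eot = rowSums(m[, key$eot, drop = FALSE]),
                    stringsAsFactors = FALSE)
  ai_cols <- paste0("ai_", 1:5)
  if (all(ai_cols %in% names(cohort))) {
    a <- as.matrix(cohort[ai_cols])
    if (length(ai_reverse)) a[, ai_reverse] <- 5 - a[, ai_reverse]
    out$ai_total <- rowSums(a)
  }
  crt_cols <- paste0("crt_", 1:3)
  if (all(crt_cols %in% names(cohort))) {
    out$crt_total <- rowSums(as.matrix(cohort[crt_cols]))
  }
  out
}

#' Write a cohort (and its generating truth) to CSV
#'
#' One row per participant in the documented wide layout. When `truth` is
#' supplied, a `<stem>_truth.csv` sidecar with the per-participant latent
#' values and a `<stem>_config.csv` key-value echo of the generating
#' parameters are written next to the cohort file.
#'
#' @param cohort cohort data frame (or the list returned by
#'   [generate_cohort()], in which case `truth` is taken from it).
#' @param path output CSV path.
#' @param truth optional truth list from [generate_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth = NULL) {
  if (is.list(cohort) && !is.data.frame(cohort) &&
      all(c("cohort", "truth") %in% names(cohort))) {
    truth <- cohort$truth
    cohort <- cohort$cohort
  }
  utils::write.csv(cohort, path, row.names = FALSE)
  if (!is.null(truth)) {
    stem <- sub("\\.csv$", "", path)
    utils::write.csv(truth$participants, paste0(stem, "_truth.csv"),
                     row.names = FALSE)
    cfg <- truth$config
    utils::write.csv(
      data.frame(key = names(cfg),
                 value = vapply(cfg, function(v) paste(v, collapse = ";"),
                                character(1))),
      paste0(stem, "_config.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Checks the documented header dialect (mandatory `pid`, `condition`,
#' `tas_1..tas_20`, `attn`, and `rating_<pic>_<scale>` columns) and value
#' ranges; malformed values are rejected with their row number.
#'
#' @param path CSV path.
#' @param rating_scale_max top of the rating scale (default 100).
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path, rating_scale_max = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("pid", "condition", paste0("tas_", 1:20), "attn")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rating_cols <- grep("^rating_p[0-9]+_s[0-9]+$", names(df), value = TRUE)
  if (!length(rating_cols)) {
    stop("cohort file has no rating_<pic>_<scale> columns", call. = FALSE)
  }
  check_range <- function(cols, lo, hi, what) {
    for (cc in cols) {
      v <- df[[cc]]
      bad <- which(is.na(v) | v < lo | v > hi)
      if (length(bad)) {
        stop(sprintf("column %s: value %s out of range [%g, %g] at row %d",
                     cc, as.character(v[bad[1]]), lo, hi, bad[1]),
             call. = FALSE)
      }
    }
  }
  check_range(paste0("tas_", 1:20), 1, 5, "tas")
  check_range("attn", 1, 5, "attn")
  check_range(rating_cols, 0, rating_scale_max, "rating")
  if (all(paste0("ai_", 1:5) %in% names(df))) {
    check_range(paste0("ai_", 1:5), 1, 4, "ai")
  }
  if (all(paste0("crt_", 1:3) %in% names(df))) {
    check_range(paste0("crt_", 1:3), 0, 1, "crt")
  }
  if (anyDuplicated(df$pid)) stop("duplicate participant ids", call. = FALSE)
  df
}

#' Study analysis configuration
#'
#' @param study_design `"two_group"` (emotion- vs evaluation-wording
#'   conditions analysed separately, Study-1 style) or `"single_group"`
#'   (one condition, with a bootstrapped regression when AI and CRT are
#'   available, Study-2 style).
#' @param threshold_high,threshold_low alexithymia group cutoffs (TAS > high
#'   is the high group, TAS < low the low group).
#' @param n_boot,seed bootstrap resamples and seed for the regression and
#'   the normality screen's Monte-Carlo calibration.
#' @param normality_screen run the Lilliefors KS screen on outcome
#'   variables.
#' @param manual_exclusions participant ids excluded regardless of the
#'   attention check.
#' @param tas_scoring_key TAS key, see [tas_key()].
#' @return a `study_config` list.
#' @export
study_config <- function(study_design = c("single_group", "two_group"),
                         threshold_high = 60, threshold_low = 52,
                         n_boot = 1000, seed = 1L,
                         normality_screen = TRUE,
                         manual_exclusions = character(0),
                         tas_scoring_key = tas_key()) {
  study_design <- match.arg(study_design)
  if (threshold_low > threshold_high) {
    stop("threshold_low must not exceed threshold_high", call. = FALSE)
  }
  structure(list(study_design = study_design,
                 threshold_high = threshold_high,
                 threshold_low = threshold_low,
                 n_boot = n_boot, seed = as.integer(seed),
                 normality_screen = normality_screen,
                 manual_exclusions = manual_exclusions,
                 tas_scoring_key = tas_scoring_key),
            class = "study_config")
}

#' Run a full study analysis
#'
#' Executes the analysis chain on a cohort table: attention-check filter,
#' questionnaire scoring, differentiation indices, normality screen,
#' Spearman correlation matrix (pairwise deletion, paper-style variable
#' order), high- vs low-alexithymia Mann-Whitney comparison per
#' differentiation variable, and — for the single-group design with AI and
#' CRT present — a bias-corrected bootstrapped regression of evaluation
#' differentiation on DIF, DDF, EOT, AI and CRT (listwise). Comparisons
#' with fewer than 2 participants in either group are skipped and logged.
#'
#' @param cohort cohort data frame (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config a [study_config()].
#' @return a `study_report` list: `scored` (per-participant analysis table),
#'   `descriptives`, `correlations` (rho/p/n matrices), `normality`,
#'   `comparisons`, `regression` (or NULL), `exclusions`, `skipped`,
#'   `provenance`.
#' @export
run_study <- function(cohort, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  filt <- filter_attention(cohort, config$manual_exclusions)
  dat <- filt$cohort
  if (nrow(dat) == 0) stop("no participants remain after exclusions", call. = FALSE)

  scored <- score_cohort_tas(dat, key = config$tas_scoring_key)
  dd <- cohort_differentiation(dat)
  scored <- merge(scored, dd, by = "pid", sort = FALSE)
  scored$condition <- dat$condition[match(scored$pid, dat$pid)]
  scored$group <- assign_group(scored$tas_total,
                               config$threshold_high, config$threshold_low)

  skipped <- character(0)
  undef <- scored$pid[scored$n_defined == 0]
  if (length(undef)) {
    skipped <- c(skipped, sprintf("participant %s: no defined pictures, dropped from analyses",
                                  undef))
    scored_use <- scored[scored$n_defined > 0, , drop = FALSE]
  } else scored_use <- scored

  vars <- analysis_variables(scored_use, config$study_design)

  normality <- NULL
  if (config$normality_screen) {
    outcome_vars <- intersect(c("em_diff", "ev_diff"), names(vars))
    normality <- lapply(outcome_vars, function(v) {
      x <- vars[[v]][!is.na(vars[[v]])]
      if (length(x) < 4 || stats::sd(x) == 0) return(NULL)
      ks_normality(x, seed = config$seed)
    })
    names(normality) <- outcome_vars
  }

  correlations <- correlation_matrix(vars)

  comparisons <- list()
  for (v in intersect(c("em_diff", "ev_diff"), names(vars))) {
    hi <- vars[[v]][!is.na(vars[[v]]) & vars$group == "high"]
    lo <- vars[[v]][!is.na(vars[[v]]) & vars$group == "low"]
    if (length(hi) < 2 || length(lo) < 2) {
      skipped <- c(skipped, sprintf("comparison on %s skipped: high n = %d, low n = %d",
                                    v, length(hi), length(lo)))
      next
    }
    comparisons[[v]] <- mann_whitney(hi, lo)
  }

  regression <- NULL
  if (config$study_design == "single_group" &&
      all(c("ai_total", "crt_total") %in% names(scored_use))) {
    reg_dat <- scored_use[stats::complete.cases(
      scored_use[c("diff_index", "dif", "ddf", "eot", "ai_total", "crt_total")]), ]
    if (nrow(reg_dat) > 7) {
      regression <- bootstrap_ols(
        reg_dat$diff_index,
        data.frame(AI = reg_dat$ai_total, CRT = reg_dat$crt_total,
                   DIF = reg_dat$dif, DDF = reg_dat$ddf, EOT = reg_dat$eot),
        n_boot = config$n_boot, seed = config$seed)
    } else {
      skipped <- c(skipped, "regression skipped: fewer than 8 complete cases")
    }
  }

  structure(list(
    scored = scored,
    descriptives = descriptives_table(vars),
    correlations = correlations,
    normality = normality,
    comparisons = comparisons,
    regression = regression,
    exclusions = filt$log,
    skipped = skipped,
    provenance = list(seed = config$seed, design = config$study_design,
                      n_input = nrow(cohort), n_analysed = nrow(scored_use),
                      package_version = as.character(utils::packageVersion("evaldiff")))
  ), class = "study_report")
}

# analysis table in the paper's variable order:
# EmDiff/EvDiff, AI, CRT, DIF, DDF, EOT, TAS
analysis_variables <- function(scored, design) {
  out <- data.frame(pid = scored$pid, group = scored$group)
  if (design == "two_group") {
    out$em_diff <- ifelse(scored$condition == "emotion", scored$diff_index, NA)
    out$ev_diff <- ifelse(scored$condition == "evaluation", scored$diff_index, NA)
  } else {
    out$ev_diff <- scored$diff_index
  }
  if ("ai_total" %in% names(scored)) out$ai <- scored$ai_total
  if ("crt_total" %in% names(scored)) out$crt <- scored$crt_total
  out$dif <- scored$dif
  out$ddf <- scored$ddf
  out$eot <- scored$eot
  out$tas <- scored$tas_total
  out
}

numeric_vars <- function(vars) {
  vars[setdiff(names(vars), c("pid", "group"))]
}

descriptives_table <- function(vars) {
  nv <- numeric_vars(vars)
  data.frame(variable = names(nv),
             mean = vapply(nv, function(x) mean(x, na.rm = TRUE), numeric(1)),
             sd = vapply(nv, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
             n = vapply(nv, function(x) sum(!is.na(x)), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# pairwise-deletion Spearman matrix over the analysis variables
correlation_matrix <- function(vars) {
  nv <- numeric_vars(vars)
  p <- length(nv)
  rho <- pval <- nn <- matrix(NA_real_, p, p,
                              dimnames = list(names(nv), names(nv)))
  diag(rho) <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(nv[[i]], nv[[j]])
    if (sum(ok) >= 3 && stats::sd(rank(nv[[i]][ok])) > 0 &&
        stats::sd(rank(nv[[j]][ok])) > 0) {
      s <- spearman(nv[[i]], nv[[j]])
      rho[i, j] <- rho[j, i] <- s$rho
      pval[i, j] <- pval[j, i] <- s$p
      nn[i, j] <- nn[j, i] <- s$n
    }
  }
  list(rho = rho, p = pval, n = nn)
}

#' Format a correlation matrix with significance stars
#'
#' Upper-triangle display with the table-note convention: `*` marks
#' p < .05 and `**` marks p < .001.
#'
#' @param correlations the `correlations` element of a `study_report`.
#' @return character matrix.
#' @export
star_matrix <- function(correlations) {
  rho <- correlations$rho; p <- correlations$p
  out <- matrix("", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  for (i in seq_len(nrow(rho))) for (j in seq_len(ncol(rho))) {
    if (j < i || is.na(rho[i, j])) next
    stars <- if (i == j) "" else if (is.na(p[i, j])) "" else
      if (p[i, j] < 0.001) "**" else if (p[i, j] < 0.05) "*" else ""
    out[i, j] <- paste0(formatC(rho[i, j], digits = 3, format = "f"), stars)
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report (%s design): %d analysed of %d input participants\n",
              x$provenance$design, x$provenance$n_analysed, x$provenance$n_input))
  cat(sprintf("exclusions: %d; skipped analyses: %d\n",
              nrow(x$exclusions), length(x$skipped)))
  cat("\nDescriptives:\n"); print(x$descriptives, row.names = FALSE)
  cat("\nSpearman correlations (* p < .05, ** p < .001):\n")
  print(star_matrix(x$correlations), quote = FALSE)
  for (v in names(x$comparisons)) {
    cat(sprintf("\nHigh vs low alexithymia on %s: ", v))
    print(x$comparisons[[v]])
  }
  if (!is.null(x$regression)) { cat("\n"); print(x$regression) }
  invisible(x)
}

#' Write every table of a study report to CSV
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(report$descriptives, "descriptives.csv")
  utils::write.csv(star_matrix(report$correlations),
                   file.path(dir, "correlations.csv"))
  utils::write.csv(report$correlations$n, file.path(dir, "correlation_n.csv"))
  if (length(report$comparisons)) {
    comp <- do.call(rbind, lapply(names(report$comparisons), function(v) {
      cc <- report$comparisons[[v]]
      data.frame(variable = v, U = cc$U, z = cc$z, p = cc$p,
                 n_high = cc$n1, n_low = cc$n2, r = cc$r, d = cc$d)
    }))
    w(comp, "group_comparisons.csv")
  }
  if (!is.null(report$regression)) {
    w(report$regression$coef, "regression.csv")
    w(data.frame(r2 = report$regression$r2, adj_r2 = report$regression$adj_r2,
                 n = report$regression$n, n_boot = report$regression$n_boot,
                 seed = report$regression$seed), "regression_model.csv")
  }
  if (!is.null(report$normality)) {
    norm <- do.call(rbind, lapply(names(report$normality), function(v) {
      nr <- report$normality[[v]]
      if (is.null(nr)) return(NULL)
      data.frame(variable = v, D = nr$D, p = nr$p, n = nr$n)
    }))
    if (!is.null(norm)) w(norm, "normality.csv")
  }
  w(report$exclusions, "exclusions.csv")
  writeLines(c(sprintf("seed: %d", report$provenance$seed),
               sprintf("design: %s", report$provenance$design),
               sprintf("n_input: %d", report$provenance$n_input),
               sprintf("n_analysed: %d", report$provenance$n_analysed),
               sprintf("package_version: %s", report$provenance$package_version),
               if (length(report$skipped)) paste("skipped:", report$skipped)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
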
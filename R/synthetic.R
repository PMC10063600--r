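#' Configuration for a synthetic rating-scale cohort
#'
#' Defines the generating model for a cohort with the structure the analyses
#' assume: a single standard-normal latent trait (emotional unawareness)
#' drives the TAS-20 items and, through `trait_coupling`, the elevation of
#' off-target picture ratings toward the target rating — so higher trait
#' means blunter rating profiles and a lower differentiation index, while
#' overall valence detection (the target rating itself) stays intact. An
#' independent reasoning ability drives the CRT and, through
#' `crt_diff_rho`, sharpens differentiation; an attention-impulsiveness
#' latent shares loading with the trait to hit `tas_ai_rho`.
#'
#' @param n_participants cohort size.
#' @param n_categories number of picture categories = number of rating
#'   scales (default 4: fear/anger/disgust/sadness or their evaluations).
#' @param pictures_per_category pictures per category (default 3).
#' @param rating_scale_max top of the rating scale (default 100).
#' @param trait_coupling unitless logistic slope linking the latent trait to
#'   off-target elevation; 0 decouples ratings from the trait. See
#'   [tune_trait_coupling()] to pick a value for a target Spearman
#'   correlation between TAS and differentiation.
#' @param rating_noise_sd rating noise SD in rating units (default 15).
#' @param target_tas_mean,target_tas_sd targeted TAS-20 total mean and SD
#'   (defaults 45 and 13, the range typical of online community samples).
#' @param tas_ai_rho target correlation between TAS and AI totals
#'   (default 0.5).
#' @param tas_crt_rho target correlation between TAS and CRT (default 0).
#' @param crt_diff_rho target correlation between CRT and differentiation
#'   (default 0.17).
#' @param n_attention_failures how many participants fail the attention
#'   check (their response is overwritten with a non-maximum option).
#' @param master_seed integer master seed; every participant and purpose
#'   gets a derived stream, so growing the cohort never reshuffles earlier
#'   participants.
#' @param conditions rating-wording condition labels cycled over
#'   participants ("evaluation", "emotion", or both for a Study-1-style
#'   two-group design). Wording affects scale labels only, never values.
#' @param include_ai,include_crt generate the 5 AI items / 3 CRT answers.
#' @param base_target_rating,base_offtarget_rating expected target and
#'   off-target ratings for a trait-average participant before elevation
#'   (defaults 75 and 10, giving differentiation indices near 1.5).
#' @return validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants,
                          n_categories = 4L,
                          pictures_per_category = 3L,
                          rating_scale_max = 100,
                          trait_coupling = 1,
                          rating_noise_sd = 15,
                          target_tas_mean = 45,
                          target_tas_sd = 13,
                          tas_ai_rho = 0.5,
                          tas_crt_rho = 0,
                          crt_diff_rho = 0.17,
                          n_attention_failures = 0L,
                          master_seed = 1L,
                          conditions = "evaluation",
                          include_ai = TRUE,
                          include_crt = TRUE,
                          base_target_rating = 75,
                          base_offtarget_rating = 10) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_categories = as.integer(n_categories),
              pictures_per_category = as.integer(pictures_per_category),
              rating_scale_max = rating_scale_max,
              trait_coupling = trait_coupling,
              rating_noise_sd = rating_noise_sd,
              target_tas_mean = target_tas_mean,
              target_tas_sd = target_tas_sd,
              tas_ai_rho = tas_ai_rho,
              tas_crt_rho = tas_crt_rho,
              crt_diff_rho = crt_diff_rho,
              n_attention_failures = as.integer(n_attention_failures),
              master_seed = as.integer(master_seed),
              conditions = conditions,
              include_ai = include_ai,
              include_crt = include_crt,
              base_target_rating = base_target_rating,
              base_offtarget_rating = base_offtarget_rating)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, why),
         call. = FALSE)
  }
  for (f in c("n_participants", "n_categories", "pictures_per_category",
              "n_attention_failures")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) bad(f, "must be a non-negative count")
  }
  if (cfg$n_categories < 2) bad("n_categories", "must be >= 2")
  if (cfg$pictures_per_category < 1) bad("pictures_per_category", "must be >= 1")
  if (cfg$n_attention_failures > cfg$n_participants) {
    bad("n_attention_failures", "cannot exceed n_participants")
  }
  if (cfg$rating_scale_max <= 0) bad("rating_scale_max", "must be positive")
  if (cfg$target_tas_mean < 20 || cfg$target_tas_mean > 100) {
    bad("target_tas_mean", "must lie in the attainable TAS range [20, 100]")
  }
  if (cfg$target_tas_sd <= 0) bad("target_tas_sd", "must be positive")
  if (cfg$rating_noise_sd < 0) bad("rating_noise_sd", "must be non-negative")
  for (f in c("tas_ai_rho", "tas_crt_rho", "crt_diff_rho")) {
    if (abs(cfg[[f]]) > 1) bad(f, "must lie in [-1, 1]")
  }
  if (!all(cfg$conditions %in% c("emotion", "evaluation"))) {
    bad("conditions", "must be drawn from {emotion, evaluation}")
  }
  if (cfg$base_offtarget_rating < 0 ||
      cfg$base_target_rating > cfg$rating_scale_max ||
      cfg$base_target_rating <= cfg$base_offtarget_rating) {
    bad("base_target_rating", "base profile must satisfy 0 <= off-target < target <= scale max")
  }
  structure(cfg, class = "cohort_config")
}

# fixed internal loadings of the generating model (see the methods vignette):
# tas_lambda  - common loading of TAS items on the latent trait
# ai_lambda   - loading of AI items on the AI latent
# crt_lambda  - loading of CRT items on reasoning ability (alpha ~ .7)
# crt_pass    - CRT item pass probabilities (mean score ~ 1.4)
# elev_base   - off-target elevation fraction for a trait-average participant
# rho_atten   - attenuation divisor mapping a target total-score correlation
#               to a latent-trait correlation (discretisation + item noise)
# sd_inflate  - compensates the total-score SD shrinkage caused by rounding
#               responses to integer options and clipping at the scale ends
gen_const <- list(
  tas_lambda = 0.7,
  ai_lambda = 0.75,
  ai_mean = 9.5, ai_sd = 3.2,
  crt_lambda = 0.8,
  crt_pass = c(0.62, 0.48, 0.32),
  elev_base = 0.15,
  rho_atten = 0.81,
  sd_inflate = 1.10
)

participant_seed <- function(master_seed, i, purpose = 0L) {
  # cheap splitmix-style derivation, kept inside 32-bit integer range
  as.integer((as.double(master_seed) * 2654435 + i * 40503 + purpose * 69069) %% 2147483647)
}

category_labels <- c("fear", "anger", "disgust", "sadness")
scale_labels <- list(
  emotion = c("Afraid", "Angry", "Grossed out", "Sad"),
  evaluation = c("Dangerous", "Offensive", "Foul", "Irrevocable loss")
)

picture_categories <- function(cfg) {
  rep(seq_len(cfg$n_categories), each = cfg$pictures_per_category)
}

#' Generate one participant's ratings block
#'
#' Builds the pictures x scales matrix for a participant with the given
#' latent trait. Each picture's target-scale expectation is the base target
#' rating; off-target expectations sit `elevation` of the way from the base
#' off-target rating to the target, where elevation is a logistic function
#' of `trait_coupling * trait` (minus a reasoning contribution), so the
#' expected target/off-target gap shrinks as the trait rises but never
#' inverts. Gaussian rating noise is added, and values are rounded and
#' clipped to \[0, rating_scale_max\].
#'
#' @param trait latent trait value in standard-normal units.
#' @param config a [cohort_config()].
#' @param stream_seed integer seed for this block's noise stream.
#' @param ability reasoning-ability latent (sharpens differentiation when
#'   `crt_diff_rho` is nonzero).
#' @param condition wording condition, sets the column labels only.
#' @return numeric matrix (`ratings_block`) with picture rows, scale
#'   columns, and a `target_category` attribute.
#' @export
generate_rating_block <- function(trait, config, stream_seed,
                                  ability = 0, condition = "evaluation") {
  if (!is.finite(trait)) stop("trait must be finite", call. = FALSE)
  cfg <- validate_config(config)
  set.seed(stream_seed)
  block <- rating_block_values(trait, cfg, ability)
  n_pic <- nrow(block)
  cats <- picture_categories(cfg)
  cat_names <- if (cfg$n_categories == 4) category_labels else
    paste0("cat", seq_len(cfg$n_categories))
  cols <- if (cfg$n_categories == 4 && condition %in% names(scale_labels)) {
    scale_labels[[condition]]
  } else paste0("s", seq_len(cfg$n_categories))
  dimnames(block) <- list(sprintf("p%02d", seq_len(n_pic)), cols)
  structure(block, target_category = cat_names[cats], class = "ratings_block")
}

# noise drawn from the current RNG state
rating_block_values <- function(trait, cfg, ability) {
  n_pic <- cfg$n_categories * cfg$pictures_per_category
  k <- cfg$n_categories
  gap <- cfg$base_target_rating - cfg$base_offtarget_rating
  lin <- stats::qlogis(gen_const$elev_base) +
    cfg$trait_coupling * trait - crt_weight(cfg) * ability
  elev <- stats::plogis(lin)
  mu <- matrix(cfg$base_offtarget_rating + elev * gap, n_pic, k)
  cats <- picture_categories(cfg)
  mu[cbind(seq_len(n_pic), cats)] <- cfg$base_target_rating
  noise <- matrix(stats::rnorm(n_pic * k, 0, cfg$rating_noise_sd), n_pic, k)
  pmin(pmax(round(mu + noise), 0), cfg$rating_scale_max)
}

# logistic weight of reasoning ability on elevation, scaled so the default
# crt_diff_rho ~ .17 produces a correlation of about that size
crt_weight <- function(cfg) {
  if (!cfg$include_crt) return(0)
  1.4 * cfg$crt_diff_rho
}

#' Generate a synthetic cohort with its generating truth
#'
#' Draws `n_participants` records under the model described in
#' [cohort_config()]. Deterministic for a fixed `master_seed`; each
#' participant owns a derived random stream, so a cohort of size n is a
#' prefix of the same-seed cohort of size n' > n. Exactly
#' `n_attention_failures` records get a non-maximum attention response
#' (chosen from a dedicated stream, independent of the trait).
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (wide data frame: `pid`, `condition`,
#'   `tas_1..tas_20`, `attn`, optional `ai_1..ai_5` and `crt_1..crt_3`,
#'   `rating_<pic>_<scale>`, `age`, `gender`) and `truth` (per-participant
#'   latent values plus the echoed config).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_config(config)
  n <- cfg$n_participants
  key <- tas_key()
  n_pic <- cfg$n_categories * cfg$pictures_per_category
  k <- cfg$n_categories

  # latent-trait correlations implied by the configured total-score targets
  c_ai <- clamp_rho(cfg$tas_ai_rho / gen_const$rho_atten)
  c_crt <- clamp_rho(cfg$tas_crt_rho / gen_const$rho_atten)

  lam <- gen_const$tas_lambda
  tas_item_mu <- cfg$target_tas_mean / 20
  tas_item_sd <- gen_const$sd_inflate * cfg$target_tas_sd /
    sqrt(400 * lam^2 + 20 * (1 - lam^2))
  lam_a <- gen_const$ai_lambda
  ai_item_mu <- gen_const$ai_mean / 5
  ai_item_sd <- gen_const$sd_inflate * gen_const$ai_sd /
    sqrt(25 * lam_a^2 + 5 * (1 - lam_a^2))
  lam_c <- gen_const$crt_lambda

  n_cols <- 20 + 1 + 5 + 3 + n_pic * k + 2  # tas, attn, ai, crt, ratings, age/gender code
  vals <- matrix(NA_real_, n, n_cols)
  trait <- numeric(n)
  ability <- numeric(n)

  for (i in seq_len(n)) {
    set.seed(participant_seed(cfg$master_seed, i))
    th <- stats::rnorm(1)
    gg <- c_crt * th + sqrt(1 - c_crt^2) * stats::rnorm(1)
    vv <- c_ai * th + sqrt(1 - c_ai^2) * stats::rnorm(1)
    trait[i] <- th; ability[i] <- gg

    # TAS-20: keyed-scale values, monotone in the trait, then raw-coded
    u <- lam * th + sqrt(1 - lam^2) * stats::rnorm(20)
    s_items <- pmin(pmax(round(tas_item_mu + tas_item_sd * u), 1), 5)
    raw <- s_items
    raw[key$reverse] <- 6 - s_items[key$reverse]

    ai_u <- lam_a * vv + sqrt(1 - lam_a^2) * stats::rnorm(5)
    ai_items <- pmin(pmax(round(ai_item_mu + ai_item_sd * ai_u), 1), 4)

    crt_u <- lam_c * gg + sqrt(1 - lam_c^2) * stats::rnorm(3)
    crt_items <- as.numeric(crt_u > stats::qnorm(1 - gen_const$crt_pass))

    ratings <- rating_block_values(th, cfg, gg)

    age <- round(min(max(stats::rnorm(1, 36, 12), 18), 80))
    gender_code <- stats::rbinom(1, 1, 0.5)

    vals[i, ] <- c(raw, 5, ai_items, crt_items, as.vector(t(ratings)),
                   age, gender_code)
  }

  # attention failures: dedicated stream, independent of participant draws
  if (cfg$n_attention_failures > 0) {
    set.seed(participant_seed(cfg$master_seed, 0L, purpose = 1L))
    fail_idx <- sample.int(n, cfg$n_attention_failures)
    vals[fail_idx, 21] <- sample(1:4, cfg$n_attention_failures, replace = TRUE)
  }

  pic_ids <- sprintf("p%02d", seq_len(n_pic))
  rating_names <- as.vector(t(outer(pic_ids, paste0("s", seq_len(k)),
                                    function(p, s) paste0("rating_", p, "_", s))))
  cn <- c(paste0("tas_", 1:20), "attn", paste0("ai_", 1:5),
          paste0("crt_", 1:3), rating_names, "age", "gender_code")
  colnames(vals) <- cn

  df <- as.data.frame(vals)
  df$gender <- ifelse(df$gender_code == 1, "female", "male")
  df$gender_code <- NULL
  df$pid <- sprintf("P%04d", seq_len(n))
  df$condition <- rep_len(cfg$conditions, n)
  if (!cfg$include_ai) df[paste0("ai_", 1:5)] <- NULL
  if (!cfg$include_crt) df[paste0("crt_", 1:3)] <- NULL
  front <- c("pid", "condition")
  df <- df[c(front, setdiff(names(df), front))]

  truth <- list(
    participants = data.frame(pid = df$pid, trait = trait, ability = ability,
                              stringsAsFactors = FALSE),
    picture_category = if (cfg$n_categories == 4) {
      category_labels[picture_categories(cfg)]
    } else paste0("cat", picture_categories(cfg)),
    config = cfg
  )
  list(cohort = df, truth = truth)
}

clamp_rho <- function(x) max(-0.99, min(0.99, x))

#' Tune the trait coupling for a target TAS-differentiation correlation
#'
#' The mapping from the logistic coupling slope to the observable Spearman
#' correlation between TAS totals and the differentiation index has no
#' closed form (it passes through item discretisation, rating noise and the
#' max/mean index), so it is solved numerically: the sample correlation is
#' evaluated on a seeded calibration cohort and the slope is found by
#' bisection. Deterministic given the config's master seed.
#'
#' @param config a [cohort_config()]; its `trait_coupling` is ignored.
#' @param target_rho desired Spearman correlation (negative: higher TAS,
#'   lower differentiation), e.g. -0.42 for a Study-1-like cohort or -0.16
#'   for a Study-2-like one.
#' @param n_cal calibration cohort size (default 4000).
#' @param iterations bisection steps (default 12).
#' @return the tuned `trait_coupling` slope.
#' @export
tune_trait_coupling <- function(config, target_rho, n_cal = 4000,
                                iterations = 12) {
  cfg <- validate_config(config)
  if (target_rho >= 0) stop("target_rho must be negative: the trait blunts differentiation",
                            call. = FALSE)
  cal_seed <- participant_seed(cfg$master_seed, 0L, purpose = 2L)
  rho_at <- function(coupling) {
    cfg$trait_coupling <- coupling
    cfg$n_participants <- as.integer(n_cal)
    cfg$n_attention_failures <- 0L
    cfg$master_seed <- cal_seed
    g <- generate_cohort(cfg)
    tas <- score_cohort_tas(g$cohort)$tas_total
    d <- cohort_differentiation(g$cohort)$diff_index
    spearman(tas, d)$rho
  }
  lo <- 0; hi <- 2
  while (rho_at(hi) > target_rho) {
    hi <- hi * 2
    if (hi > 32) stop("target_rho unreachable at this noise level", call. = FALSE)
  }
  for (it in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (rho_at(mid) > target_rho) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Study-condition cohort configurations
#'
#' Convenience constructors matching the two study designs: Study 1 is a
#' two-condition (emotion- vs evaluation-wording) cohort of 151 with 3
#' attention failures and a TAS-differentiation correlation near -0.42;
#' Study 2 is a single-condition cohort of 301 with 4 attention failures,
#' AI and CRT measures, and a correlation near -0.16.
#'
#' @param master_seed integer seed.
#' @param tuned tune `trait_coupling` to the study's correlation target
#'   (costs a few seconds); if FALSE a pre-tuned default slope is used.
#' @return a [cohort_config()].
#' @export
study1_config <- function(master_seed = 1L, tuned = TRUE) {
  cfg <- cohort_config(n_participants = 151, n_attention_failures = 3,
                       conditions = c("emotion", "evaluation"),
                       include_ai = FALSE, include_crt = FALSE,
                       target_tas_sd = 14.7,
                       master_seed = master_seed)
  cfg$trait_coupling <- if (tuned) tune_trait_coupling(cfg, -0.42) else 0.75
  cfg
}

#' @rdname study1_config
#' @export
study2_config <- function(master_seed = 2L, tuned = TRUE) {
  cfg <- cohort_config(n_participants = 301, n_attention_failures = 4,
                       conditions = "evaluation",
                       target_tas_sd = 11.6,
                       master_seed = master_seed)
  cfg$trait_coupling <- if (tuned) tune_trait_coupling(cfg, -0.16) else 0.25
  cfg
}
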
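#' Combine the two affective items into one score
#'
#' The two affective responses (felt negativity, expected offensiveness to
#' similar people) are averaged into one summative scale. Higher values
#' mean a more negative/offended reaction; "neutral or positive" therefore
#' means a score at or below the neutrality cutoff.
#'
#' @param negativity,offensiveness Numeric responses on the same scale
#'   (-3..+3 in the synthetic world).
#' @return Element-wise arithmetic mean; `NA` where either item is missing
#'   (such records are excluded from aggregation with a log message).
#' @export
affect_score <- function(negativity, offensiveness) {
  (negativity + offensiveness) / 2
}

#' Check affective-item polarity across a dataset
#'
#' The two affective items should correlate positively (about .70 under the
#' default synthetic world). A negative correlation indicates a
#' scale-reversal misconfiguration and triggers a warning.
#'
#' @param ratings Rating records with `negativity` and `offensiveness`.
#' @return The Pearson correlation, invisibly.
#' @export
check_affect_polarity <- function(ratings) {
  r <- stats::cor(ratings$negativity, ratings$offensiveness,
                  use = "complete.obs")
  if (!is.na(r) && r < 0)
    warning(sprintf(paste("affective items correlate negatively (r = %.2f):",
                          "one item's scale is likely reversed"), r),
            call. = FALSE)
  invisible(r)
}

#' Aggregate rating records into per-group tweet scores
#'
#' For every tweet x rater-group cell computes the mean perceived political
#' orientation among raters who judged the tweet political (`NA` when no
#' rater in the group did), the fraction judging it political
#' (`p_political`), the mean combined affect score, and the rater count.
#' Records missing an affective item are excluded with a message.
#'
#' @param ratings Rating records: `tweet_id`, `rater_id`, `rater_group`,
#'   `orientation` (integer or `NA` = "not political"), `negativity`,
#'   `offensiveness`.
#' @return Data frame with one row per tweet x group: `tweet_id`,
#'   `rater_group`, `orientation_mean`, `p_political`, `affect_mean`,
#'   `n_raters`.
#' @export
aggregate_group_scores <- function(ratings) {
  if (nrow(ratings) == 0)
    stop("no rating records to aggregate", call. = FALSE)
  aff <- affect_score(ratings$negativity, ratings$offensiveness)
  drop <- is.na(aff)
  if (any(drop)) {
    message(sprintf("excluding %d record(s) with a missing affective item",
                    sum(drop)))
    ratings <- ratings[!drop, , drop = FALSE]
    aff <- aff[!drop]
  }
  key <- interaction(ratings$tweet_id, ratings$rater_group, drop = TRUE)
  or_mean <- tapply(ratings$orientation, key,
                    function(x) if (all(is.na(x))) NA_real_
                                else mean(x, na.rm = TRUE))
  p_pol <- tapply(!is.na(ratings$orientation), key, mean)
  af_mean <- tapply(aff, key, mean)
  n <- tapply(aff, key, length)
  parts <- do.call(rbind, strsplit(names(or_mean), ".", fixed = TRUE))
  out <- data.frame(tweet_id = parts[, 1], rater_group = parts[, 2],
                    orientation_mean = as.numeric(or_mean),
                    p_political = as.numeric(p_pol),
                    affect_mean = as.numeric(af_mean),
                    n_raters = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$tweet_id, out$rater_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inclusion filter: at least three raters from every group
#'
#' Keeps tweets rated by at least `min_raters` raters from each of the four
#' political-leaning groups.
#'
#' @param ratings Rating records (see [aggregate_group_scores()]).
#' @param min_raters Minimum raters per group per tweet (default 3).
#' @return List with `included` (character vector of tweet IDs) and
#'   `counts` (data frame of per-tweet, per-group rater counts).
#' @export
inclusion_filter <- function(ratings, min_raters = 3L) {
  tab <- table(ratings$tweet_id, ratings$rater_group)
  missing_groups <- setdiff(rater_groups, colnames(tab))
  counts <- as.data.frame.matrix(tab)
  for (g in missing_groups) counts[[g]] <- 0L
  counts <- counts[, rater_groups, drop = FALSE]
  ok <- apply(counts >= min_raters, 1, all)
  list(included = rownames(counts)[ok],
       counts = data.frame(tweet_id = rownames(counts), counts,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Threshold configuration for covert/overt classification
#'
#' All tunable cutoffs live here; none are hidden in the classifier.
#' Gap criteria use percentile cutoffs computed over the pooled
#' per-tweet-per-side statistics of the dataset at hand (as in the
#' percentile-based preselection); bands and minima are absolute values on
#' the response scales.
#'
#' @param covert_or_gap_pctl Percentile of the copartisan orientation gap a
#'   covert candidate must exceed.
#' @param covert_affect_gap_pctl Percentile of the copartisan affect gap a
#'   covert candidate must exceed.
#' @param neutral_band Moderates' mean orientation is "neutral" when its
#'   absolute value is at most this (7-point scale units).
#' @param not_political_majority Moderates are "predominantly not
#'   political" when their `p_political` is at most this.
#' @param moderate_affect_max Moderates' affect is "neutral or positive"
#'   (toward the tweet) when at most this (higher = more negative).
#' @param recognition_min Minimum `p_political` among far copartisans for a
#'   covert candidate.
#' @param overt_or_band Maximum cross-partisan orientation-mean gap for an
#'   overt candidate.
#' @param overt_cross_affect_gap_pctl Percentile of the cross-partisan
#'   affect gap an overt candidate must exceed.
#' @param overt_co_affect_band Maximum copartisan affect gap for an overt
#'   candidate.
#' @param overt_recognition_min Minimum `p_political` in every group for an
#'   overt candidate.
#' @param side_lean_min Minimum far-copartisan orientation lean (toward the
#'   candidate side) for either category.
#' @param preselect_cap Per-category cap for automatic preselection
#'   (default 30).
#' @param final_cap Per-category count for the final menu (default 20);
#'   recorded for downstream use, not applied by the classifier.
#' @return A list of class `"classification_thresholds"`.
#' @export
classification_thresholds <- function(covert_or_gap_pctl = 60,
                                      covert_affect_gap_pctl = 60,
                                      neutral_band = 0.5,
                                      not_political_majority = 0.5,
                                      moderate_affect_max = 0.5,
                                      recognition_min = 0.5,
                                      overt_or_band = 0.75,
                                      overt_cross_affect_gap_pctl = 55,
                                      overt_co_affect_band = 1.5,
                                      overt_recognition_min = 0.5,
                                      side_lean_min = 1.0,
                                      preselect_cap = 30L,
                                      final_cap = 20L) {
  pct <- c(covert_or_gap_pctl, covert_affect_gap_pctl,
           overt_cross_affect_gap_pctl)
  if (any(pct < 0 | pct > 100))
    stop("percentile cutoffs must lie in [0, 100]", call. = FALSE)
  if (preselect_cap < 0 || final_cap < 0)
    stop("caps must be non-negative", call. = FALSE)
  structure(as.list(environment()), class = "classification_thresholds")
}

# wide per-tweet score table: one column per group per statistic
scores_wide <- function(scores) {
  tw <- sort(unique(scores$tweet_id))
  out <- data.frame(tweet_id = tw, stringsAsFactors = FALSE)
  for (g in rater_groups) {
    sg <- scores[scores$rater_group == g, , drop = FALSE]
    i <- match(tw, sg$tweet_id)
    out[[paste0("or_", g)]] <- sg$orientation_mean[i]
    out[[paste0("p_", g)]] <- sg$p_political[i]
    out[[paste0("af_", g)]] <- sg$affect_mean[i]
  }
  out
}

# per-tweet criterion statistics for one candidate side.
# Undefined orientation means (no recognizers in a group) are treated as
# "not recognized": they enter gap statistics as 0 (scale midpoint).
side_stats <- function(wide, side) {
  co <- if (side == "left") c("far_left", "moderate_left")
        else c("far_right", "moderate_right")
  cross <- setdiff(rater_groups, co)
  fill0 <- function(x) ifelse(is.na(x), 0, x)
  or_far_co <- fill0(wide[[paste0("or_", co[1])]])
  or_mod_co <- fill0(wide[[paste0("or_", co[2])]])
  or_far_cross <- fill0(wide[[paste0("or_", cross[2])]])
  or_mod_cross <- fill0(wide[[paste0("or_", cross[1])]])
  af <- lapply(rater_groups, function(g) wide[[paste0("af_", g)]])
  names(af) <- rater_groups
  p <- lapply(rater_groups, function(g) wide[[paste0("p_", g)]])
  names(p) <- rater_groups
  side_sign <- if (side == "left") -1 else 1
  data.frame(
    tweet_id = wide$tweet_id, side = side,
    co_or_gap = abs(or_far_co - or_mod_co),
    co_affect_gap = abs(af[[co[1]]] - af[[co[2]]]),
    mod_or_abs = abs(or_mod_co),
    mod_p_political = p[[co[2]]],
    mod_affect = af[[co[2]]],
    far_p_political = p[[co[1]]],
    cross_or_gap = abs((or_far_co + or_mod_co) / 2 -
                         (or_far_cross + or_mod_cross) / 2),
    cross_affect_gap = abs((af[[co[1]]] + af[[co[2]]]) / 2 -
                             (af[[cross[1]]] + af[[cross[2]]]) / 2),
    min_p_political = pmin(p[[rater_groups[1]]], p[[rater_groups[2]]],
                           p[[rater_groups[3]]], p[[rater_groups[4]]]),
    far_co_lean = side_sign * or_far_co,
    stringsAsFactors = FALSE
  )
}

pct_rank <- function(x) rank(x, ties.method = "average") / length(x)

#' Evaluate the covert-signal criteria for one candidate side
#'
#' Applies the five theory-based covert criteria to per-tweet side
#' statistics: (1) large copartisan orientation gap, (2) large copartisan
#' affect gap, (3) moderates neutral in orientation or predominantly "not
#' political", (4) moderates' affect neutral-or-positive, (5) political
#' content recognized by far copartisans. A side-consistency flag
#' additionally requires the far copartisans' mean orientation to lean
#' toward the candidate side. Gap cutoffs are absolute values (resolved
#' from percentile settings by [classify_tweets()]).
#'
#' @param stats Per-tweet side statistics from the internal score table.
#' @param cutoffs Named list with `or_gap`, `affect_gap` absolute cutoffs
#'   plus the band/minimum entries of [classification_thresholds()].
#' @return Data frame of logical flags `c1`..`c5`, `side_match`, and
#'   `pass`.
#' @export
evaluate_covert_criteria <- function(stats, cutoffs) {
  c1 <- stats$co_or_gap >= cutoffs$or_gap
  c2 <- stats$co_affect_gap >= cutoffs$affect_gap
  c3 <- stats$mod_or_abs <= cutoffs$neutral_band |
    stats$mod_p_political <= cutoffs$not_political_majority
  c4 <- stats$mod_affect <= cutoffs$moderate_affect_max
  c5 <- stats$far_p_political >= cutoffs$recognition_min
  side_match <- stats$far_co_lean >= cutoffs$side_lean_min
  data.frame(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
             side_match = side_match,
             pass = c1 & c2 & c3 & c4 & c5 & side_match)
}

#' Evaluate the overt-signal criteria for one candidate side
#'
#' Applies the four theory-based overt criteria: (1) small cross-partisan
#' orientation gap (everyone agrees on the author's side), (2) large
#' cross-partisan affect gap, (3) small copartisan affect gap, (4)
#' political content recognized by all four groups; plus the side
#' consistency flag.
#'
#' @inheritParams evaluate_covert_criteria
#' @return Data frame of logical flags `c1`..`c4`, `side_match`, `pass`.
#' @export
evaluate_overt_criteria <- function(stats, cutoffs) {
  c1 <- stats$cross_or_gap <= cutoffs$overt_or_band
  c2 <- stats$cross_affect_gap >= cutoffs$affect_gap
  c3 <- stats$co_affect_gap <= cutoffs$overt_co_affect_band
  c4 <- stats$min_p_political >= cutoffs$overt_recognition_min
  side_match <- stats$far_co_lean >= cutoffs$side_lean_min
  data.frame(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
             side_match = side_match,
             pass = c1 & c2 & c3 & c4 & side_match)
}

#' Classify tweets as covert or overt identity signals from rater scores
#'
#' Runs the full rater-based classification: applies the inclusion filter
#' (>= 3 raters per group), aggregates group scores, computes per-side
#' criterion statistics, resolves percentile cutoffs on the pooled
#' statistics (pooling both sides keeps the procedure exactly symmetric
#' under a left/right mirror), evaluates the covert and overt criteria, and
#' assigns each tweet to `covert_left`, `covert_right`, `overt_left`,
#' `overt_right`, or `none`. A tweet passing both the covert and the overt
#' criteria (possible under loose thresholds) is assigned `none` and
#' flagged, mirroring the recoding of ambiguous items as neither covert nor
#' overt.
#'
#' The composite score used for ranking within a category is the mean of
#' the per-criterion percentile ranks of the tweet's statistics (equal
#' weights); it orders candidates but plays no role in pass/fail.
#'
#' @param ratings Rating records (see [aggregate_group_scores()]).
#' @param thresholds A [classification_thresholds()].
#' @return Data frame with one row per included tweet: `tweet_id`,
#'   `category`, `covert_score_left/right`, `overt_score_left/right`,
#'   `both_flag`. Per-criterion flags are attached as
#'   `attr(, "details")` (one data frame per side and family); resolved
#'   absolute cutoffs as `attr(, "cutoffs")`.
#' @export
classify_tweets <- function(ratings, thresholds = classification_thresholds()) {
  check_affect_polarity(ratings)
  incl <- inclusion_filter(ratings)
  ratings <- ratings[ratings$tweet_id %in% incl$included, , drop = FALSE]
  if (nrow(ratings) == 0)
    stop("no tweets satisfy the inclusion rule", call. = FALSE)
  scores <- aggregate_group_scores(ratings)
  wide <- scores_wide(scores)
  st <- rbind(side_stats(wide, "left"), side_stats(wide, "right"))

  cutoffs <- list(
    or_gap = as.numeric(stats::quantile(st$co_or_gap,
                                        thresholds$covert_or_gap_pctl / 100)),
    affect_gap = as.numeric(
      stats::quantile(st$co_affect_gap,
                      thresholds$covert_affect_gap_pctl / 100)),
    overt_cross_affect_gap = as.numeric(
      stats::quantile(st$cross_affect_gap,
                      thresholds$overt_cross_affect_gap_pctl / 100)),
    neutral_band = thresholds$neutral_band,
    not_political_majority = thresholds$not_political_majority,
    moderate_affect_max = thresholds$moderate_affect_max,
    recognition_min = thresholds$recognition_min,
    overt_or_band = thresholds$overt_or_band,
    overt_co_affect_band = thresholds$overt_co_affect_band,
    overt_recognition_min = thresholds$overt_recognition_min,
    side_lean_min = thresholds$side_lean_min
  )

  details <- list()
  res <- data.frame(tweet_id = wide$tweet_id, stringsAsFactors = FALSE)
  for (side in c("left", "right")) {
    s <- st[st$side == side, , drop = FALSE]
    cov <- evaluate_covert_criteria(s, cutoffs)
    ov <- evaluate_overt_criteria(
      s, within(cutoffs, affect_gap <- overt_cross_affect_gap))
    details[[paste0("covert_", side)]] <- cbind(s["tweet_id"], cov)
    details[[paste0("overt_", side)]] <- cbind(s["tweet_id"], ov)
    res[[paste0("covert_pass_", side)]] <- cov$pass
    res[[paste0("overt_pass_", side)]] <- ov$pass
    # composite percentile-rank scores (ranks over the pooled two-side set)
    res[[paste0("covert_score_", side)]] <- rowMeans(cbind(
      pct_rank(st$co_or_gap)[st$side == side],
      pct_rank(st$co_affect_gap)[st$side == side],
      pct_rank(-st$mod_or_abs)[st$side == side],
      pct_rank(-st$mod_affect)[st$side == side],
      pct_rank(st$far_p_political)[st$side == side]))
    res[[paste0("overt_score_", side)]] <- rowMeans(cbind(
      pct_rank(-st$cross_or_gap)[st$side == side],
      pct_rank(st$cross_affect_gap)[st$side == side],
      pct_rank(-st$co_affect_gap)[st$side == side],
      pct_rank(st$min_p_political)[st$side == side]))
  }

  n_pass <- res$covert_pass_left + res$covert_pass_right +
    res$overt_pass_left + res$overt_pass_right
  res$both_flag <- n_pass > 1
  if (any(res$both_flag))
    message(sprintf(paste("%d tweet(s) pass more than one category and are",
                          "recoded as neither covert nor overt"),
                    sum(res$both_flag)))
  category <- rep("none", nrow(res))
  category[res$covert_pass_left & n_pass == 1] <- "covert_left"
  category[res$covert_pass_right & n_pass == 1] <- "covert_right"
  category[res$overt_pass_left & n_pass == 1] <- "overt_left"
  category[res$overt_pass_right & n_pass == 1] <- "overt_right"
  res$category <- category
  structure(res[, c("tweet_id", "category", "covert_score_left",
                    "covert_score_right", "overt_score_left",
                    "overt_score_right", "both_flag")],
            details = details, cutoffs = cutoffs)
}

#' Rank and truncate candidate lists per category
#'
#' Orders each category's passing tweets by the composite percentile-rank
#' score (ties broken by tweet ID, lower first) and truncates at the
#' preselection cap. When fewer tweets pass than the cap, the shorter list
#' is returned with a warning; lists are never padded.
#'
#' @param labels Output of [classify_tweets()].
#' @param thresholds A [classification_thresholds()] (supplies
#'   `preselect_cap`).
#' @return Named list of data frames (`covert_left`, `covert_right`,
#'   `overt_left`, `overt_right`) with `tweet_id`, `composite`, `rank`.
#' @export
select_candidates <- function(labels,
                              thresholds = classification_thresholds()) {
  cap <- thresholds$preselect_cap
  out <- list()
  for (cat in c("covert_left", "covert_right", "overt_left", "overt_right")) {
    side <- sub("^[a-z]+_", "", cat)
    fam <- sub("_[a-z]+$", "", cat)
    score_col <- paste0(fam, "_score_", side)
    sel <- labels[labels$category == cat, c("tweet_id", score_col)]
    names(sel)[2] <- "composite"
    sel <- sel[order(-sel$composite, sel$tweet_id), , drop = FALSE]
    if (nrow(sel) < cap)
      warning(sprintf("category %s: only %d candidate(s) pass (cap %d)",
                      cat, nrow(sel), cap), call. = FALSE)
    sel <- utils::head(sel, cap)
    sel$rank <- seq_len(nrow(sel))
    rownames(sel) <- NULL
    out[[cat]] <- sel
  }
  out
}

#' Shapley decomposition of interrater rating variance
#'
#' Fits random-effects (intercept-only) linear models of the political
#' orientation ratings on every subset of the factors tweet, rater, and
#' rater group, measures each subset's explained variance with McFadden's
#' pseudo-R-squared (1 minus the ratio of model to intercept-only
#' log-likelihood, maximum-likelihood fits), and attributes the full
#' model's explained share to the factors by their Shapley values. By the
#' efficiency axiom the per-factor shares sum exactly to the total
#' explained share.
#'
#' @param ratings Rating records; only rows with a political-orientation
#'   judgment (non-`NA` `orientation`) enter the model.
#' @param factors Factor columns to decompose over; defaults to
#'   `tweet_id`, `rater_id`, `rater_group`.
#' @return List with `total_explained` (McFadden pseudo-R-squared of the
#'   full model), `shares` (named, summing to `total_explained`),
#'   `shares_of_explained` (`shares / total_explained`), and
#'   `subset_r2` (pseudo-R-squared of every factor subset).
#' @export
rating_variance_decomposition <- function(ratings,
                                          factors = c("tweet_id", "rater_id",
                                                      "rater_group")) {
  dat <- ratings[!is.na(ratings$orientation), , drop = FALSE]
  if (nrow(dat) < 10)
    stop("too few political judgments to decompose", call. = FALSE)
  y <- as.numeric(dat$orientation)
  degenerate <- vapply(factors, function(f) length(unique(dat[[f]])) < 2,
                       logical(1))
  if (any(degenerate)) {
    warning(sprintf("factor(s) with a single level get share 0: %s",
                    paste(factors[degenerate], collapse = ", ")),
            call. = FALSE)
  }
  active <- factors[!degenerate]
  p <- length(active)
  ll0 <- as.numeric(stats::logLik(stats::lm(y ~ 1)))

  subset_key <- function(s) paste(sort(s), collapse = "+")
  r2 <- c(`(none)` = 0)
  if (p > 0) {
    subsets <- unlist(lapply(seq_len(p), function(k)
      utils::combn(active, k, simplify = FALSE)), recursive = FALSE)
    for (s in subsets) {
      fml <- stats::as.formula(paste(
        "y ~ 1 +", paste(sprintf("(1 | %s)", s), collapse = " + ")))
      fit <- lme4::lmer(fml, data = cbind(dat, y = y), REML = FALSE,
                        control = lme4::lmerControl(calc.derivs = FALSE,
                                                    check.conv.singular =
                                                      "ignore"))
      r2[subset_key(s)] <- 1 - as.numeric(stats::logLik(fit)) / ll0
    }
  }
  get_r2 <- function(s) if (length(s) == 0) 0 else r2[[subset_key(s)]]

  shares <- stats::setNames(numeric(length(factors)), factors)
  for (f in active) {
    others <- setdiff(active, f)
    val <- 0
    for (k in 0:length(others)) {
      combos <- if (k == 0) list(character(0))
                else utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (s in combos)
        val <- val + w * (get_r2(c(s, f)) - get_r2(s))
    }
    shares[f] <- val
  }
  total <- get_r2(active)
  list(total_explained = total, shares = shares,
       shares_of_explained = if (total > 0) shares / total else shares * NA,
       subset_r2 = r2)
}
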
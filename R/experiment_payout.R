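#' Compute a participant's payout for one experimental round
#'
#' Applies the majority rule: each audience member who liked a strict
#' majority (> half) of the tweets the participant shared confers the
#' like bonus; each member who disliked a strict majority is charged as a
#' dislike cost; members with no strict majority either way (including
#' neutral-heavy members and exact ties) contribute nothing. The baseline
#' payment is added in all cases.
#'
#' @param reactions Data frame of per-member, per-tweet reactions:
#'   `member_id`, `tweet_id`, `reaction` in
#'   `{"like", "dislike", "neutral"}` (as produced by
#'   [generate_audience_responses()]).
#' @param benefit Bonus per like-majority member, cents (default 1).
#' @param cost Cost per dislike-majority member, cents.
#' @param baseline Baseline payment, cents (the study baseline was 340).
#' @return Payout in cents. When no tweets were shared, no member can hold
#'   a majority: the baseline is returned with
#'   `attr(, "no_shares") = TRUE`.
#' @export
compute_round_payout <- function(reactions, benefit = 1, cost = 1,
                                 baseline = 0) {
  if (nrow(reactions) == 0)
    return(structure(baseline, no_shares = TRUE))
  n_shared <- length(unique(reactions$tweet_id))
  likes <- tapply(reactions$reaction == "like", reactions$member_id, sum)
  dislikes <- tapply(reactions$reaction == "dislike", reactions$member_id,
                     sum)
  like_majority <- sum(likes > n_shared / 2)
  dislike_majority <- sum(dislikes > n_shared / 2)
  baseline + benefit * like_majority - cost * dislike_majority
}

#' Maximum difference in losses between cost conditions
#'
#' The worst case for a round is every audience member disliking a majority
#' of shares: a loss of `n * c`. Summed over the design's rounds, the
#' maximum difference in losses between the high- and low-cost conditions
#' is `sum(n * c_high) - sum(n * c_low)`. For the study design (4 rounds
#' per condition, 10 audience members, costs 1 and 0.5 cents) this is 20
#' cents.
#'
#' @param design Data frame with one row per round: `cost_condition`
#'   (cents per dislike) and optionally `n` (audience size). Defaults to
#'   the study design.
#' @param n Audience size used when `design` lacks an `n` column.
#' @return Difference in worst-case losses, cents.
#' @export
max_cost_exposure_difference <- function(design = NULL, n = 10L) {
  if (is.null(design))
    design <- data.frame(cost_condition = rep(c(0.5, 1), each = 4))
  if (is.null(design$n)) design$n <- n
  costs <- sort(unique(design$cost_condition))
  if (length(costs) == 1) return(0)
  if (length(costs) != 2)
    stop("expected exactly one low- and one high-cost condition",
         call. = FALSE)
  high <- design$cost_condition == costs[2]
  sum(design$n[high] * design$cost_condition[high]) -
    sum(design$n[!high] * design$cost_condition[!high])
}

#' Estimate reception probabilities from first-stage reactions
#'
#' Approximates the reception probabilities of the payoff model from
#' like/dislike data: `R` is the average of the copartisan like rate and
#' the cross-partisan dislike rate of overt tweets (both estimate the same
#' quantity under the model), `r_I` the copartisan like rate of covert
#' tweets, and `r_O` the cross-partisan dislike rate of covert tweets.
#'
#' @param reactions Data frame with one row per rater x tweet: `reaction`
#'   in `{"like", "dislike", "neutral"}`, `tweet_label` in
#'   `{"covert", "overt"}`, `relation` in
#'   `{"copartisan", "cross_partisan"}`.
#' @return List with `R`, `r_I`, `r_O` (empty cells give `NA`), the two
#'   overt components `R_like` and `R_dislike`, and `counts` per cell.
#' @export
reception_rates <- function(reactions) {
  stopifnot(all(c("reaction", "tweet_label", "relation") %in%
                  names(reactions)))
  rate <- function(label, rel, what) {
    i <- reactions$tweet_label == label & reactions$relation == rel
    if (!any(i)) return(NA_real_)
    mean(reactions$reaction[i] == what)
  }
  cnt <- function(label, rel)
    sum(reactions$tweet_label == label & reactions$relation == rel)
  R_like <- rate("overt", "copartisan", "like")
  R_dislike <- rate("overt", "cross_partisan", "dislike")
  list(
    R = mean(c(R_like, R_dislike), na.rm = TRUE),
    r_I = rate("covert", "copartisan", "like"),
    r_O = rate("covert", "cross_partisan", "dislike"),
    R_like = R_like, R_dislike = R_dislike,
    counts = c(overt_co = cnt("overt", "copartisan"),
               overt_cross = cnt("overt", "cross_partisan"),
               covert_co = cnt("covert", "copartisan"),
               covert_cross = cnt("covert", "cross_partisan"))
  )
}

#' Per-condition strategy summaries
#'
#' Summarizes sharing behavior per (arm x outgroup size x cost x political
#' group) cell: mean covert and total counts and the distribution (mean,
#' median, interquartile range) of the covert proportion among rounds in
#' which anything was shared. Zero-share rounds have an undefined covert
#' proportion; they are excluded from the proportion summaries and counted
#' separately.
#'
#' @param rounds Round records (see [generate_experiment_dataset()]).
#' @param participants Participant records; supplies `audience_arm` and
#'   `political_group`.
#' @return Data frame of per-cell summaries.
#' @export
strategy_profile <- function(rounds, participants) {
  d <- merge(rounds,
             participants[, c("participant_id", "audience_arm",
                              "political_group")],
             by = "participant_id")
  d$covert_prop <- ifelse(d$n_total > 0, d$n_covert_shared / d$n_total,
                          NA_real_)
  key <- list(audience_arm = d$audience_arm,
              political_group = d$political_group,
              outgroup_size = d$outgroup_size,
              cost_condition = d$cost_condition)
  agg <- function(x, f) stats::aggregate(x, by = key, FUN = f)[, 5]
  out <- stats::aggregate(d$n_covert_shared, by = key, FUN = mean)
  names(out)[5] <- "mean_covert"
  out$mean_total <- agg(d$n_total, mean)
  out$prop_mean <- agg(d$covert_prop, function(x) mean(x, na.rm = TRUE))
  out$prop_median <- agg(d$covert_prop,
                         function(x) stats::median(x, na.rm = TRUE))
  out$prop_iqr <- agg(d$covert_prop,
                      function(x) stats::IQR(x, na.rm = TRUE))
  out$n_rounds <- agg(d$covert_prop, length)
  out$n_zero_share <- agg(d$covert_prop, function(x) sum(is.na(x)))
  out[order(out$audience_arm, out$political_group, out$outgroup_size,
            out$cost_condition), , drop = FALSE]
}

#' Association between theory-consistent strategy shifts and earnings
#'
#' Scores each participant's strategy adjustment as the least-squares slope
#' of their per-round covert proportion on outgroup size, then correlates
#' the adjustment scores with total earnings across rounds. A positive
#' association indicates that shifting toward covert sharing as the
#' outgroup grows paid off.
#'
#' @param rounds Round records with a `payout` column (cents per round) in
#'   addition to the share counts.
#' @return List with `estimate` (Pearson correlation), `conf_int` (95%),
#'   `p_value`, `n`, and the per-participant `scores` data frame. When the
#'   adjustment scores or earnings are constant the estimate is `NA` with
#'   `reason` set.
#' @export
theory_consistency_score <- function(rounds) {
  stopifnot("payout" %in% names(rounds))
  slope_one <- function(df) {
    df <- df[df$n_total > 0, , drop = FALSE]
    prop <- df$n_covert_shared / df$n_total
    if (nrow(df) < 2 || stats::var(df$outgroup_size) == 0) return(NA_real_)
    stats::coef(stats::lm(prop ~ outgroup_size, data = df))[["outgroup_size"]]
  }
  ids <- unique(rounds$participant_id)
  scores <- data.frame(
    participant_id = ids,
    adjustment = vapply(ids, function(p)
      slope_one(rounds[rounds$participant_id == p, , drop = FALSE]),
      numeric(1)),
    total_payout = vapply(ids, function(p)
      sum(rounds$payout[rounds$participant_id == p]), numeric(1))
  )
  ok <- stats::complete.cases(scores[, c("adjustment", "total_payout")])
  sc <- scores[ok, , drop = FALSE]
  if (nrow(sc) < 3 || stats::var(sc$adjustment) == 0 ||
      stats::var(sc$total_payout) == 0) {
    return(list(estimate = NA_real_, conf_int = c(NA_real_, NA_real_),
                p_value = NA_real_, n = nrow(sc), scores = scores,
                reason = "degenerate variance"))
  }
  ct <- stats::cor.test(sc$adjustment, sc$total_payout)
  list(estimate = unname(ct$estimate), conf_int = as.numeric(ct$conf.int),
       p_value = ct$p.value, n = nrow(sc), scores = scores)
}
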
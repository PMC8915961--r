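#' Rater groups and tweet archetypes used by the synthetic world
#'
#' Raters come from four political-leaning groups; synthetic tweets carry a
#' planted archetype. Tweets are opaque IDs: no text is generated.
#' @name synthetic-vocab
#' @keywords internal
NULL

rater_groups <- c("far_left", "moderate_left", "moderate_right", "far_right")
tweet_archetypes <- c("covert_left", "covert_right", "overt_left",
                      "overt_right", "apolitical")

#' Default perception matrix for synthetic raters
#'
#' For every (rater group, tweet archetype) cell, gives the probability the
#' rater recognizes the tweet as political (`p_recognize`; otherwise they
#' answer "not political"), the location/scale of the 7-point perceived
#' political-orientation response when they do (coded -3..+3, left
#' negative), and the location/scale of the two affective items (higher =
#' more negative/offended).
#'
#' Defaults encode the study's perceptual assumptions: extreme partisans
#' are highly attuned to covert copartisan signals (they recognize and like
#' them), moderates mostly miss them; overt signals are recognized by
#' essentially everyone, liked by copartisans and disliked by
#' cross-partisans; apolitical tweets are rarely judged political by
#' anyone. Right-side archetypes are exact mirrors of left-side ones.
#'
#' @return A data frame with columns `rater_group`, `archetype`,
#'   `p_recognize`, `orientation_mean`, `orientation_sd`, `affect_mean`,
#'   `affect_sd`.
#' @export
default_perception_matrix <- function() {
  # left-side archetypes; right side is generated by mirroring
  left <- rbind(
    data.frame(rater_group = rater_groups, archetype = "covert_left",
               p_recognize      = c(0.95, 0.10, 0.05, 0.35),
               orientation_mean = c(-2.5, 0.0, 0.0, -2.0),
               orientation_sd   = c(0.5, 0.8, 1.0, 0.7),
               affect_mean      = c(-2.2, -0.2, 0.1, 1.0),
               affect_sd        = 0.8),
    data.frame(rater_group = rater_groups, archetype = "overt_left",
               p_recognize      = c(0.98, 0.95, 0.92, 0.97),
               orientation_mean = c(-2.5, -2.2, -2.3, -2.5),
               orientation_sd   = c(0.5, 0.7, 0.7, 0.6),
               affect_mean      = c(-1.8, -1.5, 1.8, 2.3),
               affect_sd        = 0.8)
  )
  mirror_group <- c(far_left = "far_right", moderate_left = "moderate_right",
                    moderate_right = "moderate_left", far_right = "far_left")
  right <- left
  right$archetype <- sub("left", "right", right$archetype)
  right$rater_group <- unname(mirror_group[right$rater_group])
  right$orientation_mean <- -right$orientation_mean
  apolit <- data.frame(rater_group = rater_groups, archetype = "apolitical",
                       p_recognize = 0.05, orientation_mean = 0,
                       orientation_sd = 1.0, affect_mean = 0,
                       affect_sd = 0.8)
  pm <- rbind(left, right, apolit)
  stopifnot(all(pm$p_recognize >= 0 & pm$p_recognize <= 1))
  rownames(pm) <- NULL
  pm
}

#' Configuration for the synthetic rating world
#'
#' @param n_tweets_per_class Number of planted tweets per archetype.
#' @param raters_per_group Size of the rater pool in each of the four
#'   political-leaning groups.
#' @param tweets_per_rater Maximum ratings one rater contributes (the
#'   feasible batch size for a single session).
#' @param raters_per_tweet_per_group Planned ratings per tweet from each
#'   group; must be at least 3 to satisfy the downstream inclusion rule.
#' @param affect_cor Target correlation between the two affective items
#'   (negativity, offensiveness); default 0.70.
#' @param perception Perception matrix, see [default_perception_matrix()].
#' @return A list of class `"rating_config"`.
#' @export
rating_config <- function(n_tweets_per_class = 100,
                          raters_per_group = 60,
                          tweets_per_rater = 50,
                          raters_per_tweet_per_group = 5,
                          affect_cor = 0.70,
                          perception = default_perception_matrix()) {
  stopifnot(n_tweets_per_class >= 0, raters_per_group >= 0,
            tweets_per_rater >= 1, raters_per_tweet_per_group >= 1,
            affect_cor >= -1, affect_cor <= 1)
  structure(list(n_tweets_per_class = as.integer(n_tweets_per_class),
                 raters_per_group = as.integer(raters_per_group),
                 tweets_per_rater = as.integer(tweets_per_rater),
                 raters_per_tweet_per_group =
                   as.integer(raters_per_tweet_per_group),
                 affect_cor = affect_cor,
                 perception = perception),
            class = "rating_config")
}

# two correlated affect items, clipped to the -3..+3 response scale
draw_affect_items <- function(n, mean, sd, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  neg <- pmin(3, pmax(-3, mean + sd * z1))
  off <- pmin(3, pmax(-3, mean + sd * z2))
  list(negativity = neg, offensiveness = off)
}

#' Generate a synthetic rating dataset with planted covert/overt structure
#'
#' Assigns raters to tweets with a balanced incomplete design that
#' guarantees `raters_per_tweet_per_group` ratings per tweet from every
#' group (so the >= 3-raters-per-group inclusion rule always holds), then
#' draws each response from the perception matrix: the rater recognizes the
#' tweet as political with probability `p_recognize` (else answers "not
#' political", recorded as `NA` orientation), orientation responses are
#' rounded Gaussians clipped to -3..+3, and the two affective items are
#' correlated Gaussians (target correlation `affect_cor`) clipped to the
#' same scale.
#'
#' @param config A [rating_config()].
#' @param seed Integer seed; identical config + seed reproduce the dataset
#'   bit for bit.
#' @return A list with `ratings` (data frame: `tweet_id`, `rater_id`,
#'   `rater_group`, `orientation` (integer -3..+3 or `NA` = "not
#'   political"), `negativity`, `offensiveness`) and `truth` (data frame:
#'   `tweet_id`, `archetype`). The seed is recorded as an attribute.
#' @export
generate_rating_dataset <- function(config = rating_config(), seed = 1L) {
  stopifnot(inherits(config, "rating_config"))
  set.seed(seed)
  n_per <- config$n_tweets_per_class
  if (n_per == 0) {
    empty <- data.frame(tweet_id = character(0), rater_id = character(0),
                        rater_group = character(0), orientation = integer(0),
                        negativity = numeric(0), offensiveness = numeric(0))
    return(structure(list(ratings = empty,
                          truth = data.frame(tweet_id = character(0),
                                             archetype = character(0))),
                     seed = seed))
  }
  truth <- data.frame(
    tweet_id = sprintf("t%04d", seq_len(n_per * length(tweet_archetypes))),
    archetype = rep(tweet_archetypes, each = n_per),
    stringsAsFactors = FALSE
  )
  n_tweets <- nrow(truth)
  k <- config$raters_per_tweet_per_group
  n_raters <- config$raters_per_group
  if (n_raters < k)
    stop(sprintf("rater pool too small: need at least %d raters per group, have %d",
                 k, n_raters), call. = FALSE)
  load_per_rater <- ceiling(n_tweets * k / n_raters)
  if (load_per_rater > config$tweets_per_rater)
    stop(sprintf(paste("rater pool too small: coverage requires %d ratings",
                       "per rater but the batch cap is %d"),
                 load_per_rater, config$tweets_per_rater), call. = FALSE)

  # balanced design: copy j of tweet i goes to rater ((i - 1 + j - 1) mod
  # n_raters) + 1; distinct offsets mod n_raters, so no rater sees a tweet
  # twice
  idx <- expand.grid(tweet = seq_len(n_tweets), copy = seq_len(k))
  rater_idx <- ((idx$tweet - 1 + idx$copy - 1) %% n_raters) + 1

  pm <- config$perception
  out <- vector("list", length(rater_groups))
  for (gi in seq_along(rater_groups)) {
    g <- rater_groups[gi]
    df <- data.frame(
      tweet_id = truth$tweet_id[idx$tweet],
      rater_id = sprintf("%s_r%03d", g, rater_idx),
      rater_group = g,
      archetype = truth$archetype[idx$tweet],
      stringsAsFactors = FALSE
    )
    key <- match(paste(g, df$archetype), paste(pm$rater_group, pm$archetype))
    stopifnot(!anyNA(key))
    p <- pm$p_recognize[key]
    recognized <- stats::runif(nrow(df)) < p
    orientation <- rep(NA_integer_, nrow(df))
    orientation[recognized] <- as.integer(pmin(3, pmax(-3, round(
      stats::rnorm(sum(recognized),
                   pm$orientation_mean[key][recognized],
                   pm$orientation_sd[key][recognized])))))
    aff <- draw_affect_items(nrow(df), pm$affect_mean[key],
                             pm$affect_sd[key], config$affect_cor)
    df$orientation <- orientation
    df$negativity <- aff$negativity
    df$offensiveness <- aff$offensiveness
    df$archetype <- NULL
    out[[gi]] <- df
  }
  ratings <- do.call(rbind, out)
  rownames(ratings) <- NULL
  structure(list(ratings = ratings, truth = truth), seed = seed)
}

#' Mirror a rating dataset left <-> right
#'
#' Negates every orientation response and swaps the rater groups across the
#' left/right divide (far_left <-> far_right, moderate_left <->
#' moderate_right). Used to check that the classification criteria treat
#' the two sides symmetrically.
#'
#' @param ratings A rating record data frame.
#' @return The mirrored data frame.
#' @export
mirror_ratings <- function(ratings) {
  swap <- c(far_left = "far_right", moderate_left = "moderate_right",
            moderate_right = "moderate_left", far_right = "far_left")
  ratings$rater_group <- unname(swap[ratings$rater_group])
  ratings$orientation <- -ratings$orientation
  ratings
}

#' Configuration for synthetic follower worlds
#'
#' Plants three kinds of engaged seed accounts: `homogeneous` seeds whose
#' followers are mostly engaged with copartisan news, `heterogeneous` seeds
#' whose followers are mostly disengaged, and middling seeds in between.
#' The planted fractions default to 20%/20%/60% so that the top-20%
#' rankings used downstream align with the planted classes.
#'
#' @param n_seeds_per_side Engaged seed accounts per political side.
#' @param followers_per_seed Followers drawn for each seed.
#' @param frac_homogeneous,frac_heterogeneous Planted fractions of seeds.
#' @param mix_homogeneous,mix_heterogeneous,mix_middle Length-3 probability
#'   vectors (engaged, disengaged, neither) for followers of each seed
#'   class.
#' @return A list of class `"network_config"`.
#' @export
network_config <- function(n_seeds_per_side = 40,
                           followers_per_seed = 30,
                           frac_homogeneous = 0.2,
                           frac_heterogeneous = 0.2,
                           mix_homogeneous = c(0.75, 0.15, 0.10),
                           mix_heterogeneous = c(0.10, 0.75, 0.15),
                           mix_middle = c(0.42, 0.42, 0.16)) {
  for (m in list(mix_homogeneous, mix_heterogeneous, mix_middle)) {
    if (length(m) != 3 || any(m < 0) || any(m > 1) ||
        abs(sum(m) - 1) > 1e-8)
      stop("follower mixes must be length-3 probability vectors summing to 1",
           call. = FALSE)
  }
  if (frac_homogeneous < 0 || frac_heterogeneous < 0 ||
      frac_homogeneous + frac_heterogeneous > 1)
    stop("planted fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  structure(list(n_seeds_per_side = as.integer(n_seeds_per_side),
                 followers_per_seed = as.integer(followers_per_seed),
                 frac_homogeneous = frac_homogeneous,
                 frac_heterogeneous = frac_heterogeneous,
                 mix_homogeneous = mix_homogeneous,
                 mix_heterogeneous = mix_heterogeneous,
                 mix_middle = mix_middle),
            class = "network_config")
}

# news-follow counts by engagement class; thresholds are 3 (left) / 4
# (right) for engaged, <= 1 total for disengaged
draw_news_counts <- function(class, side) {
  eng_min <- if (side == "left") 3L else 4L
  own <- switch(class,
                engaged = eng_min + stats::rpois(1, 2),
                disengaged = stats::rbinom(1, 1, 0.5),
                neither = 2L)
  other <- stats::rbinom(1, 1, 0.05)
  list_size <- c(left = 43L, right = 50L)
  own <- min(own, list_size[[side]])
  if (side == "left") c(left = own, right = other) else c(left = other, right = own)
}

#' Generate a synthetic follower world with planted network types
#'
#' Builds engaged seed accounts on both political sides and their
#' followers. Followers of planted `homogeneous` seeds are mostly engaged
#' (follow at least the engagement threshold of copartisan news accounts);
#' followers of planted `heterogeneous` seeds are mostly disengaged (follow
#' at most one). The remaining seeds get an intermediate mix.
#'
#' @param config A [network_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `"follower_world"`: list with `accounts`
#'   (data frame: `account_id`, `side`, `followed_left_news`,
#'   `followed_right_news`, `role`), `edges` (data frame: `seed_id`,
#'   `follower_id`), `news_list_sizes` (left 43, right 50), and `truth`
#'   (data frame: `seed_id`, `side`, `planted_type`).
#' @export
generate_follower_world <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  accounts <- list(); edges <- list(); truth <- list()
  fid <- 0L
  for (side in c("left", "right")) {
    n_seed <- config$n_seeds_per_side
    n_hom <- round(config$frac_homogeneous * n_seed)
    n_het <- round(config$frac_heterogeneous * n_seed)
    types <- c(rep("homogeneous", n_hom), rep("heterogeneous", n_het),
               rep("middle", n_seed - n_hom - n_het))
    types <- sample(types)
    for (i in seq_len(n_seed)) {
      sid <- sprintf("seed_%s_%03d", side, i)
      cnt <- draw_news_counts("engaged", side)
      accounts[[length(accounts) + 1L]] <-
        data.frame(account_id = sid, side = side,
                   followed_left_news = cnt[["left"]],
                   followed_right_news = cnt[["right"]], role = "seed")
      truth[[length(truth) + 1L]] <-
        data.frame(seed_id = sid, side = side, planted_type = types[i])
      mix <- switch(types[i],
                    homogeneous = config$mix_homogeneous,
                    heterogeneous = config$mix_heterogeneous,
                    middle = config$mix_middle)
      classes <- sample(c("engaged", "disengaged", "neither"),
                        config$followers_per_seed, replace = TRUE, prob = mix)
      for (cl in classes) {
        fid <- fid + 1L
        aid <- sprintf("fol_%06d", fid)
        cnt <- draw_news_counts(cl, side)
        accounts[[length(accounts) + 1L]] <-
          data.frame(account_id = aid, side = side,
                     followed_left_news = cnt[["left"]],
                     followed_right_news = cnt[["right"]], role = "follower")
        edges[[length(edges) + 1L]] <-
          data.frame(seed_id = sid, follower_id = aid)
      }
    }
  }
  structure(list(accounts = do.call(rbind, accounts),
                 edges = do.call(rbind, edges),
                 news_list_sizes = c(left = 43L, right = 50L),
                 truth = do.call(rbind, truth)),
            class = "follower_world", seed = seed)
}

#' Configuration for the synthetic behavioral experiment
#'
#' Plants a mixed-effects Poisson data-generating process for the counts of
#' covert and overt tweets shared per round. Each participant plays 8
#' rounds crossing outgroup size (1, 4, 6, 9 of an audience of 10) with
#' dislike cost (0.5 or 1 cent); the audience arm (copartisan vs.
#' cross-partisan) is between-subject. Planted effects are expressed as
#' marginal mean counts (random intercepts integrated out): the covert
#' margin at outgroup size s equals
#' `covert_margin_out1 * covert_out_mult[s]` in the cross-partisan arm,
#' flat in the copartisan arm. Defaults give marginal covert means 2.00 at
#' outgroup 1 rising to 2.73 at outgroup 9 (a planted covert effect of
#' +0.73 tweets) and total means falling from 12.0 to 6.62 (a planted
#' total effect of -5.38), echoing the calibrated study conditions.
#'
#' Demographic covariates (age, gender, race, education, political group)
#' are generated and carried through so model adjustment is exercised;
#' their planted effects default to zero.
#'
#' @param n_participants Participants overall (split equally across arms).
#' @param sigma_u SD of the participant-level Gaussian random intercept on
#'   the log scale.
#' @param covert_margin_out1,overt_margin_out1 Marginal mean counts at
#'   outgroup size 1 (cross-partisan arm).
#' @param covert_out_mult,overt_out_mult Named multipliers over outgroup
#'   sizes 1, 4, 6, 9 applied in the cross-partisan arm.
#' @param cost_mult_covert,cost_mult_overt Multiplier applied in high-cost
#'   rounds (1 = no planted cost effect, as observed).
#' @param covert_cap,total_cap Menu caps: at most 20 covert and 40 total
#'   tweets can be shared per round; counts are clipped and the truncation
#'   rate recorded.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_participants = 480,
                              sigma_u = 0.3,
                              covert_margin_out1 = 2.0,
                              overt_margin_out1 = 10.0,
                              covert_out_mult = c(`1` = 1, `4` = 1.15,
                                                  `6` = 1.27, `9` = 1.365),
                              overt_out_mult = c(`1` = 1, `4` = 0.75,
                                                 `6` = 0.55, `9` = 0.389),
                              cost_mult_covert = 1.0,
                              cost_mult_overt = 1.0,
                              covert_cap = 20L,
                              total_cap = 40L) {
  stopifnot(n_participants >= 0, sigma_u >= 0,
            length(covert_out_mult) == 4, length(overt_out_mult) == 4)
  structure(list(n_participants = as.integer(n_participants),
                 sigma_u = sigma_u,
                 covert_margin_out1 = covert_margin_out1,
                 overt_margin_out1 = overt_margin_out1,
                 covert_out_mult = covert_out_mult,
                 overt_out_mult = overt_out_mult,
                 cost_mult_covert = cost_mult_covert,
                 cost_mult_overt = cost_mult_overt,
                 covert_cap = as.integer(covert_cap),
                 total_cap = as.integer(total_cap)),
            class = "experiment_config")
}

#' Planted marginal cell means of the synthetic experiment
#'
#' Returns the marginal (random effects integrated out) mean covert, overt
#' and total counts the generator plants in each outgroup-size cell of each
#' arm, before menu-cap truncation. The planted covert AME between two
#' outgroup sizes is the difference of the covert columns.
#'
#' @param config An [experiment_config()].
#' @return Data frame with columns `audience_arm`, `outgroup_size`,
#'   `covert`, `overt`, `total`.
#' @export
experiment_planted_margins <- function(config = experiment_config()) {
  sizes <- c(1L, 4L, 6L, 9L)
  rows <- list()
  for (arm in c("copartisan", "cross_partisan")) {
    cmult <- if (arm == "cross_partisan") config$covert_out_mult else rep(1, 4)
    omult <- if (arm == "cross_partisan") config$overt_out_mult else rep(1, 4)
    rows[[arm]] <- data.frame(
      audience_arm = arm, outgroup_size = sizes,
      covert = config$covert_margin_out1 * as.numeric(cmult),
      overt = config$overt_margin_out1 * as.numeric(omult))
  }
  out <- do.call(rbind, rows)
  out$total <- out$covert + out$overt
  rownames(out) <- NULL
  out
}

#' Generate a synthetic behavioral-experiment dataset
#'
#' Draws participants (with demographics and a political group), assigns
#' each to an audience arm, and simulates the 8 within-subject rounds
#' (outgroup size 1/4/6/9 crossed with dislike cost 0.5/1 cent, in random
#' order). Counts of covert and overt tweets shared are Poisson draws from
#' the planted mixed model of [experiment_config()], sharing one Gaussian
#' random intercept per participant, then clipped to the menu caps (20
#' covert, 40 total) with the truncation rate recorded.
#'
#' @param config An [experiment_config()].
#' @param seed Integer RNG seed.
#' @return List with `participants`, `rounds` data frames and a `truth`
#'   list (planted margins, `sigma_u`, truncation rate). Rounds carry
#'   `participant_id`, `round`, `outgroup_size`, `cost_condition` (cents
#'   per dislike), `n_covert_shared`, `n_overt_shared`, `n_total`.
#' @export
generate_experiment_dataset <- function(config = experiment_config(),
                                        seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  n <- config$n_participants
  if (n == 0) {
    return(structure(list(
      participants = data.frame(participant_id = character(0)),
      rounds = data.frame(participant_id = character(0)),
      truth = list(margins = experiment_planted_margins(config),
                   sigma_u = config$sigma_u, truncation_rate = NA_real_)),
      seed = seed))
  }
  groups <- c("far_left", "mainstream_left", "mainstream_right", "far_right")
  participants <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    audience_arm = rep(c("copartisan", "cross_partisan"), length.out = n),
    political_group = sample(groups, n, replace = TRUE),
    age = sample(18:80, n, replace = TRUE),
    gender = sample(c("woman", "man", "other"), n, replace = TRUE,
                    prob = c(0.48, 0.48, 0.04)),
    race = sample(c("white", "black", "asian", "hispanic", "other"), n,
                  replace = TRUE, prob = c(0.6, 0.13, 0.07, 0.15, 0.05)),
    education = sample(c("hs_or_less", "some_college", "college", "graduate"),
                       n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  sizes <- c(1L, 4L, 6L, 9L)
  costs <- c(0.5, 1)
  design <- expand.grid(outgroup_size = sizes, cost_condition = costs)
  # planted log-scale intercepts so that marginal means (with the
  # lognormal correction exp(sigma_u^2 / 2)) equal the configured margins
  adj <- config$sigma_u^2 / 2
  u <- stats::rnorm(n, 0, config$sigma_u)
  rounds <- vector("list", n)
  margins <- experiment_planted_margins(config)
  for (i in seq_len(n)) {
    arm <- participants$audience_arm[i]
    ord <- sample(nrow(design))
    cells <- design[ord, , drop = FALSE]
    m <- margins[margins$audience_arm == arm, ]
    mu_c <- m$covert[match(cells$outgroup_size, m$outgroup_size)]
    mu_o <- m$overt[match(cells$outgroup_size, m$outgroup_size)]
    high <- cells$cost_condition == 1
    mu_c <- mu_c * ifelse(high, config$cost_mult_covert, 1)
    mu_o <- mu_o * ifelse(high, config$cost_mult_overt, 1)
    lam_c <- exp(log(mu_c) - adj + u[i])
    lam_o <- exp(log(mu_o) - adj + u[i])
    n_cov <- stats::rpois(nrow(cells), lam_c)
    n_ov <- stats::rpois(nrow(cells), lam_o)
    rounds[[i]] <- data.frame(
      participant_id = participants$participant_id[i],
      round = seq_len(nrow(cells)),
      outgroup_size = cells$outgroup_size,
      cost_condition = cells$cost_condition,
      n_covert_raw = n_cov, n_overt_raw = n_ov)
  }
  rounds <- do.call(rbind, rounds)
  rownames(rounds) <- NULL
  cov_clip <- pmin(rounds$n_covert_raw, config$covert_cap)
  ov_cap <- pmin(config$covert_cap, config$total_cap - cov_clip)
  ov_clip <- pmin(rounds$n_overt_raw, ov_cap)
  truncated <- (cov_clip != rounds$n_covert_raw) |
    (ov_clip != rounds$n_overt_raw)
  trunc_rate <- mean(truncated)
  if (trunc_rate > 0.05)
    warning(sprintf(paste("planted means press against the menu caps:",
                          "%.1f%% of rounds truncated"), 100 * trunc_rate),
            call. = FALSE)
  rounds$n_covert_shared <- cov_clip
  rounds$n_overt_shared <- ov_clip
  rounds$n_total <- cov_clip + ov_clip
  rounds$n_covert_raw <- NULL
  rounds$n_overt_raw <- NULL
  structure(list(participants = participants, rounds = rounds,
                 truth = list(margins = margins, sigma_u = config$sigma_u,
                              truncation_rate = trunc_rate)),
            seed = seed)
}

#' Simulate per-member audience reactions to a round's shared tweets
#'
#' Each of the `n` audience members reacts to every shared tweet under the
#' reception model: ingroup members perceive similarity with probability
#' `R` (overt tweet) or `r_I` (covert) and then like it; outgroup members
#' perceive dissimilarity with probability `R` (overt) or `r_O` (covert)
#' and then dislike it; otherwise the reaction is neutral.
#'
#' @param shared Data frame of the round's shared tweets with columns
#'   `tweet_id` and `label` (`"covert"` or `"overt"`).
#' @param env A [signaling_env()] supplying `n`, `d` (via the outgroup
#'   count), `R`, `r_I`, `r_O`.
#' @param seed Optional integer seed.
#' @return Data frame with one row per member x tweet: `member_id`,
#'   `is_outgroup`, `tweet_id`, `label`, `reaction` in
#'   `{"like", "dislike", "neutral"}`.
#' @export
generate_audience_responses <- function(shared, env, seed = NULL) {
  env <- as_signaling_env(env)
  if (nrow(shared) > 0 &&
      (!"label" %in% names(shared) || anyNA(shared$label) ||
       !all(shared$label %in% c("covert", "overt"))))
    stop("every shared tweet must be labeled \"covert\" or \"overt\"",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_out <- as.integer(round(env$d * env$n))
  members <- data.frame(member_id = sprintf("m%02d", seq_len(env$n)),
                        is_outgroup = c(rep(FALSE, env$n - n_out),
                                        rep(TRUE, n_out)))
  if (nrow(shared) == 0) {
    return(cbind(members[0, ], data.frame(tweet_id = character(0),
                                          label = character(0),
                                          reaction = character(0))))
  }
  grid <- merge(members, shared[, c("tweet_id", "label")], by = NULL)
  p <- ifelse(grid$label == "overt", env$R,
              ifelse(grid$is_outgroup, env$r_O, env$r_I))
  received <- stats::runif(nrow(grid)) < p
  grid$reaction <- ifelse(!received, "neutral",
                          ifelse(grid$is_outgroup, "dislike", "like"))
  grid[order(grid$member_id, grid$tweet_id), , drop = FALSE]
}
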
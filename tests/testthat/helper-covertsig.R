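# shared fixtures built in code

fig4_env <- function(d = 0.5, c = 1, w0 = 0) {
  signaling_env(n = 10, d = d, R = 0.8, r_I = 0.6, r_O = 0.5,
                b = 1, c = c, w0 = w0)
}

# independent oracle: expected payoff by per-member summation
payoff_by_member_sum <- function(env, strategy) {
  n_out <- env$d * env$n
  n_in <- env$n - n_out
  if (strategy == "overt") {
    env$w0 + n_in * env$R * env$b - n_out * env$R * env$c
  } else {
    env$w0 + n_in * env$r_I * env$b - n_out * env$r_O * env$c
  }
}

# one rating record
rec <- function(tweet, rater, group, orientation, neg = 0, off = 0) {
  data.frame(tweet_id = tweet, rater_id = rater, rater_group = group,
             orientation = orientation, negativity = neg,
             offensiveness = off, stringsAsFactors = FALSE)
}

# a minimal complete rating set: `per_group` raters per group for one tweet
tweet_ratings <- function(tweet, orientation_by_group, affect_by_group,
                          per_group = 3) {
  out <- list()
  for (g in names(orientation_by_group)) {
    for (i in seq_len(per_group)) {
      out[[length(out) + 1]] <- rec(tweet, sprintf("%s_%d", g, i), g,
                                    orientation_by_group[[g]],
                                    affect_by_group[[g]],
                                    affect_by_group[[g]])
    }
  }
  do.call(rbind, out)
}

# small follower world built by hand: one seed per type per side
tiny_world <- function() {
  accounts <- data.frame(
    account_id = c("seed_left_hom", "seed_left_het",
                   "f01", "f02", "f03", "f04"),
    side = "left",
    followed_left_news = c(5L, 5L, 4L, 6L, 0L, 1L),
    followed_right_news = 0L,
    role = c("seed", "seed", "follower", "follower", "follower", "follower"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    seed_id = c("seed_left_hom", "seed_left_hom",
                "seed_left_het", "seed_left_het"),
    follower_id = c("f01", "f02", "f03", "f04"),
    stringsAsFactors = FALSE
  )
  list(accounts = accounts, edges = edges,
       news_list_sizes = c(left = 43L, right = 50L))
}

# tweet table exercising every filter rule
filter_fixture <- function(ref_time) {
  ref <- as.numeric(ref_time)
  long <- paste(rep("word", 12), collapse = " ")
  linked <- paste(paste(rep("token", 12), collapse = " "),
                  "https://example.org/x")
  data.frame(
    tweet_id = sprintf("tw%02d", 1:9),
    created_at = ref - c(1e5, 1e5, 1e5, 1e5, 1e5, 1e7, 1e5, 1e5, 1e5),
    is_reply = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE),
    has_image = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE),
    has_news_link = FALSE,
    lang = c("en", "en", "en", "fr", "en", "en", "en", "en", "en"),
    is_retweet = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                   FALSE),
    text = c(long, long, long, long, "short #tagged", long, long,
             "tiny one", linked),
    stringsAsFactors = FALSE
  )
}
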
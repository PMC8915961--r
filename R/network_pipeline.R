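#' Classify an account's political side from its media diet
#'
#' The side of an account is inferred from the proportion of curated
#' far-left (43 accounts) and far-right (50 accounts) news sources it
#' follows: the side with the larger followed proportion wins; equal
#' nonzero proportions (or following neither list) yield `"none"` with a
#' tie flag.
#'
#' @param followed_left,followed_right Counts of followed accounts from the
#'   left and right news lists (vectorized).
#' @param news_list_sizes Named sizes of the curated lists, default
#'   `c(left = 43, right = 50)`.
#' @return Data frame with `side` (`"left"`, `"right"`, `"none"`),
#'   `prop_left`, `prop_right`, `tie` (logical).
#' @export
media_diet_side <- function(followed_left, followed_right,
                            news_list_sizes = c(left = 43L, right = 50L)) {
  if (any(news_list_sizes <= 0)) stop("news lists must be non-empty",
                                      call. = FALSE)
  if (any(followed_left < 0) || any(followed_right < 0) ||
      any(followed_left > news_list_sizes[["left"]]) ||
      any(followed_right > news_list_sizes[["right"]]))
    stop("followed counts must lie between 0 and the list size",
         call. = FALSE)
  pl <- followed_left / news_list_sizes[["left"]]
  pr <- followed_right / news_list_sizes[["right"]]
  tie <- pl == pr
  side <- ifelse(tie, "none", ifelse(pl > pr, "left", "right"))
  data.frame(side = side, prop_left = pl, prop_right = pr, tie = tie,
             stringsAsFactors = FALSE)
}

#' Label an account's engagement with copartisan news
#'
#' An account on a given side is `engaged` if it follows at least the
#' side's engagement threshold of copartisan news accounts (the 50th
#' percentile of the seed pool: 3 for the left, 4 for the right),
#' `disengaged` if it follows at most one far-left/right news site in
#' total, and `neither` otherwise. Accounts without a side can only be
#' `disengaged` or `neither`.
#'
#' @param followed_left,followed_right Followed counts per list.
#' @param side Side from [media_diet_side()] (vectorized).
#' @param engaged_min Named engagement thresholds,
#'   default `c(left = 3, right = 4)`.
#' @param disengaged_max Maximum total news follows for `disengaged`
#'   (default 1).
#' @return Character vector in `{"engaged", "disengaged", "neither"}`.
#' @export
engagement_label <- function(followed_left, followed_right, side,
                             engaged_min = c(left = 3L, right = 4L),
                             disengaged_max = 1L) {
  total <- followed_left + followed_right
  own <- ifelse(side == "left", followed_left,
                ifelse(side == "right", followed_right, 0L))
  thr <- ifelse(side == "left", engaged_min[["left"]],
                ifelse(side == "right", engaged_min[["right"]], Inf))
  ifelse(total <= disengaged_max, "disengaged",
         ifelse(own >= thr, "engaged", "neither"))
}

#' Select the top fraction of accounts by a score
#'
#' Returns the `ceiling(fraction * N)` highest-scoring IDs, breaking ties
#' deterministically by ID (lower first). Warns when a tie straddles the
#' selection boundary.
#'
#' @param ids Character vector of account IDs.
#' @param scores Numeric scores, same length.
#' @param fraction Fraction to keep, in `(0, 1]`.
#' @return Character vector of selected IDs.
#' @export
select_top_fraction <- function(ids, scores, fraction = 0.2) {
  stopifnot(length(ids) == length(scores))
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  if (length(ids) == 0) return(character(0))
  ord <- order(-scores, ids)
  k <- ceiling(fraction * length(ids))
  if (k < length(ids) && scores[ord[k]] == scores[ord[k + 1]])
    warning("tied scores at the selection boundary; ties broken by ID",
            call. = FALSE)
  ids[ord[seq_len(k)]]
}

#' Classify seed accounts as having homogeneous or heterogeneous networks
#'
#' Labels every follower in the world as engaged/disengaged/neither via
#' [engagement_label()], computes each seed's proportion of engaged and of
#' disengaged followers, and, per side, labels the top `fraction` of seeds
#' by engaged-follower proportion `homogeneous` and the top `fraction` by
#' disengaged-follower proportion `heterogeneous`. Seeds appearing in both
#' top sets become `neither` with a conflict flag; seeds without followers
#' are `neither` with a warning.
#'
#' @param world A `follower_world` (see [generate_follower_world()]) or a
#'   list with `accounts` and `edges` in the same layout.
#' @param fraction Top fraction used for both rankings (default 0.2).
#' @return Data frame with one row per seed: `seed_id`, `side`,
#'   `prop_engaged`, `prop_disengaged`, `n_followers`, `network_type`
#'   (`"homogeneous"`, `"heterogeneous"`, `"neither"`), `conflict`.
#' @export
classify_seed_network <- function(world, fraction = 0.2) {
  acc <- world$accounts
  edges <- world$edges
  list_sizes <- world$news_list_sizes
  if (is.null(list_sizes)) list_sizes <- c(left = 43L, right = 50L)
  md <- media_diet_side(acc$followed_left_news, acc$followed_right_news,
                        list_sizes)
  eng <- engagement_label(acc$followed_left_news, acc$followed_right_news,
                          md$side)
  names(eng) <- acc$account_id
  seeds <- acc[acc$role == "seed", , drop = FALSE]
  f_eng <- eng[edges$follower_id]
  prop <- function(seed_id, what) {
    e <- f_eng[edges$seed_id == seed_id]
    if (length(e) == 0) return(NA_real_)
    mean(e == what)
  }
  res <- data.frame(
    seed_id = seeds$account_id,
    side = md$side[match(seeds$account_id, acc$account_id)],
    prop_engaged = vapply(seeds$account_id, prop, numeric(1), "engaged"),
    prop_disengaged = vapply(seeds$account_id, prop, numeric(1),
                             "disengaged"),
    stringsAsFactors = FALSE
  )
  res$n_followers <- vapply(res$seed_id,
                            function(s) sum(edges$seed_id == s), integer(1))
  if (any(res$n_followers == 0))
    warning(sprintf("%d seed(s) have no followers and are labeled neither",
                    sum(res$n_followers == 0)), call. = FALSE)
  res$network_type <- "neither"
  res$conflict <- FALSE
  for (side in unique(res$side)) {
    i <- which(res$side == side & res$n_followers > 0)
    if (length(i) == 0) next
    hom <- select_top_fraction(res$seed_id[i], res$prop_engaged[i], fraction)
    het <- select_top_fraction(res$seed_id[i], res$prop_disengaged[i],
                               fraction)
    conflict <- intersect(hom, het)
    res$network_type[res$seed_id %in% hom] <- "homogeneous"
    res$network_type[res$seed_id %in% het] <- "heterogeneous"
    res$network_type[res$seed_id %in% conflict] <- "neither"
    res$conflict[res$seed_id %in% conflict] <- TRUE
  }
  rownames(res) <- NULL
  res
}

strip_links <- function(text) {
  trimws(gsub("\\s+", " ", gsub("https?://\\S+", "", text)))
}

count_words <- function(text) {
  lengths(regmatches(text, gregexpr("\\S+", text)))
}

has_hashtag <- function(text) {
  grepl("(^|\\s)#\\S", text)
}

#' Filter tweets for ratability
#'
#' Applies, in order, the ratability rules used before human rating:
#' drop tweets older than `max_age_weeks` (42 days by default, in UTC
#' seconds), replies, tweets with images or news-article links, non-English
#' tweets, and tweets that are too short (fewer than `min_words` words OR
#' fewer than `min_chars` characters, both measured on link-stripped text,
#' waived when the tweet contains a hashtag); strips remaining links from
#' the kept text; then removes retweets and exact-text duplicates. Records
#' missing a required field are rejected as malformed. The function is
#' idempotent and its per-rule tallies do not depend on input order.
#'
#' @param tweets Data frame with `tweet_id`, `created_at` (POSIXct or
#'   seconds since epoch), `is_reply`, `has_image`, `has_news_link`,
#'   `lang`, `is_retweet`, `text`.
#' @param reference_time Time the collection is anchored to (POSIXct or
#'   seconds).
#' @param max_age_weeks Maximum age, default 6 (42 x 86400 seconds).
#' @param min_words,min_chars Length rule: a tweet is removed if it has
#'   fewer than `min_words` words or fewer than `min_chars` characters,
#'   unless it contains a hashtag.
#' @return List with `kept` (filtered data frame, links stripped, ordered
#'   by `tweet_id`) and `tally` (named integer vector of removals per
#'   rule).
#' @export
filter_tweets <- function(tweets, reference_time, max_age_weeks = 6,
                          min_words = 5L, min_chars = 50L) {
  required <- c("tweet_id", "created_at", "is_reply", "has_image",
                "has_news_link", "lang", "is_retweet", "text")
  miss_col <- setdiff(required, names(tweets))
  if (length(miss_col) > 0)
    stop("tweet table lacks column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  tweets <- tweets[order(tweets$tweet_id), , drop = FALSE]
  tally <- c(malformed = 0L, too_old = 0L, reply = 0L, media_or_news = 0L,
             language = 0L, too_short = 0L, retweet_or_duplicate = 0L)
  malformed <- !stats::complete.cases(tweets[required])
  tally["malformed"] <- sum(malformed)
  tweets <- tweets[!malformed, , drop = FALSE]

  age <- as.numeric(reference_time) - as.numeric(tweets$created_at)
  keep <- age <= max_age_weeks * 7 * 86400 & age >= 0
  tally["too_old"] <- sum(!keep)
  tweets <- tweets[keep, , drop = FALSE]

  tally["reply"] <- sum(tweets$is_reply)
  tweets <- tweets[!tweets$is_reply, , drop = FALSE]

  media <- tweets$has_image | tweets$has_news_link
  tally["media_or_news"] <- sum(media)
  tweets <- tweets[!media, , drop = FALSE]

  non_en <- tweets$lang != "en"
  tally["language"] <- sum(non_en)
  tweets <- tweets[!non_en, , drop = FALSE]

  stripped <- strip_links(tweets$text)
  short <- (count_words(stripped) < min_words | nchar(stripped) < min_chars) &
    !has_hashtag(stripped)
  tally["too_short"] <- sum(short)
  tweets <- tweets[!short, , drop = FALSE]
  tweets$text <- strip_links(tweets$text)

  dup <- tweets$is_retweet | duplicated(tweets$text)
  tally["retweet_or_duplicate"] <- sum(dup)
  tweets <- tweets[!dup, , drop = FALSE]

  rownames(tweets) <- NULL
  list(kept = tweets, tally = tally)
}
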
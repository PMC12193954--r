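#' Flag a corpus for PD-relatedness
#'
#' Combines the three flagging routes on every post: (1) the dictionary gate
#' plus the trained classifier (the classifier is only consulted for posts
#' with at least one dictionary hit); (2) the explicit "parkinson" substring
#' rule; (3) the standalone "PD" abbreviation rule. The final verdict is
#' their union: `pd_related = (dict_hit AND classifier positive) OR
#' parkinson_mention OR pd_abbrev`. A post is `exercise_only` when its
#' PD-relatedness rests solely on exercise-tagged dictionary matches and it
#' has no explicit mention.
#'
#' @param posts post data.frame (`post_id`, `participant_id`, `timestamp`,
#'   `text`).
#' @param dict a `term_dictionary`.
#' @param model a fitted [fit_pd_classifier()] (or a single fitted candidate
#'   plus `space`).
#' @param participants participant table (needed for classifier features).
#' @param threshold classifier threshold (default 0.5, boundary positive).
#' @return data.frame of flag results, one row per post: `post_id`,
#'   `dict_hit`, `n_terms`, `classifier_prob` (NA when no dictionary hit),
#'   `parkinson_mention`, `pd_abbrev`, `pd_related`, `exercise_only`.
#' @export
flag_corpus <- function(posts, dict, model, participants, threshold = 0.5) {
  if (!inherits(model, "pd_classifier")) stop("model must be a fitted pd_classifier")
  dflag <- dictionary_flag_corpus(posts$text, dict)
  expl <- explicit_mention(posts$text)
  prob <- rep(NA_real_, nrow(posts))
  if (any(dflag$hit)) {
    hit_posts <- posts[dflag$hit, , drop = FALSE]
    pr <- predict(model, hit_posts, participants, threshold = threshold)
    prob[dflag$hit] <- pr$probability
  }
  clf_pos <- !is.na(prob) & prob >= threshold
  pd_related <- clf_pos | expl$parkinson | expl$pd_abbrev
  only_exercise_terms <- vapply(dflag$tags, function(tg)
    length(tg) > 0L && all(tg == "exercise"), logical(1))
  exercise_only <- pd_related & only_exercise_terms &
    !expl$parkinson & !expl$pd_abbrev
  data.frame(post_id = posts$post_id, participant_id = posts$participant_id,
             dict_hit = dflag$hit, n_terms = dflag$n_terms,
             classifier_prob = prob,
             parkinson_mention = expl$parkinson, pd_abbrev = expl$pd_abbrev,
             pd_related = pd_related, exercise_only = exercise_only,
             stringsAsFactors = FALSE)
}

#' Per-participant flag summary
#'
#' Counts per participant (total, PD-related, explicit-mention and
#' exercise-only posts) and cohort shares of participants with at least one
#' flagged / explicit post. Participants with zero posts are excluded from
#' the cohort shares.
#'
#' @param results flag data.frame from [flag_corpus()].
#' @param participants participant table.
#' @return list with `per_participant` (data.frame) and `cohort` (named
#'   numeric: `share_any_flagged`, `share_any_explicit`, `n_active`).
#' @export
summarize_flags <- function(results, participants) {
  ids <- participants$id
  per <- data.frame(
    participant_id = ids,
    n_posts = as.integer(table(factor(results$participant_id, levels = ids))),
    stringsAsFactors = FALSE)
  agg <- function(v) {
    s <- tapply(v, factor(results$participant_id, levels = ids), sum)
    as.integer(ifelse(is.na(s), 0L, s))
  }
  per$n_pd_related <- agg(results$pd_related)
  per$n_explicit <- agg(results$parkinson_mention | results$pd_abbrev)
  per$n_exercise_only <- agg(results$exercise_only)
  active <- per$n_posts > 0L
  cohort <- c(
    share_any_flagged = mean(per$n_pd_related[active] > 0L),
    share_any_explicit = mean(per$n_explicit[active] > 0L),
    n_active = sum(active))
  list(per_participant = per, cohort = cohort)
}
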
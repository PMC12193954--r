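#' Assign a diagnosis phase to posts
#'
#' A post is `pre` when its (UTC) calendar date falls strictly before the
#' diagnosis date, `post` on or after it (diagnosis-day posts count as
#' post-diagnosis), and `unknown` when the participant has no diagnosis date.
#'
#' @param timestamps epoch seconds (UTC).
#' @param diagnosis_date a `Date` (or ISO string / year-only string), possibly
#'   NA.
#' @return character vector in `{"pre", "post", "unknown"}`.
#' @export
assign_phase <- function(timestamps, diagnosis_date) {
  dx <- parse_flex_date(diagnosis_date)[1]
  if (is.na(dx)) return(rep("unknown", length(timestamps)))
  ifelse(ts_to_date(timestamps) < dx, "pre", "post")
}

pct_or_na <- function(k, n) if (n > 0) 100 * k / n else NA_real_

#' Percentage of PD-related posts
#'
#' The normalization used throughout the longitudinal analyses:
#' `100 * n_pd / n_posts`, undefined (NA, never zero) when the timeframe has
#' no posts.
#'
#' @param n_pd PD-related post count.
#' @param n_posts total post count.
#' @return percentage or NA.
#' @export
pd_percentage <- function(n_pd, n_posts) {
  mapply(pct_or_na, n_pd, n_posts)
}

#' Per-participant timeframe summary
#'
#' Counts and percentages of PD-related posts overall, pre- and
#' post-diagnosis, each also recomputed excluding exercise-only posts, plus
#' the account span and years of pre-diagnosis history. Posts without a
#' phase (no diagnosis date) stay in the overall timeframe but are excluded
#' from pre/post.
#'
#' @param flags flag data.frame with `post_id`, `pd_related`,
#'   `exercise_only` covering all of the participant's posts.
#' @param posts the participant's post data.frame (`post_id`, `timestamp`).
#' @param participant one-row participant data.frame.
#' @return one-row data.frame (`timeframe_summary`).
#' @export
participant_summary <- function(flags, posts, participant) {
  stopifnot(nrow(participant) == 1L)
  f <- flags[match(posts$post_id, flags$post_id), , drop = FALSE]
  if (anyNA(f$pd_related) && nrow(posts))
    stop("flags must cover every post")
  phase <- assign_phase(posts$timestamp, participant$diagnosis_date)
  pd <- f$pd_related
  pd_nx <- f$pd_related & !f$exercise_only
  count <- function(sel) c(n = sum(sel), pd = sum(pd[sel]), pd_nx = sum(pd_nx[sel]))
  all_c <- count(rep(TRUE, length(phase)))
  pre_c <- count(phase == "pre")
  post_c <- count(phase == "post")
  span <- if (nrow(posts)) (max(posts$timestamp) - min(posts$timestamp)) / (365.25 * 86400) else NA_real_
  dx <- parse_flex_date(participant$diagnosis_date)[1]
  years_pre <- if (!is.na(dx) && nrow(posts)) {
    max(as.numeric(dx - ts_to_date(min(posts$timestamp))) / 365.25, 0)
  } else NA_real_
  out <- data.frame(
    participant_id = participant$id, group = participant$group,
    n_posts = all_c["n"], n_pd = all_c["pd"],
    n_posts_pre = pre_c["n"], n_pd_pre = pre_c["pd"],
    n_posts_post = post_c["n"], n_pd_post = post_c["pd"],
    pct = pct_or_na(all_c["pd"], all_c["n"]),
    pct_pre = pct_or_na(pre_c["pd"], pre_c["n"]),
    pct_post = pct_or_na(post_c["pd"], post_c["n"]),
    pct_nx = pct_or_na(all_c["pd_nx"], all_c["n"]),
    pct_pre_nx = pct_or_na(pre_c["pd_nx"], pre_c["n"]),
    pct_post_nx = pct_or_na(post_c["pd_nx"], post_c["n"]),
    account_span_years = span, years_pre_diagnosis = years_pre,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort summaries for all participants
#'
#' @param flags corpus-wide flag data.frame.
#' @param posts corpus-wide post data.frame.
#' @param participants participant table.
#' @return data.frame with one `participant_summary` row per participant.
#' @export
cohort_summaries <- function(flags, posts, participants) {
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    p <- participants[i, , drop = FALSE]
    participant_summary(flags[flags$participant_id == p$id, , drop = FALSE],
                        posts[posts$participant_id == p$id, , drop = FALSE], p)
  })
  do.call(rbind, rows)
}

#' Group-by-timeframe aggregate table
#'
#' For each group and timeframe (overall / pre / post; all posts and
#' excluding exercise-only posts): number of participants with a defined
#' percentage, mean percentage and SD (NA when a single participant).
#' Participants with an undefined percentage for a timeframe are excluded
#' from that cell only.
#'
#' @param summaries data.frame from [cohort_summaries()].
#' @return data.frame with columns `group`, `timeframe`, `variant`, `n`,
#'   `mean_pct`, `sd_pct`.
#' @export
cohort_table <- function(summaries) {
  cells <- expand.grid(
    group = unique(summaries$group),
    timeframe = c("overall", "pre", "post"),
    variant = c("all", "excl_exercise"),
    stringsAsFactors = FALSE)
  col_for <- function(tf, variant) {
    base <- switch(tf, overall = "pct", pre = "pct_pre", post = "pct_post")
    if (variant == "excl_exercise") paste0(base, "_nx") else base
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$group[i]
    v <- summaries[summaries$group == g, col_for(cells$timeframe[i], cells$variant[i])]
    v <- v[!is.na(v)]
    data.frame(group = g, timeframe = cells$timeframe[i],
               variant = cells$variant[i], n = length(v),
               mean_pct = if (length(v)) mean(v) else NA_real_,
               sd_pct = if (length(v) > 1L) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Keyword frequencies in PD-related posts
#'
#' Tokenizes the PD-related posts of a stratum with the model cleaning
#' pipeline and counts token frequencies (the tabular equivalent of a word
#' cloud). Ties are broken lexicographically.
#'
#' @param flags flag data.frame.
#' @param posts post data.frame (joined by `post_id`).
#' @param participants participant table (for group lookup).
#' @param group optional group filter (e.g. "PD").
#' @param phase optional phase filter ("pre"/"post"); requires diagnosis
#'   dates.
#' @param top_k number of terms to return.
#' @return data.frame with `term`, `count`, sorted by descending count then
#'   term.
#' @export
keyword_frequencies <- function(flags, posts, participants, group = NULL,
                                phase = NULL, top_k = 25) {
  sel <- posts$post_id %in% flags$post_id[flags$pd_related]
  if (!is.null(group)) {
    i <- match(posts$participant_id, participants$id)
    sel <- sel & participants$group[i] == group
  }
  if (!is.null(phase)) {
    i <- match(posts$participant_id, participants$id)
    ph <- vapply(seq_len(nrow(posts)), function(k)
      assign_phase(posts$timestamp[k], participants$diagnosis_date[i[k]]),
      character(1))
    sel <- sel & ph == phase
  }
  if (!any(sel)) return(data.frame(term = character(0), count = integer(0)))
  toks <- unlist(clean_for_model(posts$text[sel]))
  tab <- table(toks)
  out <- data.frame(term = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}
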
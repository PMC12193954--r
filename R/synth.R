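#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions of a movement-disorder cohort
#' donating Facebook archives: 30 PD, 3 ET, 1 AP and 12 caregiver accounts;
#' about 14 +/- 3 years of account history with diagnosis about 5 years after
#' account creation (90% of accounts created pre-diagnosis); post counts with
#' mean 4018 and SD 5570 (drawn lognormal, so the heavy upper tail of very
#' active accounts is represented); and phase-specific PD-content rates per
#' group (PD 1.7% pre- and 4.0% post-diagnosis).
#'
#' @param n_pd,n_et,n_ap,n_cg participants per group.
#' @param years_active_mean,years_active_sd account span (years).
#' @param posts_mean,posts_sd posts per participant (lognormal, floored at
#'   `posts_min`).
#' @param posts_min minimum posts per participant.
#' @param years_pre_mean,years_pre_sd years of Facebook use before diagnosis.
#' @param frac_account_before_dx share of accounts created before diagnosis.
#' @param rate_pre,rate_post named per-group probabilities that a post is
#'   PD-related, by diagnosis phase.
#' @param pd_exercise_frac share of PD-related posts that are exercise-themed.
#' @param ambiguous_rate probability that a non-PD post uses ambiguous
#'   dictionary vocabulary (so the classifier task is non-trivial).
#' @param dup_exact_rate,dup_near_rate,dup_reshare_rate duplicate-injection
#'   probabilities (exact copy; near copy < 180 s; legitimate reshare >= 180 s).
#' @param memory_rate probability a post is written as a shared memory with an
#'   in-text "N years ago" prefix.
#' @param mojibake_rate probability a post's bytes are written UTF-8-as-Latin-1
#'   corrupted.
#' @param cg_dx_rate share of caregivers with an (inferred) diagnosis date.
#' @param overlap_rate share of posts duplicated across export files.
#' @param seed integer RNG seed or NULL.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_pd = 30, n_et = 3, n_ap = 1, n_cg = 12,
                         years_active_mean = 14, years_active_sd = 3,
                         posts_mean = 4018, posts_sd = 5570, posts_min = 20,
                         years_pre_mean = 5, years_pre_sd = 6,
                         frac_account_before_dx = 0.9,
                         rate_pre = c(PD = 0.017, ET = 0.010, AP = 0.093, CG = 0.011),
                         rate_post = c(PD = 0.040, ET = 0.007, AP = 0.049, CG = 0.010),
                         pd_exercise_frac = 0.4,
                         ambiguous_rate = 0.065,
                         dup_exact_rate = 0.05, dup_near_rate = 0.03,
                         dup_reshare_rate = 0.02,
                         memory_rate = 0.05, mojibake_rate = 0.02,
                         cg_dx_rate = 0.6, overlap_rate = 0.2, seed = NULL) {
  cfg <- list(n_pd = n_pd, n_et = n_et, n_ap = n_ap, n_cg = n_cg,
              years_active_mean = years_active_mean, years_active_sd = years_active_sd,
              posts_mean = posts_mean, posts_sd = posts_sd, posts_min = posts_min,
              years_pre_mean = years_pre_mean, years_pre_sd = years_pre_sd,
              frac_account_before_dx = frac_account_before_dx,
              rate_pre = rate_pre, rate_post = rate_post,
              pd_exercise_frac = pd_exercise_frac, ambiguous_rate = ambiguous_rate,
              dup_exact_rate = dup_exact_rate, dup_near_rate = dup_near_rate,
              dup_reshare_rate = dup_reshare_rate,
              memory_rate = memory_rate, mojibake_rate = mojibake_rate,
              cg_dx_rate = cg_dx_rate, overlap_rate = overlap_rate, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_pd, cfg$n_et, cfg$n_ap, cfg$n_cg)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("participant counts must be non-negative integers")
  if (cfg$posts_mean <= 0) stop("posts_mean must be positive")
  rates <- c(cfg$rate_pre, cfg$rate_post, cfg$pd_exercise_frac, cfg$ambiguous_rate,
             cfg$dup_exact_rate, cfg$dup_near_rate, cfg$dup_reshare_rate,
             cfg$memory_rate, cfg$mojibake_rate, cfg$cg_dx_rate, cfg$overlap_rate,
             cfg$frac_account_before_dx)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  for (nm in c("rate_pre", "rate_post")) {
    if (!all(c("PD", "ET", "AP", "CG") %in% names(cfg[[nm]])))
      stop(nm, " must be named with groups PD, ET, AP, CG")
  }
  invisible(cfg)
}

# Shared-pool rates: fraction of (non-exercise) positives, and of ambiguous
# negatives, drawn from the genuinely ambiguous shared templates.
SHARED_POS_RATE <- 0.12
SHARED_NEG_RATE <- 0.3

# Draw texts for a batch of posts. `is_pd` labels PD-relatedness,
# `is_exercise` marks exercise-themed positives, `ambiguous` marks negatives
# that must carry (ambiguous) dictionary vocabulary.
draw_post_texts <- function(n, is_pd, is_exercise, ambiguous = rep(TRUE, n)) {
  out <- character(n)
  shared_pos <- is_pd & !is_exercise & runif(n) < SHARED_POS_RATE
  pd_nx <- is_pd & !is_exercise & !shared_pos
  if (any(pd_nx)) {
    cat_pool <- sample(c("s", "m", "a"), sum(pd_nx), replace = TRUE,
                       prob = c(0.5, 0.3, 0.2))
    idx <- which(pd_nx)
    out[idx[cat_pool == "s"]] <- render_pool(TPL_POS_SYMPTOM, sum(cat_pool == "s"))
    out[idx[cat_pool == "m"]] <- render_pool(TPL_POS_MEDICATION, sum(cat_pool == "m"))
    out[idx[cat_pool == "a"]] <- render_pool(TPL_POS_ADVOCACY, sum(cat_pool == "a"))
  }
  if (any(shared_pos))
    out[shared_pos] <- render_pool(TPL_SHARED_AMBIG, sum(shared_pos))
  if (any(is_pd & is_exercise))
    out[is_pd & is_exercise] <- render_pool(TPL_POS_EXERCISE, sum(is_pd & is_exercise))
  neg_amb <- !is_pd & ambiguous
  shared_neg <- neg_amb & runif(n) < SHARED_NEG_RATE
  if (any(shared_neg))
    out[shared_neg] <- render_pool(TPL_SHARED_AMBIG, sum(shared_neg))
  if (any(neg_amb & !shared_neg))
    out[neg_amb & !shared_neg] <- render_pool(TPL_NEG_AMBIG, sum(neg_amb & !shared_neg))
  if (any(!is_pd & !ambiguous))
    out[!is_pd & !ambiguous] <- render_pool(TPL_NEG_PLAIN, sum(!is_pd & !ambiguous))
  out
}

#' Generate a synthetic cohort
#'
#' Draws participants, per-participant timestamped text events with known
#' PD-relatedness labels, and the ground-truth table keyed by stable post id.
#' Phase-specific PD-content rates are applied relative to each participant's
#' diagnosis date; caregivers without a diagnosis date post PD content at the
#' pre-diagnosis caregiver rate.
#'
#' @param config a [synth_config()].
#' @return list with `participants` (data.frame), `events` (named list of
#'   per-participant event data.frames), `truth` (data.frame: post_id,
#'   participant_id, is_pd_related, is_exercise).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  groups <- rep(c("PD", "ET", "AP", "CG"),
                times = c(config$n_pd, config$n_et, config$n_ap, config$n_cg))
  n <- length(groups)
  if (n == 0L) stop("empty cohort: all group counts are zero")
  ids <- sprintf("P%03d", seq_len(n))
  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.43, 0.57))
  age <- pmin(pmax(round(rnorm(n, 66.5, 13)), 35), 95)
  interview_date <- as.Date("2024-06-15") + sample(-180:180, n, replace = TRUE)
  span_years <- pmin(pmax(rnorm(n, config$years_active_mean, config$years_active_sd), 2), 19)
  first_post <- interview_date - round(span_years * 365.25)

  # diagnosis timing: years of account history before diagnosis
  has_dx <- ifelse(groups == "CG", runif(n) < config$cg_dx_rate, TRUE)
  before <- runif(n) < config$frac_account_before_dx
  years_pre <- numeric(n)
  pos_draw <- abs(rnorm(n, config$years_pre_mean, config$years_pre_sd)) + 0.1
  years_pre[before] <- pos_draw[before]
  years_pre[!before] <- -runif(sum(!before), 0.2, 3)
  dx_date <- first_post + round(years_pre * 365.25)
  dx_date <- pmin(dx_date, interview_date - 60)
  dx_date[!has_dx] <- NA

  participants <- data.frame(
    id = ids, group = groups, gender = gender, age_at_interview = age,
    interview_date = interview_date, diagnosis_date = dx_date,
    stringsAsFactors = FALSE)

  mlog <- log(config$posts_mean^2 / sqrt(config$posts_mean^2 + config$posts_sd^2))
  slog <- sqrt(log(1 + (config$posts_sd / config$posts_mean)^2))
  n_posts <- pmax(round(rlnorm(n, mlog, slog)), config$posts_min)

  events <- vector("list", n)
  names(events) <- ids
  for (i in seq_len(n)) {
    m <- n_posts[i]
    t0 <- as.numeric(as.POSIXct(first_post[i], tz = "UTC"))
    t1 <- as.numeric(as.POSIXct(interview_date[i], tz = "UTC"))
    ts <- sort(round(runif(m, t0, t1)))
    ts <- ts + seq_len(m) * 0  # keep numeric
    date <- ts_to_date(ts)
    if (has_dx[i]) {
      phase <- ifelse(date < dx_date[i], "pre", "post")
      rate <- ifelse(phase == "pre", config$rate_pre[[groups[i]]],
                     config$rate_post[[groups[i]]])
    } else {
      phase <- rep("unknown", m)
      rate <- rep(config$rate_pre[[groups[i]]], m)
    }
    is_pd <- runif(m) < rate
    is_exercise <- is_pd & runif(m) < config$pd_exercise_frac
    ambiguous <- is_pd | runif(m) < config$ambiguous_rate
    text <- draw_post_texts(m, is_pd, is_exercise, ambiguous)
    mojibake <- runif(m) < config$mojibake_rate
    if (any(mojibake))
      text[mojibake] <- paste0(text[mojibake],
                               sample(MOJIBAKE_SUFFIXES, sum(mojibake), replace = TRUE))
    # texts must be unique within a participant so the expected post-dedup
    # count is exact; vary colliding texts with filler words
    guard <- 0L
    while (anyDuplicated(text) && guard < 50L) {
      d <- duplicated(text)
      text[d] <- paste(text[d], sample(FILLER_WORDS, sum(d), replace = TRUE))
      guard <- guard + 1L
    }
    events[[i]] <- data.frame(
      participant_id = ids[i], timestamp = ts, text = text,
      kind = sample(c("post", "comment"), m, replace = TRUE, prob = c(0.8, 0.2)),
      phase = phase, is_pd = is_pd, is_exercise = is_exercise,
      is_memory = runif(m) < config$memory_rate, mojibake = mojibake,
      injected = "none", removable = FALSE, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(events, function(e) data.frame(
    post_id = post_id(e$participant_id, e$timestamp, e$text),
    participant_id = e$participant_id,
    is_pd_related = e$is_pd, is_exercise = e$is_exercise,
    stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  list(participants = participants, events = events, truth = truth)
}

#' Inject duplicate events
#'
#' Adds exact copies (same timestamp and text), near copies offset by less
#' than 180 s, and legitimate reshares offset by at least 180 s. Injected rows
#' are marked in `injected`, and `removable` records which rows the
#' deduplicator must drop, so `sum(!removable)` is the expected post-dedup
#' count.
#'
#' @param events per-participant event data.frame (time-sorted).
#' @param config a [synth_config()].
#' @return augmented, time-sorted event data.frame.
#' @export
inject_duplicates <- function(events, config) {
  if (is.unsorted(events$timestamp)) stop("events must be time-sorted")
  copies <- list()
  mk <- function(rows, kind, offset, removable) {
    if (!nrow(rows)) return(NULL)
    rows$timestamp <- rows$timestamp + offset
    rows$injected <- kind
    rows$removable <- removable
    rows
  }
  m <- nrow(events)
  ex <- events[runif(m) < config$dup_exact_rate, , drop = FALSE]
  copies$exact <- mk(ex, "exact", 0, TRUE)
  nr <- events[runif(m) < config$dup_near_rate, , drop = FALSE]
  copies$near <- mk(nr, "near", sample(10:170, nrow(nr), replace = TRUE), TRUE)
  rs <- events[runif(m) < config$dup_reshare_rate, , drop = FALSE]
  copies$reshare <- mk(rs, "reshare",
                       sample(200:2592000, max(nrow(rs), 1), replace = TRUE)[seq_len(nrow(rs))],
                       FALSE)
  out <- rbind(events, do.call(rbind, copies))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# UTF-8 bytes reinterpreted as Latin-1: the classic mojibake corruption.
corrupt_encoding <- function(x) {
  vapply(x, function(s) {
    r <- charToRaw(enc2utf8(s))
    y <- rawToChar(r)
    Encoding(y) <- "latin1"
    enc2utf8(y)
  }, character(1), USE.NAMES = FALSE)
}

#' Write one participant's archive in the export dialect
#'
#' Writes `posts.json`, `comments.json`, `pages.json` and `groups.json` under
#' `out_dir/<participant id>/`. Posts and comments are distributed by event
#' kind, with a fraction of posts duplicated into `comments.json` (export
#' files are deliberately not mutually exclusive). Memory posts are written
#' with an in-text "N years ago" prefix and mojibake-marked posts with
#' corrupted bytes.
#'
#' @param participant_id single id.
#' @param events event data.frame for that participant.
#' @param out_dir archive root directory.
#' @param config a [synth_config()].
#' @return character vector of file paths written.
#' @export
write_export <- function(participant_id, events, out_dir, config) {
  if (!nrow(events)) stop("events must be non-empty")
  dir <- file.path(out_dir, participant_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  text <- events$text
  if (any(events$is_memory)) {
    nmem <- sum(events$is_memory)
    unit <- sample(c("years", "months", "days"), nmem, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
    qty <- sample(1:9, nmem, replace = TRUE)
    sep <- sample(c(": ", " - ", " "), nmem, replace = TRUE)
    text[events$is_memory] <- paste0(qty, " ", unit, " ago", sep,
                                     text[events$is_memory])
  }
  if (any(events$mojibake))
    text[events$mojibake] <- corrupt_encoding(text[events$mojibake])

  is_post <- events$kind == "post"
  posts <- data.frame(timestamp = events$timestamp[is_post],
                      text = text[is_post], stringsAsFactors = FALSE)
  overlap <- posts[runif(nrow(posts)) < config$overlap_rate, , drop = FALSE]
  comments <- rbind(
    data.frame(timestamp = events$timestamp[!is_post], text = text[!is_post],
               stringsAsFactors = FALSE),
    overlap)

  posts_json <- lapply(seq_len(nrow(posts)), function(k) list(
    timestamp = posts$timestamp[k], data = list(list(post = posts$text[k]))))
  comments_json <- lapply(seq_len(nrow(comments)), function(k) list(
    timestamp = comments$timestamp[k],
    comment = list(comment = comments$text[k])))
  pages_json <- list(list(name = "Local Birdwatchers"),
                     list(name = "Community Garden Page"))
  groups_json <- list(list(name = "Neighborhood Group", member = TRUE))

  paths <- file.path(dir, c("posts.json", "comments.json", "pages.json",
                            "groups.json"))
  jsonlite::write_json(posts_json, paths[1], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(comments_json, paths[2], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(pages_json, paths[3], auto_unbox = TRUE)
  jsonlite::write_json(groups_json, paths[4], auto_unbox = TRUE)
  paths
}

#' Simulate a full archive directory
#'
#' Generates a cohort, injects duplicates, writes every participant's archive
#' plus `participants.tsv` and `labels.tsv`, and logs realized PD-content
#' rates.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with `dir`, `participants`, `truth`, `events` and
#'   `expected_dedup` (named expected post-dedup counts).
#' @export
simulate_archives <- function(config, out_dir) {
  cohort <- generate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expected <- integer(0)
  for (id in names(cohort$events)) {
    ev <- inject_duplicates(cohort$events[[id]], config)
    cohort$events[[id]] <- ev
    expected[id] <- sum(!ev$removable)
    write_export(id, ev, out_dir, config)
  }
  p <- cohort$participants
  p$interview_date <- as.character(p$interview_date)
  p$diagnosis_date <- ifelse(is.na(p$diagnosis_date), "",
                             as.character(p$diagnosis_date))
  write.table(p, file.path(out_dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(out_dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rate <- mean(cohort$truth$is_pd_related)
  message(sprintf("simulated %d participants, %d unique posts, %.2f%% PD-related",
                  nrow(p), nrow(cohort$truth), 100 * rate))
  invisible(list(dir = out_dir, participants = cohort$participants,
                 truth = cohort$truth, events = cohort$events,
                 expected_dedup = expected))
}

#' Generate a labeled ground-truth corpus
#'
#' Emulates the annotated corpus used for classifier development: every post
#' contains at least one dictionary term, a configurable fraction is truly
#' PD-related, and each post carries author covariates (age, gender, group)
#' for the feature pipeline. Defaults mirror an annotation set of 6750 posts,
#' 35.6% PD-related, written by 14 PD participants and 5 caregivers.
#'
#' @param n number of posts.
#' @param pos_fraction fraction of PD-related posts.
#' @param n_pd_authors,n_cg_authors author counts.
#' @param exercise_frac share of exercise-themed posts among the PD-related
#'   class.
#' @param seed RNG seed or NULL.
#' @return list with `posts` (post_id, participant_id, timestamp, text, label,
#'   is_exercise) and `participants`.
#' @export
synth_labeled_corpus <- function(n = 6750, pos_fraction = 2400 / 6750,
                                 n_pd_authors = 14, n_cg_authors = 5,
                                 exercise_frac = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  na <- n_pd_authors + n_cg_authors
  participants <- data.frame(
    id = sprintf("A%02d", seq_len(na)),
    group = rep(c("PD", "CG"), times = c(n_pd_authors, n_cg_authors)),
    gender = sample(c("F", "M"), na, replace = TRUE),
    age_at_interview = pmin(pmax(round(rnorm(na, 66.5, 13)), 35), 95),
    interview_date = as.Date("2024-06-15"),
    diagnosis_date = as.Date("2019-06-15") + sample(-720:720, na, replace = TRUE),
    stringsAsFactors = FALSE)
  author <- sample(participants$id, n, replace = TRUE)
  label <- runif(n) < pos_fraction
  is_exercise <- label & runif(n) < exercise_frac
  # negatives in the annotation corpus are dictionary-flagged by construction:
  # every post, either class, is drawn from dictionary-bearing templates
  text <- draw_post_texts(n, label, is_exercise, ambiguous = rep(TRUE, n))
  t0 <- as.numeric(as.POSIXct(as.Date("2012-01-01"), tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(as.Date("2024-06-01"), tz = "UTC"))
  ts <- round(runif(n, t0, t1))
  posts <- data.frame(
    post_id = post_id(author, ts, text), participant_id = author,
    timestamp = ts, text = text, label = as.integer(label),
    is_exercise = is_exercise, stringsAsFactors = FALSE)
  list(posts = posts, participants = participants)
}
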
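ts_of <- function(date) as.numeric(as.POSIXct(as.Date(date), tz = "UTC"))

lt_participant <- data.frame(
  id = "L01", group = "PD", gender = "M", age_at_interview = 70,
  interview_date = as.Date("2024-01-01"), diagnosis_date = as.Date("2020-06-15"),
  stringsAsFactors = FALSE)

mk_corpus <- function(dates, pd, exercise_only = rep(FALSE, length(dates)),
                      id = "L01") {
  ts <- vapply(dates, ts_of, numeric(1))
  posts <- data.frame(post_id = paste0(rep(id, length(ts)), seq_along(ts)),
                      participant_id = rep(id, length(ts)),
                      timestamp = ts, text = rep("x", length(ts)),
                      stringsAsFactors = FALSE)
  flags <- data.frame(post_id = posts$post_id,
                      participant_id = rep(id, length(ts)),
                      pd_related = pd, exercise_only = exercise_only,
                      stringsAsFactors = FALSE)
  list(posts = posts, flags = flags)
}

test_that("phase assignment: day before is pre, diagnosis day is post", {
  expect_identical(assign_phase(ts_of("2020-06-14"), as.Date("2020-06-15")), "pre")
  expect_identical(assign_phase(ts_of("2020-06-15"), as.Date("2020-06-15")), "post")
  expect_identical(assign_phase(ts_of("2020-06-16"), NA), "unknown")
})

test_that("year-only diagnosis dates coerce to July 1 with a message", {
  expect_message(ph <- assign_phase(ts_of("2020-06-30"), "2020"), "July 1")
  expect_identical(ph, "pre")
})

test_that("participant summary computes counts, percentages and spans", {
  cc <- mk_corpus(c("2018-01-01", "2019-01-01", "2021-01-01", "2022-01-01"),
                  pd = c(FALSE, TRUE, TRUE, FALSE))
  s <- participant_summary(cc$flags, cc$posts, lt_participant)
  expect_identical(s$n_posts, 4L)
  expect_equal(s$pct, 50)
  expect_equal(s$pct_pre, 50)
  expect_equal(s$pct_post, 50)
  expect_equal(s$account_span_years, 4, tolerance = 0.01)
  expect_equal(s$years_pre_diagnosis, 2.45, tolerance = 0.01)
  # 1000 posts with 36 PD-related -> 3.6%
  expect_equal(pd_percentage(36, 1000), 3.6)
})

test_that("timeframes without posts give NA percentages, never zero", {
  cc <- mk_corpus(c("2017-01-01", "2018-01-01"), pd = c(TRUE, FALSE))
  s <- participant_summary(cc$flags, cc$posts, lt_participant)
  expect_true(is.na(s$pct_post))
  expect_equal(s$pct_pre, 50)
  empty <- mk_corpus(character(0), logical(0))
  s0 <- participant_summary(empty$flags, empty$posts, lt_participant)
  expect_identical(s0$n_posts, 0L)
  expect_true(is.na(s0$pct))
})

test_that("caregivers without diagnosis dates stay in overall only", {
  cg <- data.frame(id = "C01", group = "CG", gender = "F", age_at_interview = 60,
                   interview_date = as.Date("2024-01-01"),
                   diagnosis_date = as.Date(NA), stringsAsFactors = FALSE)
  cc <- mk_corpus(c("2019-01-01", "2021-01-01"), pd = c(TRUE, FALSE), id = "C01")
  s <- participant_summary(cc$flags, cc$posts, cg)
  expect_equal(s$pct, 50)
  expect_true(is.na(s$pct_pre) && is.na(s$pct_post))
  expect_identical(s$n_posts_pre + s$n_posts_post, 0L)
})

test_that("exercise-excluded percentages drop exercise-only posts", {
  cc <- mk_corpus(c("2021-01-01", "2021-02-01", "2021-03-01", "2021-04-01"),
                  pd = c(TRUE, TRUE, FALSE, FALSE),
                  exercise_only = c(FALSE, TRUE, FALSE, FALSE))
  s <- participant_summary(cc$flags, cc$posts, lt_participant)
  expect_equal(s$pct, 50)
  expect_equal(s$pct_nx, 25)
})

test_that("doubling post volume at the same PD fraction leaves pct unchanged", {
  cc <- mk_corpus(c("2021-01-01", "2021-02-01"), pd = c(TRUE, FALSE))
  dates2 <- c("2021-01-01", "2021-02-01", "2021-05-01", "2021-06-01")
  cc2 <- mk_corpus(dates2, pd = c(TRUE, FALSE, TRUE, FALSE))
  s1 <- participant_summary(cc$flags, cc$posts, lt_participant)
  s2 <- participant_summary(cc2$flags, cc2$posts, lt_participant)
  expect_equal(s1$pct, s2$pct)
  expect_equal(s1$pct_post, s2$pct_post)
})

test_that("pre and post partition the phase-known posts exactly", {
  co <- generate_cohort(synth_config(n_pd = 3, n_et = 0, n_ap = 0, n_cg = 2,
                                     posts_mean = 80, posts_sd = 20, seed = 61))
  truth <- co$truth
  flags <- data.frame(post_id = truth$post_id, participant_id = truth$participant_id,
                      pd_related = truth$is_pd_related, exercise_only = FALSE,
                      stringsAsFactors = FALSE)
  posts <- do.call(rbind, lapply(co$events, function(e) data.frame(
    post_id = post_id(e$participant_id, e$timestamp, e$text),
    participant_id = e$participant_id, timestamp = e$timestamp,
    text = e$text, stringsAsFactors = FALSE)))
  s <- cohort_summaries(flags, posts, co$participants)
  has_dx <- !is.na(co$participants$diagnosis_date)
  expect_true(all((s$n_posts_pre + s$n_posts_post)[has_dx] == s$n_posts[has_dx]))
  expect_true(all((s$n_posts_pre + s$n_posts_post)[!has_dx] == 0))
  expect_true(all(s$n_pd <= s$n_posts))
})

test_that("cohort table matches hand-computed means and handles single cells", {
  mk_sum <- function(id, group, pre, post) data.frame(
    participant_id = id, group = group, n_posts = 10L, n_pd = 1L,
    n_posts_pre = 5L, n_pd_pre = 1L, n_posts_post = 5L, n_pd_post = 0L,
    pct = mean(c(pre, post)), pct_pre = pre, pct_post = post,
    pct_nx = mean(c(pre, post)), pct_pre_nx = pre, pct_post_nx = post,
    account_span_years = 10, years_pre_diagnosis = 5, stringsAsFactors = FALSE)
  sums <- rbind(mk_sum("a", "PD", 2, 4), mk_sum("b", "PD", 4, 8),
                mk_sum("c", "PD", 3, 6), mk_sum("d", "AP", 9.3, 4.9))
  tab <- cohort_table(sums)
  pd_pre <- tab[tab$group == "PD" & tab$timeframe == "pre" & tab$variant == "all", ]
  expect_identical(pd_pre$n, 3L)
  expect_equal(pd_pre$mean_pct, 3)
  expect_equal(pd_pre$sd_pct, 1)
  ap_pre <- tab[tab$group == "AP" & tab$timeframe == "pre" & tab$variant == "all", ]
  expect_identical(ap_pre$n, 1L)
  expect_true(is.na(ap_pre$sd_pct))   # single participant: SD undefined
  # identical participants -> SD 0
  sums2 <- rbind(mk_sum("a", "PD", 2, 4), mk_sum("b", "PD", 2, 4))
  tab2 <- cohort_table(sums2)
  expect_equal(tab2[tab2$group == "PD" & tab2$timeframe == "pre" &
                      tab2$variant == "all", "sd_pct"], 0)
  # NA percentages excluded from the cell N
  sums3 <- rbind(mk_sum("a", "PD", 2, 4),
                 transform(mk_sum("b", "PD", 2, 4), pct_pre = NA_real_))
  tab3 <- cohort_table(sums3)
  expect_identical(tab3[tab3$group == "PD" & tab3$timeframe == "pre" &
                          tab3$variant == "all", "n"], 1L)
})

test_that("keyword frequencies count cleaned tokens with lexicographic ties", {
  posts <- data.frame(post_id = c("k1", "k2", "k3"), participant_id = "L01",
                      timestamp = ts_of("2021-01-01") + 1:3,
                      text = c("tremor tremor pain", "pain", "the and a"),
                      stringsAsFactors = FALSE)
  flags <- data.frame(post_id = c("k1", "k2", "k3"), participant_id = "L01",
                      pd_related = c(TRUE, TRUE, FALSE), exercise_only = FALSE,
                      stringsAsFactors = FALSE)
  kw <- keyword_frequencies(flags, posts, lt_participant)
  expect_identical(kw$term, c("pain", "tremor"))   # tie broken lexicographically
  expect_identical(kw$count, c(2L, 2L))
  expect_identical(nrow(keyword_frequencies(flags, posts, lt_participant,
                                            group = "CG")), 0L)
  expect_identical(keyword_frequencies(flags, posts, lt_participant,
                                       top_k = 1)$term, "pain")
})
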
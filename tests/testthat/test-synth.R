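small_cfg <- function(...) {
  synth_config(n_pd = 3, n_et = 1, n_ap = 0, n_cg = 2,
               posts_mean = 100, posts_sd = 40, ...)
}

test_that("config validation rejects bad rates and counts", {
  expect_error(synth_config(n_pd = -1), "non-negative")
  expect_error(synth_config(posts_mean = 0), "positive")
  expect_error(synth_config(memory_rate = 1.2), "rates")
  expect_error(synth_config(rate_pre = c(PD = 0.1)), "named")
})

test_that("zero PD rates produce zero PD labels", {
  cfg <- small_cfg(rate_pre = c(PD = 0, ET = 0, AP = 0, CG = 0),
                   rate_post = c(PD = 0, ET = 0, AP = 0, CG = 0), seed = 2)
  co <- generate_cohort(cfg)
  expect_identical(sum(co$truth$is_pd_related), 0L)
})

test_that("labels are conserved: one label pair per unique generated post", {
  co <- generate_cohort(small_cfg(seed = 3))
  n_events <- sum(vapply(co$events, nrow, integer(1)))
  expect_identical(nrow(co$truth), n_events)
  expect_false(anyDuplicated(co$truth$post_id) > 0)
})

test_that("realized post-phase PD fraction is within 3 binomial SDs of the rate", {
  cfg <- synth_config(n_pd = 30, n_et = 0, n_ap = 0, n_cg = 0,
                      posts_mean = 400, posts_sd = 50, seed = 4)
  co <- generate_cohort(cfg)
  post_sel <- do.call(rbind, co$events)
  post_sel <- post_sel[post_sel$phase == "post", ]
  n <- nrow(post_sel)
  phat <- mean(post_sel$is_pd)
  expect_lt(abs(phat - 0.04), 3 * sqrt(0.04 * 0.96 / n))
})

test_that("identical seeds give byte-identical archives and labels", {
  cfg <- small_cfg(seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_archives(cfg, d1)
  s2 <- simulate_archives(small_cfg(seed = 7), d2)
  expect_identical(s1$truth, s2$truth)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  same <- vapply(f1, function(f) identical(
    readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
    readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))), logical(1))
  expect_true(all(same))
})

test_that("duplicate injection marks exactly the removable copies", {
  ev <- data.frame(participant_id = "p", timestamp = c(1000, 5000, 9000),
                   text = c("a", "b", "c"), kind = "post", phase = "pre",
                   is_pd = FALSE, is_exercise = FALSE, is_memory = FALSE,
                   mojibake = FALSE, injected = "none", removable = FALSE,
                   stringsAsFactors = FALSE)
  cfg0 <- small_cfg(dup_exact_rate = 0, dup_near_rate = 0, dup_reshare_rate = 0)
  expect_identical(inject_duplicates(ev, cfg0), ev)
  set.seed(1)
  cfg1 <- small_cfg(dup_exact_rate = 1, dup_near_rate = 0, dup_reshare_rate = 0)
  out <- inject_duplicates(ev, cfg1)
  expect_identical(sum(out$removable), 3L)
  expect_identical(sum(!out$removable), 3L)
  # near copy within the window is removable, reshare past it is not
  cfg2 <- small_cfg(dup_near_rate = 1, dup_reshare_rate = 1, dup_exact_rate = 0)
  out2 <- inject_duplicates(ev, cfg2)
  expect_identical(sum(out2$removable), 3L)       # the three near copies
  expect_identical(sum(out2$injected == "reshare"), 3L)
  expect_true(all(!out2$removable[out2$injected == "reshare"]))
})

test_that("near copy at +100 s and reshare at +400 s leave one removable copy", {
  base <- data.frame(participant_id = "p", timestamp = 1000, text = "hello world",
                     kind = "post", stringsAsFactors = FALSE)
  entries <- rbind(base,
                   transform(base, timestamp = 1100),
                   transform(base, timestamp = 1400))
  posts <- deduplicate(entries)
  expect_identical(posts$timestamp, c(1000, 1400))
})

test_that("export conservation: union of file texts covers all events", {
  cfg <- small_cfg(seed = 11, memory_rate = 0, mojibake_rate = 0)
  co <- generate_cohort(cfg)
  id <- names(co$events)[1]
  td <- tempfile()
  paths <- write_export(id, co$events[[id]], td, cfg)
  expect_true(all(file.exists(paths)))
  harvested <- read_export(file.path(td, id))
  expect_setequal(unique(harvested$text), unique(co$events[[id]]$text))
})

test_that("memory_rate 1 prefixes every written post with an ago phrase", {
  cfg <- small_cfg(seed = 12, memory_rate = 1, mojibake_rate = 0)
  co <- generate_cohort(cfg)
  id <- names(co$events)[1]
  td <- tempfile()
  write_export(id, co$events[[id]], td, cfg)
  harvested <- read_export(file.path(td, id))
  expect_true(all(grepl("\\bago\\b", harvested$text)))
  # and stripping recovers the original texts
  cleaned <- strip_memory_timestamps(harvested$text)
  expect_setequal(unique(cleaned), unique(co$events[[id]]$text))
})

test_that("mojibake_rate 1 corrupts raw bytes but repair recovers the text", {
  cfg <- small_cfg(seed = 13, memory_rate = 0, mojibake_rate = 1)
  co <- generate_cohort(cfg)
  id <- names(co$events)[1]
  td <- tempfile()
  write_export(id, co$events[[id]], td, cfg)
  harvested <- read_export(file.path(td, id))
  orig <- co$events[[id]]$text
  expect_false(any(harvested$text %in% orig))
  expect_setequal(unique(normalize_encoding(harvested$text)), unique(orig))
})

test_that("labeled corpus hits the configured prevalence and is fully dictionary-flagged", {
  lc <- synth_labeled_corpus(n = 1500, seed = 21)
  phat <- mean(lc$posts$label)
  expect_lt(abs(phat - 2400 / 6750), 3 * sqrt(0.356 * 0.644 / 1500))
  hits <- dictionary_flag_corpus(lc$posts$text, default_dictionary())$hit
  expect_true(all(hits))
})
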
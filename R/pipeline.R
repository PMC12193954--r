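# End-to-end orchestration over the module functions, driven by a config
# list (or YAML file). Stage order: ingest -> lexicon -> train (when labels
# are present) -> flag -> longitudinal -> stats. Every stage logs counts in
# and out so conservation is machine-checkable from the log.

#' Load a pipeline run configuration
#'
#' @param path YAML file; fields: `archives_dir`, `participants`,
#'   `dictionary` (optional; bundled default), `cluster_table` (optional),
#'   `labels` (optional TSV for classifier training), `out_dir`, `seed`,
#'   plus optional `classifier` overrides (`families`, `test_fraction`, `B`).
#' @return named list (class `run_config`).
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

read_participants_tsv <- function(path) {
  p <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  p$age_at_interview <- as.numeric(p$age_at_interview)
  p$interview_date <- parse_flex_date(p$interview_date)
  p$diagnosis_date <- parse_flex_date(p$diagnosis_date)
  p
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Ingests every participant archive, flags the corpus (training the
#' classifier first on the labeled posts), computes per-participant and
#' cohort longitudinal summaries, keyword frequencies and the statistical
#' battery, and writes all report files under `out_dir`.
#'
#' @param config a `run_config` (or list with the same fields).
#' @return (invisibly) list with `corpus`, `flags`, `summaries`, `table`,
#'   `stats`, `model`, and the written file paths.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% "pdposts_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  participants <- read_participants_tsv(config$participants)
  dict <- if (is.null(config$dictionary)) default_dictionary()
          else load_dictionary(config$dictionary)
  cluster_table <- load_cluster_table(config$cluster_table)

  # ingest
  dirs <- list.dirs(config$archives_dir, recursive = FALSE)
  dirs <- dirs[basename(dirs) %in% participants$id]
  corpus <- list()
  for (d in dirs) {
    posts <- ingest_archive(d)
    errs <- attr(posts, "errors")
    if (length(errs)) log_stage("ingest", "%s: %d file error(s)", basename(d), length(errs))
    corpus[[basename(d)]] <- posts
  }
  corpus <- do.call(rbind, corpus)
  rownames(corpus) <- NULL
  log_stage("ingest", "harvested %d posts from %d archives", nrow(corpus), length(dirs))

  # train (labels present) on the ingested posts that appear in the label file
  model <- NULL
  if (!is.null(config$labels)) {
    labels <- utils::read.delim(config$labels, sep = "\t", stringsAsFactors = FALSE)
    lab <- merge(corpus, labels[, c("post_id", "is_pd_related")], by = "post_id")
    dhit <- dictionary_flag_corpus(lab$text, dict)$hit
    lab <- lab[dhit, , drop = FALSE]   # annotation corpus = dictionary-flagged posts
    lab$label <- as.integer(lab$is_pd_related %in% c(TRUE, "TRUE", "True", 1))
    cls <- config$classifier %||% list()
    model <- fit_pd_classifier(
      lab, participants,
      families = cls$families %||% FAMILIES,
      test_fraction = cls$test_fraction %||% 0.2,
      B = cls$B %||% 1000, seed = seed, cluster_table = cluster_table)
    log_stage("train", "trained on %d labeled posts; selected %s",
              nrow(lab), model$selected)
    write_model_report(model, file.path(out_dir, "classifier_metrics"))
  }

  # flag
  if (is.null(model)) stop("flagging requires a trained classifier: supply `labels`")
  flags <- flag_corpus(corpus, dict, model, participants)
  log_stage("flag", "%d of %d posts PD-related (%d dictionary hits)",
            sum(flags$pd_related), nrow(flags), sum(flags$dict_hit))
  utils::write.table(flags, file.path(out_dir, "flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # longitudinal
  summaries <- cohort_summaries(flags, corpus, participants)
  tab <- cohort_table(summaries)
  utils::write.table(summaries, file.path(out_dir, "participant_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab, file.path(out_dir, "cohort_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kw <- keyword_frequencies(flags, corpus, participants, top_k = 50)
  utils::write.table(kw, file.path(out_dir, "keyword_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("longitudinal", "summarized %d participants", nrow(summaries))

  # stats: within-group pre/post Wilcoxon per group with enough pairs,
  # between-group pre-diagnosis Mann-Whitney (PD vs CG)
  stats_out <- list()
  for (g in unique(summaries$group)) {
    s <- summaries[summaries$group == g, ]
    ok <- !is.na(s$pct_pre) & !is.na(s$pct_post) & s$pct_pre != s$pct_post
    if (sum(ok) >= 5) {
      stats_out[[paste0("wilcoxon_", g)]] <-
        wilcoxon_signed_rank(s$pct_pre[ok], s$pct_post[ok])
    }
  }
  pd_pre <- summaries$pct_pre[summaries$group == "PD"]
  cg_pre <- summaries$pct_pre[summaries$group == "CG"]
  pd_pre <- pd_pre[!is.na(pd_pre)]; cg_pre <- cg_pre[!is.na(cg_pre)]
  if (length(pd_pre) && length(cg_pre)) {
    stats_out$mann_whitney_pre_pd_vs_cg <- mann_whitney_u(pd_pre, cg_pre)
  }
  if (length(stats_out)) {
    json <- lapply(stats_out, function(s) s[c("test", "statistic", "df",
                                              "p_value", "effect_size",
                                              "n_used", "notes")])
    jsonlite::write_json(json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    log_stage("stats", "skipped: not enough participants with valid pre/post pairs")
  }

  invisible(list(corpus = corpus, flags = flags, summaries = summaries,
                 table = tab, stats = stats_out, model = model,
                 out_dir = out_dir))
}

#' Write classifier metrics reports
#'
#' Writes a metrics table (TSV, one row per model) and a JSON report.
#'
#' @param model a `pd_classifier`.
#' @param stem output path stem (writes `<stem>.tsv` and `<stem>.json`).
#' @return (invisibly) the metrics data.frame.
#' @export
write_model_report <- function(model, stem) {
  tab <- summary(model)
  utils::write.table(tab, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(tab, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(tab)
}
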
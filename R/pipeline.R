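# Pipeline commands tying the modules together: simulate a bundle, process
# it (segment -> match -> classify -> rank -> features), render static HTML
# reports, and evaluate annotation statistics. Every command writes a
# manifest (inputs, configuration hash, seed, package version) sufficient
# to reproduce its outputs; outputs carry no timestamps, so reruns with the
# same inputs are byte-identical.

write_run_manifest <- function(dir, command, config, seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE, null = "null")
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp, useBytes = TRUE)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(command = command, config = config, config_md5 = hash,
                   seed = seed,
                   natkit_version = as.character(utils::packageVersion("natkit")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(hash)
}

#' Simulate a chart bundle on disk
#'
#' Generates a synthetic cohort and writes the chart bundle, the
#' ground-truth label table (`truth.csv`, kept outside the bundle
#' directory so it can never leak into processing), and a run manifest.
#'
#' @param out_dir output directory.
#' @param config a [cohort_config()].
#' @return list with paths `bundle_dir` and `truth_file`, invisibly.
#' @export
cmd_simulate <- function(out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory '%s'", out_dir))
  gen <- generate_cohort(config)
  bundle_dir <- file.path(out_dir, "bundle")
  write_chart_bundle(gen$charts, bundle_dir)
  truth_file <- file.path(out_dir, "truth.csv")
  utils::write.csv(gen$truth, truth_file, row.names = FALSE)
  cfg <- unclass(config)
  cfg$period_start <- format(cfg$period_start)
  cfg$period_end <- format(cfg$period_end)
  write_run_manifest(out_dir, "simulate", cfg, seed = config$seed)
  invisible(list(bundle_dir = bundle_dir, truth_file = truth_file))
}

#' Process one chart through the NLP pipeline
#'
#' @param chart a `patient_chart`.
#' @param matcher compiled lexicon.
#' @param model classifier handle.
#' @param max_len sequence length bound for [segment_notes()].
#' @param sparse_note_threshold passed to [suggest_label()].
#' @return list with sequences, spans, classifications, ranking, features,
#'   match summary and label suggestion for the chart.
#' @export
process_chart <- function(chart, matcher, model, max_len = 512L,
                          sparse_note_threshold = 3L) {
  sequences <- segment_notes(chart, max_len)
  spans <- find_spans_all(sequences, matcher)
  classifications <- classify_sequences(sequences, model)
  ranking <- if (nrow(classifications)) {
    rank_notes(note_results(classifications, chart$notes))
  } else {
    rank_notes(data.frame(note_id = character(0), class = character(0),
                          score = numeric(0), date = as.Date(character(0)),
                          stringsAsFactors = FALSE))
  }
  summary <- count_matches(chart, spans)
  features <- build_patient_features(chart, summary, classifications)
  suggestion <- suggest_label(chart, spans, features, sparse_note_threshold)
  list(patient_id = chart$patient$patient_id, sequences = sequences,
       spans = spans, classifications = classifications, ranking = ranking,
       match_summary = summary, features = features, suggestion = suggestion)
}

#' Process a bundle and write pipeline outputs
#'
#' Runs period filtering, note segmentation, lexicon matching, sequence
#' classification, CI-first ranking, feature engineering and label
#' suggestion over every chart in a bundle, writing CSV outputs plus a run
#' manifest. Outputs are pure functions of (bundle, lexicon, classifier,
#' configuration).
#'
#' @param bundle_dir bundle directory (see [load_chart_bundle()]).
#' @param out_dir output directory.
#' @param lexicon lexicon data.frame (default [default_lexicon()]).
#' @param classifier `"baseline"` or a classifier handle.
#' @param period optional `c(start, end)` window; defaults to the bundle's
#'   manifest range when present.
#' @param max_len,sparse_note_threshold pipeline tuning parameters.
#' @return (invisibly) the per-patient result list from [process_chart()].
#' @export
cmd_process <- function(bundle_dir, out_dir, lexicon = default_lexicon(),
                        classifier = "baseline", period = NULL,
                        max_len = 512L, sparse_note_threshold = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  charts <- load_chart_bundle(bundle_dir)
  matcher <- compile_lexicon(lexicon)
  model <- if (is.function(classifier)) classifier else
    baseline_lexicon_classifier(matcher)
  if (!is.null(period)) {
    charts[] <- lapply(charts, filter_period, start = period[1L], end = period[2L])
  }
  results <- lapply(charts, process_chart, matcher = matcher, model = model,
                    max_len = max_len,
                    sparse_note_threshold = sparse_note_threshold)

  bind <- function(field) {
    parts <- Filter(function(x) is.data.frame(x) && nrow(x) > 0L,
                    lapply(results, `[[`, field))
    if (!length(parts)) return(NULL)
    out <- do.call(rbind, c(parts, make.row.names = FALSE))
    rownames(out) <- NULL
    out
  }
  wr <- function(df, file) {
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE, na = "")
  }
  seqs <- bind("sequences")
  if (!is.null(seqs)) seqs <- seqs[, c("note_id", "seq_index", "start", "end")]
  wr(seqs, "sequences.csv")
  wr(bind("spans"), "spans.csv")
  wr(bind("classifications"), "classifications.csv")
  rankings <- bind("ranking")
  if (!is.null(rankings)) rankings$date <- format(rankings$date)
  wr(rankings, "rankings.csv")
  wr(feature_table(lapply(results, `[[`, "features")), "features.csv")
  suggestions <- data.frame(
    patient_id = vapply(results, `[[`, "", "patient_id"),
    suggested_label = vapply(results, function(r) r$suggestion$label, ""),
    rationale = vapply(results, function(r) paste(r$suggestion$rationale, collapse = "; "), ""),
    stringsAsFactors = FALSE
  )
  rownames(suggestions) <- NULL
  wr(suggestions, "suggestions.csv")
  write_run_manifest(out_dir, "process",
                     list(bundle_dir = bundle_dir, classifier =
                            if (is.function(classifier)) "custom" else classifier,
                          n_lexicon_entries = nrow(lexicon),
                          period = if (is.null(period)) NULL else format(period),
                          max_len = max_len,
                          sparse_note_threshold = sparse_note_threshold))
  invisible(results)
}

#' Evaluate annotation statistics
#'
#' Computes the evaluation suite from flat files: Cohen kappa between two
#' label columns (with optional undetermined removal on side A and 5-class
#' binarisation on side B), the paired Wilcoxon timing comparison, and the
#' learning-effect split. Results are written as JSON and a plain-text
#' report.
#'
#' @param out_dir output directory (`NULL` to skip writing).
#' @param label_file CSV with columns patient_id, label_a, label_b.
#' @param timing_file CSV with columns patient_id, tool_min, manual_min.
#' @param drop_undetermined remove pairs where label_a is undetermined.
#' @param binarize_b collapse 5-class label_b to CN/CI first.
#' @return list with `kappa`, `timing`, `learning` components.
#' @export
cmd_evaluate <- function(out_dir = NULL, label_file = NULL, timing_file = NULL,
                         drop_undetermined = TRUE, binarize_b = FALSE) {
  out <- list()
  if (!is.null(label_file)) {
    lab <- utils::read.csv(label_file, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("patient_id", "label_a", "label_b")
    if (!all(need %in% names(lab))) {
      stop("label file must have columns patient_id, label_a, label_b")
    }
    b <- if (binarize_b) binarize_labels(lab$label_b) else lab$label_b
    out$kappa <- cohen_kappa(lab$label_a, b, drop_undetermined = drop_undetermined)
  }
  if (!is.null(timing_file)) {
    tim <- utils::read.csv(timing_file, stringsAsFactors = FALSE)
    if (!all(c("tool_min", "manual_min") %in% names(tim))) {
      stop("timing file must have columns tool_min and manual_min")
    }
    out$timing <- paired_timing_test(tim$manual_min, tim$tool_min)
    if (nrow(tim) >= 4L) out$learning <- learning_effect(tim$tool_min)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json <- list()
    if (!is.null(out$kappa)) {
      k <- out$kappa
      json$kappa <- list(kappa = if (k$kappa_defined) k$kappa else NULL,
                         po = k$po, pe = k$pe, n = k$n,
                         excluded_undetermined = k$excluded_undetermined)
    }
    if (!is.null(out$timing)) {
      t <- out$timing
      json$timing <- list(n = t$n, W = t$W, p_value = t$p_value,
                          method = t$method, mean_diff = t$mean_diff,
                          sd_diff = t$sd_diff, median_ratio = t$median_ratio,
                          min_ratio = t$min_ratio, max_ratio = t$max_ratio)
    }
    if (!is.null(out$learning)) json$learning <- out$learning
    jsonlite::write_json(json, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    txt <- utils::capture.output({
      if (!is.null(out$kappa)) print(out$kappa)
      if (!is.null(out$timing)) print(out$timing)
      if (!is.null(out$learning)) {
        cat(sprintf("Learning effect: first-half median %.2f (n=%d), second-half median %.2f (n=%d), p = %.4g\n",
                    out$learning$median_first, out$learning$n_first,
                    out$learning$median_second, out$learning$n_second,
                    out$learning$p_value))
      }
    })
    writeLines(txt, file.path(out_dir, "report.txt"), useBytes = TRUE)
    write_run_manifest(out_dir, "evaluate",
                       list(label_file = label_file, timing_file = timing_file,
                            drop_undetermined = drop_undetermined,
                            binarize_b = binarize_b))
  }
  out
}
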
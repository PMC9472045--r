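# Annotation session bookkeeping: patient-to-annotator assignment, an
# append-only flat-file label store with timing, the rule-based label
# suggestion implementing the adjudication guideline, and the dashboard
# summary rows.

LABELS <- c("CN", "CI", "undetermined")
CONFIDENCE_LEVELS <- c("low", "medium", "moderate", "high")

#' Assign patients to annotators
#'
#' Individual mode partitions the patients near-evenly (sizes differing by
#' at most one) after a seeded shuffle; shared mode gives every annotator
#' every patient.
#'
#' @param patient_ids character vector of patients (may be empty).
#' @param annotators nonempty character vector of annotator ids.
#' @param mode `"individual"` or `"shared"`.
#' @param seed integer seed making the individual-mode shuffle reproducible.
#' @return data.frame with patient_id, annotator_id, mode.
#' @export
assign_patients <- function(patient_ids, annotators, mode = c("individual", "shared"),
                            seed) {
  mode <- match.arg(mode)
  if (!length(annotators)) stop("at least one annotator is required")
  if (mode == "shared" && length(annotators) < 2L) {
    stop("shared mode requires at least two annotators")
  }
  if (!length(patient_ids)) {
    return(data.frame(patient_id = character(0), annotator_id = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  if (mode == "shared") {
    out <- expand.grid(patient_id = patient_ids, annotator_id = annotators,
                       stringsAsFactors = FALSE)
  } else {
    shuffled <- with_seed(seed, sample(patient_ids))
    out <- data.frame(
      patient_id = shuffled,
      annotator_id = rep_len(annotators, length(shuffled)),
      stringsAsFactors = FALSE
    )
  }
  out$mode <- mode
  out <- out[stable_order(out$patient_id, out$annotator_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Suggest a cognitive-status label for one patient
#'
#' Decision-support heuristic formalising the adjudication guideline; it is
#' surfaced with its rationale and never auto-saved. Rules:
#' \enumerate{
#'   \item any dementia ICD code or dementia medication -> CI;
#'   \item conflicting impaired and intact cognition keywords -> the
#'     latest-dated evidence decides (ties resolved to impaired);
#'   \item impaired cognition keywords only -> CI;
#'   \item intact cognition keywords only -> CN;
#'   \item no evidence and a sparse chart (fewer than `sparse_note_threshold`
#'     notes) -> undetermined;
#'   \item otherwise CN on implicit evidence (notes reviewed, no concern).
#' }
#'
#' @param chart a `patient_chart`.
#' @param spans highlight spans for the chart's sequences.
#' @param features a [build_patient_features()] record for the same patient
#'   (computed from the chart when `NULL`).
#' @param sparse_note_threshold minimum note count below which a patient
#'   with no evidence is undetermined.
#' @return list of class `label_suggestion` with `label` and `rationale`.
#' @export
suggest_label <- function(chart, spans, features = NULL, sparse_note_threshold = 3L) {
  stopifnot(inherits(chart, "patient_chart"))
  if (is.null(features)) features <- build_patient_features(chart)
  if (!identical(features$patient_id, chart$patient$patient_id)) {
    stop("features belong to a different patient than the chart")
  }
  suggestion <- function(label, rationale) {
    structure(list(label = label, rationale = rationale), class = "label_suggestion")
  }
  if (features$dementia_icd_flag || features$dementia_med_flag) {
    rat <- c(
      if (features$dementia_icd_flag)
        sprintf("dementia_icd_code [%s]", paste(features$dementia_icd_hits, collapse = ", ")),
      if (features$dementia_med_flag)
        sprintf("dementia_medication [%s]", paste(features$dementia_med_hits, collapse = ", "))
    )
    return(suggestion("CI", rat))
  }
  cog <- spans[spans$category == "cognition", , drop = FALSE]
  cog_date <- chart$notes$date[match(cog$note_id, chart$notes$note_id)]
  has_imp <- any(cog$polarity == "impaired")
  has_int <- any(cog$polarity == "intact")
  if (has_imp && has_int) {
    last_imp <- max(cog_date[cog$polarity == "impaired"])
    last_int <- max(cog_date[cog$polarity == "intact"])
    if (last_int > last_imp) {
      return(suggestion("CN", sprintf("latest_evidence_intact [%s]", format(last_int))))
    }
    return(suggestion("CI", sprintf("latest_evidence_impaired [%s]", format(last_imp))))
  }
  if (has_imp) return(suggestion("CI", "impaired_cognition_keyword"))
  if (has_int) return(suggestion("CN", "intact_cognition_keyword"))
  if (features$n_notes < sparse_note_threshold) {
    return(suggestion("undetermined", "sparse_chart"))
  }
  suggestion("CN", "implicit_evidence")
}

#' @export
print.label_suggestion <- function(x, ...) {
  cat(sprintf("<label_suggestion> %s\n  rationale: %s\n", x$label,
              paste(x$rationale, collapse = "; ")))
  invisible(x)
}

#' Create an annotation session store
#'
#' An append-only in-memory store of annotation records, serialisable to a
#' JSONL session file. The latest record per (patient, annotator) pair is
#' authoritative; earlier records are retained for audit.
#'
#' @param assignments an [assign_patients()] data.frame, or `NULL` to accept
#'   any (patient, annotator) pair.
#' @return an `annotation_store` environment.
#' @export
new_session <- function(assignments = NULL) {
  store <- new.env(parent = emptyenv())
  store$records <- empty_annotation_records()
  store$assignments <- assignments
  class(store) <- "annotation_store"
  store
}

empty_annotation_records <- function() {
  data.frame(patient_id = character(0), annotator_id = character(0),
             label = character(0), confidence = character(0),
             started_at = character(0), saved_at = character(0),
             duration_min = numeric(0), stringsAsFactors = FALSE)
}

#' Record an annotation
#'
#' Appends a label record with its adjudication duration. Fails when the
#' annotator is not assigned the patient. Re-annotation appends a new
#' record; nothing is ever mutated or deleted.
#'
#' @param store an `annotation_store`.
#' @param patient_id,annotator_id identifiers.
#' @param label one of CN, CI, undetermined.
#' @param duration_min adjudication time in minutes (> 0); computed from
#'   `started_at`/`saved_at` when those are supplied instead.
#' @param confidence optional low/medium/moderate/high grade.
#' @param started_at,saved_at optional ISO-8601 timestamps.
#' @return the store, invisibly.
#' @export
record_annotation <- function(store, patient_id, annotator_id, label,
                              duration_min = NULL, confidence = NA_character_,
                              started_at = NA_character_, saved_at = NA_character_) {
  stopifnot(inherits(store, "annotation_store"))
  if (!label %in% LABELS) stop(sprintf("unknown label '%s'", label))
  if (!is.na(confidence) && !confidence %in% CONFIDENCE_LEVELS) {
    stop(sprintf("unknown confidence grade '%s'", confidence))
  }
  asg <- store$assignments
  if (!is.null(asg) &&
      !any(asg$patient_id == patient_id & asg$annotator_id == annotator_id)) {
    stop(sprintf("annotator '%s' is not assigned patient '%s'",
                 annotator_id, patient_id))
  }
  if (is.null(duration_min)) {
    if (is.na(started_at) || is.na(saved_at)) {
      stop("either duration_min or both started_at and saved_at are required")
    }
    duration_min <- as.numeric(difftime(as.POSIXct(saved_at, tz = "UTC"),
                                        as.POSIXct(started_at, tz = "UTC"),
                                        units = "mins"))
  }
  if (!is.finite(duration_min) || duration_min <= 0) {
    stop("duration_min must be a positive number of minutes")
  }
  rec <- data.frame(patient_id = patient_id, annotator_id = annotator_id,
                    label = label, confidence = confidence,
                    started_at = started_at, saved_at = saved_at,
                    duration_min = duration_min, stringsAsFactors = FALSE)
  store$records <- rbind(store$records, rec)
  rownames(store$records) <- NULL
  invisible(store)
}

#' Latest authoritative annotation per (patient, annotator)
#'
#' @param store an `annotation_store`.
#' @return data.frame of the last-recorded label per pair.
#' @export
latest_annotations <- function(store) {
  rec <- store$records
  if (!nrow(rec)) return(rec)
  key <- paste(rec$patient_id, rec$annotator_id, sep = "\r")
  last <- !duplicated(key, fromLast = TRUE)
  out <- rec[last, , drop = FALSE]
  out <- out[stable_order(out$patient_id, out$annotator_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a session to a JSONL file
#'
#' @param store an `annotation_store`.
#' @param path output file; one JSON record per line.
#' @return `path`, invisibly.
#' @export
write_session <- function(store, path) {
  rec <- store$records
  lines <- vapply(seq_len(nrow(rec)), function(i) {
    jsonlite::toJSON(as.list(rec[i, , drop = FALSE]), auto_unbox = TRUE,
                     na = "null", digits = NA)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a session JSONL file
#'
#' @param path session file written by [write_session()].
#' @param assignments optional assignment table to enforce on later appends.
#' @return an `annotation_store`.
#' @export
read_session <- function(path, assignments = NULL) {
  store <- new_session(assignments)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      data.frame(patient_id = x$patient_id, annotator_id = x$annotator_id,
                 label = x$label, confidence = x$confidence %||% NA_character_,
                 started_at = x$started_at %||% NA_character_,
                 saved_at = x$saved_at %||% NA_character_,
                 duration_min = as.numeric(x$duration_min),
                 stringsAsFactors = FALSE)
    })
    store$records <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  store
}

#' Dashboard summary rows
#'
#' One row per assigned patient: demographics, note and keyword-match
#' counts, per-class note counts from the ranking, and the patient's
#' current label (or "unlabeled"). Rows are sorted by patient id.
#'
#' @param assignments [assign_patients()] table.
#' @param charts named list of `patient_chart` objects.
#' @param features named list of `patient_features`.
#' @param rankings named list of [rank_notes()] outputs.
#' @param store an `annotation_store` (optional).
#' @return data.frame of dashboard rows.
#' @export
dashboard_summary <- function(assignments, charts, features, rankings,
                              store = NULL) {
  ids <- sort(unique(assignments$patient_id))
  labels <- if (!is.null(store)) latest_annotations(store) else NULL
  rows <- lapply(ids, function(pid) {
    ch <- charts[[pid]]
    f <- features[[pid]]
    rk <- rankings[[pid]]
    age <- if (!is.na(ch$period_end) && !is.na(ch$patient$birth_date)) {
      floor(as.numeric(ch$period_end - ch$patient$birth_date) / 365.25)
    } else NA_real_
    lab <- "unlabeled"
    if (!is.null(labels) && nrow(labels)) {
      mine <- labels$label[labels$patient_id == pid]
      if (length(mine)) lab <- mine[length(mine)]
    }
    class_count <- function(cl) if (is.null(rk)) 0L else sum(rk$class == cl)
    data.frame(patient_id = pid, age = age, sex = ch$patient$sex,
               n_notes = nrow(ch$notes),
               cognition_seq_count = f$cognition_seq_count,
               adl_seq_count = f$adl_seq_count,
               n_notes_ci = class_count("CI"),
               n_notes_no_ci = class_count("no_CI"),
               n_notes_neither = class_count("neither"),
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
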
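# EHR chart data model: a "patient_chart" aggregates one patient's
# demographics plus all dated clinical records inside a study period.
# Each record kind is a plain data.frame with a fixed column schema so that
# chart bundles round-trip through flat CSV files.

SEX_LEVELS <- c("male", "female", "other", "missing")
ETHNIC_LEVELS <- c("black", "hispanic", "asian", "indigenous", "white", "other", "missing")
MARITAL_LEVELS <- c("married", "not_married", "missing")
EDUCATION_LEVELS <- c("college_or_more", "less_than_college", "missing")
ENCOUNTER_STATUS <- c("completed", "no_show", "cancelled")
ICD_SYSTEMS <- c("ICD9", "ICD10")
IMAGING_MODALITIES <- c("MRI", "CT", "other")

# Column schema for each bundle table. `date_cols` are parsed strictly as
# YYYY-MM-DD; `required` marks tables that must exist in every bundle.
bundle_schema <- function() {
  list(
    patients = list(
      file = "patients.csv", required = TRUE,
      cols = c("patient_id", "birth_date", "sex", "ethnic_group", "marital_status",
               "education", "pcp_id", "care_coordination_note"),
      date_cols = "birth_date"
    ),
    notes = list(
      file = "notes.csv", required = TRUE,
      cols = c("note_id", "patient_id", "date", "reason_for_visit", "text",
               "encounter_type", "provider_department", "provider_specialty",
               "provider_qualifications"),
      date_cols = "date"
    ),
    encounters = list(
      file = "encounters.csv", required = FALSE,
      cols = c("encounter_id", "patient_id", "date", "status", "kind"),
      date_cols = "date"
    ),
    medications = list(
      file = "medications.csv", required = FALSE,
      cols = c("patient_id", "name", "date", "current"),
      date_cols = "date", optional_date = "date"
    ),
    diagnoses = list(
      file = "diagnoses.csv", required = FALSE,
      cols = c("patient_id", "code", "system", "description", "date"),
      date_cols = "date", optional_date = "date"
    ),
    labs = list(
      file = "labs.csv", required = FALSE,
      cols = c("patient_id", "test_name", "value", "units", "date"),
      date_cols = "date"
    ),
    imaging = list(
      file = "imaging.csv", required = FALSE,
      cols = c("patient_id", "modality", "body_site", "date"),
      date_cols = "date"
    ),
    refills = list(
      file = "refills.csv", required = FALSE,
      cols = c("patient_id", "date", "medication_name"),
      date_cols = "date"
    )
  )
}

empty_table <- function(kind) {
  sch <- bundle_schema()[[kind]]
  out <- lapply(sch$cols, function(col) {
    if (col %in% sch$date_cols) as.Date(character(0))
    else if (col == "current") logical(0)
    else character(0)
  })
  names(out) <- sch$cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

RECORD_KINDS <- c("notes", "encounters", "medications", "diagnoses", "labs",
                  "imaging", "refills")

#' Construct a patient chart
#'
#' Bundles one patient's demographics with their clinical records over a
#' study period. All child tables must reference `patient$patient_id`; notes
#' are sorted ascending by date with ties broken by `note_id`.
#'
#' @param patient one-row data.frame with the patient-table columns.
#' @param notes,encounters,medications,diagnoses,labs,imaging,refills record
#'   data.frames following the bundle schema (missing -> empty).
#' @param period_start,period_end study-period bounds (dates), or `NA` when
#'   the chart has not been period-filtered yet.
#' @return an object of class `patient_chart`.
#' @export
patient_chart <- function(patient, notes = empty_table("notes"),
                          encounters = empty_table("encounters"),
                          medications = empty_table("medications"),
                          diagnoses = empty_table("diagnoses"),
                          labs = empty_table("labs"),
                          imaging = empty_table("imaging"),
                          refills = empty_table("refills"),
                          period_start = as.Date(NA), period_end = as.Date(NA)) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1L)
  pid <- patient$patient_id
  if (!nzchar(pid)) stop("patient_id must be nonempty")
  chart <- structure(
    list(patient = patient, notes = notes, encounters = encounters,
         medications = medications, diagnoses = diagnoses, labs = labs,
         imaging = imaging, refills = refills,
         period_start = as_date_strict(period_start),
         period_end = as_date_strict(period_end)),
    class = "patient_chart"
  )
  validate_chart(chart)
}

validate_chart <- function(chart) {
  pid <- chart$patient$patient_id
  for (kind in RECORD_KINDS) {
    tab <- chart[[kind]]
    if (nrow(tab) && any(tab$patient_id != pid)) {
      stop(sprintf("%s table contains records for a different patient than '%s'",
                   kind, pid))
    }
  }
  if (anyDuplicated(chart$notes$note_id)) {
    stop(sprintf("duplicate note_id in chart for patient '%s'", pid))
  }
  bd <- chart$patient$birth_date
  if (!is.na(bd)) {
    for (kind in RECORD_KINDS) {
      d <- chart[[kind]]$date
      if (length(d) && any(!is.na(d) & d <= bd)) {
        stop(sprintf("patient '%s' has records dated on or before birth_date", pid))
      }
    }
  }
  if (nrow(chart$notes)) {
    ord <- stable_order(chart$notes$date, chart$notes$note_id)
    chart$notes <- chart$notes[ord, , drop = FALSE]
    rownames(chart$notes) <- NULL
  }
  chart
}

#' @export
print.patient_chart <- function(x, ...) {
  cat(sprintf("<patient_chart> %s (%s, born %s)\n", x$patient$patient_id,
              x$patient$sex, format(x$patient$birth_date)))
  cat(sprintf("  period: %s .. %s\n", format(x$period_start), format(x$period_end)))
  for (kind in RECORD_KINDS) cat(sprintf("  %-12s %d\n", kind, nrow(x[[kind]])))
  invisible(x)
}

#' Restrict a chart to a study period
#'
#' Keeps exactly the records with `start <= date <= end`. Undated records
#' (current medications, undated problem-list entries) are retained, since
#' they describe present state rather than a dated event.
#'
#' @param chart a `patient_chart`.
#' @param start,end inclusive period bounds.
#' @return the filtered `patient_chart` with `period_start`/`period_end` set.
#' @export
filter_period <- function(chart, start, end) {
  stopifnot(inherits(chart, "patient_chart"))
  start <- assert_scalar_date(start, "start")
  end <- assert_scalar_date(end, "end")
  if (start > end) stop("invalid period window: start is after end")
  for (kind in RECORD_KINDS) {
    tab <- chart[[kind]]
    if (nrow(tab)) {
      keep <- is.na(tab$date) | (tab$date >= start & tab$date <= end)
      chart[[kind]] <- tab[keep, , drop = FALSE]
      rownames(chart[[kind]]) <- NULL
    }
  }
  chart$period_start <- start
  chart$period_end <- end
  validate_chart(chart)
}

#' Segment a clinical note into bounded sequences
#'
#' Splits note text into contiguous character ranges of at most `max_len`
#' characters, preferring sentence boundaries, then whitespace, and hard
#' splitting only when a single unbreakable run exceeds `max_len`. The
#' concatenation of the sequence texts reconstructs the note text exactly.
#' Offsets are 0-based half-open.
#'
#' @param note a one-row data.frame with at least `note_id` and `text`.
#' @param max_len maximum characters per sequence (>= 32).
#' @return data.frame with columns note_id, seq_index, start, end, text.
#' @export
segment_note <- function(note, max_len = 512L) {
  stopifnot(max_len >= 32L)
  text <- enc2utf8(as.character(note$text))
  n <- nchar(text)
  empty <- data.frame(note_id = character(0), seq_index = integer(0),
                      start = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || n == 0L) return(empty)

  # Candidate break positions (0-based offsets where a cut may be placed):
  # after sentence-terminating punctuation plus trailing whitespace, or after
  # any whitespace run.
  match_ends <- function(pattern) {
    m <- gregexpr(pattern, text)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) + attr(m, "match.length") - 1L
  }
  sentence_breaks <- match_ends("[.!?]+[\"')\\]]*[[:space:]]+")
  space_breaks <- match_ends("[[:space:]]+")

  starts <- integer(0)
  ends <- integer(0)
  pos <- 0L  # 0-based current start
  while (pos < n) {
    limit <- min(pos + max_len, n)
    if (limit == n) {
      cut <- n
    } else {
      ok <- sentence_breaks[sentence_breaks > pos & sentence_breaks <= limit]
      if (!length(ok)) ok <- space_breaks[space_breaks > pos & space_breaks <= limit]
      cut <- if (length(ok)) max(ok) else limit
    }
    starts <- c(starts, pos)
    ends <- c(ends, cut)
    pos <- cut
  }
  data.frame(
    note_id = rep(as.character(note$note_id), length(starts)),
    seq_index = seq_along(starts) - 1L,
    start = starts, end = ends,
    text = substring(text, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Segment every note of a chart
#'
#' @param chart a `patient_chart`.
#' @inheritParams segment_note
#' @return row-bound [segment_note()] output for all notes, in note order.
#' @export
segment_notes <- function(chart, max_len = 512L) {
  stopifnot(inherits(chart, "patient_chart"))
  if (!nrow(chart$notes)) return(segment_note(list(note_id = "x", text = ""), max_len))
  segs <- lapply(seq_len(nrow(chart$notes)), function(i) {
    segment_note(chart$notes[i, , drop = FALSE], max_len)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
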
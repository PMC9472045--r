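# Structured-data feature engineering: dementia medication and ICD-code
# flags, the cognition-relevant laboratory panel, and utilization counts
# (cancellations, no-shows, refill requests relative to total encounters).

DEMENTIA_MED_STEMS <- c("galantamine", "donepezil", "rivastigmine", "memantine")

#' Flag dementia-related medications
#'
#' A medication matches if its name contains one of the cholinesterase
#' inhibitor / memantine stems (galantamine, donepezil, rivastigmine,
#' memantine), case-insensitively, so brand/strength variants are caught.
#'
#' @param meds medication data.frame with a `name` column.
#' @return list(flag = logical, hits = matching names).
#' @export
flag_dementia_medications <- function(meds) {
  name <- if (is.data.frame(meds)) meds$name else as.character(meds)
  if (!length(name)) return(list(flag = FALSE, hits = character(0)))
  low <- tolower(name)
  hit <- Reduce(`|`, lapply(DEMENTIA_MED_STEMS, function(s) grepl(s, low, fixed = TRUE)))
  list(flag = any(hit), hits = name[hit])
}

normalize_icd <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

#' Flag dementia-related diagnosis codes
#'
#' Codes are normalised (dots removed, upper-cased) and matched against the
#' dementia families: ICD-9 prefixes 290, 294, 331 plus the exact code
#' 780.93 (memory loss), and ICD-10 prefixes G30 and G31.
#'
#' @param diagnoses diagnosis data.frame with `code` and `system` columns.
#' @return list(flag = logical, hits = matching codes as written).
#' @export
flag_dementia_icd <- function(diagnoses) {
  if (!is.data.frame(diagnoses) || !nrow(diagnoses)) {
    return(list(flag = FALSE, hits = character(0)))
  }
  norm <- normalize_icd(diagnoses$code)
  icd9 <- diagnoses$system == "ICD9"
  icd10 <- diagnoses$system == "ICD10"
  hit9 <- icd9 & (startsWith(norm, "290") | startsWith(norm, "294") |
                    startsWith(norm, "331") | norm == "78093")
  hit10 <- icd10 & (startsWith(norm, "G30") | startsWith(norm, "G31"))
  hit <- hit9 | hit10
  list(flag = any(hit), hits = diagnoses$code[hit])
}

#' Default cognition-relevant laboratory panel
#'
#' Name stems for vitamin B12, folate and thyroid-stimulating hormone, the
#' reversible-cause work-up surfaced to annotators.
#'
#' @return character vector of case-insensitive name stems.
#' @export
default_lab_panel <- function() {
  c("b12", "cobalamin", "folate", "folic acid", "tsh",
    "thyroid stimulating", "thyroid-stimulating")
}

#' Select cognition-relevant laboratory results
#'
#' @param labs lab data.frame with a `test_name` column.
#' @param panel name stems; a lab is retained when its `test_name` contains
#'   any stem case-insensitively. Original order preserved.
#' @return the matching rows of `labs`.
#' @export
select_relevant_labs <- function(labs, panel = default_lab_panel()) {
  stopifnot(length(panel) >= 1L)
  if (!nrow(labs)) return(labs)
  low <- tolower(labs$test_name)
  keep <- Reduce(`|`, lapply(tolower(panel), function(s) grepl(s, low, fixed = TRUE)))
  out <- labs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Utilization counts and fractions
#'
#' Counts encounter events by status and refill requests, and expresses
#' no-shows, cancellations and refills relative to the total number of
#' scheduled encounters (all statuses). With zero encounters the fractions
#' are undefined (`NA` with `fractions_defined = FALSE`), never zero.
#'
#' @param encounters encounter data.frame with a `status` column.
#' @param refills refill-request data.frame.
#' @return list of counts and fractions.
#' @export
utilization_counts <- function(encounters, refills) {
  n_enc <- nrow(encounters)
  n_ns <- sum(encounters$status == "no_show")
  n_ca <- sum(encounters$status == "cancelled")
  n_rf <- nrow(refills)
  defined <- n_enc > 0L
  frac <- function(k) if (defined) k / n_enc else NA_real_
  list(n_encounters = n_enc, n_no_shows = n_ns, n_cancellations = n_ca,
       n_refill_requests = n_rf,
       frac_no_shows = frac(n_ns), frac_cancellations = frac(n_ca),
       frac_refills = frac(n_rf), fractions_defined = defined)
}

#' Build the engineered feature set for one patient
#'
#' Aggregates the structured-data flags, utilization counts and keyword
#' match summary into the per-patient feature record shown alongside the
#' notes during adjudication. Pure: identical inputs give identical output.
#'
#' @param chart a `patient_chart`.
#' @param match_summary a [count_matches()] result for the same chart
#'   (optional; zero counts assumed when `NULL`).
#' @param classifications sequence classifications for the chart (optional,
#'   accepted for interface completeness; only validated for provenance).
#' @param lab_panel passed to [select_relevant_labs()].
#' @return list of class `patient_features`.
#' @export
build_patient_features <- function(chart, match_summary = NULL,
                                   classifications = NULL,
                                   lab_panel = default_lab_panel()) {
  stopifnot(inherits(chart, "patient_chart"))
  pid <- chart$patient$patient_id
  if (!is.null(match_summary) && !identical(match_summary$patient_id, pid)) {
    stop("match_summary belongs to a different patient than the chart")
  }
  if (!is.null(classifications) && nrow(classifications) &&
      !all(classifications$note_id %in% chart$notes$note_id)) {
    stop("classifications reference notes outside the chart")
  }
  med <- flag_dementia_medications(chart$medications)
  icd <- flag_dementia_icd(chart$diagnoses)
  util <- utilization_counts(chart$encounters, chart$refills)
  structure(c(
    list(patient_id = pid, n_notes = nrow(chart$notes)),
    util,
    list(dementia_med_flag = med$flag, dementia_med_hits = med$hits,
         dementia_icd_flag = icd$flag, dementia_icd_hits = icd$hits,
         relevant_labs = select_relevant_labs(chart$labs, lab_panel),
         cognition_seq_count = match_summary$n_seq_cognition %||% 0L,
         adl_seq_count = match_summary$n_seq_adl %||% 0L)
  ), class = "patient_features")
}

#' Flatten feature records into a table
#'
#' @param features list of `patient_features` objects.
#' @return data.frame, one row per patient, list fields collapsed with ";".
#' @export
feature_table <- function(features) {
  rows <- lapply(features, function(f) {
    data.frame(
      patient_id = f$patient_id, n_notes = f$n_notes,
      n_encounters = f$n_encounters, n_no_shows = f$n_no_shows,
      n_cancellations = f$n_cancellations,
      n_refill_requests = f$n_refill_requests,
      frac_no_shows = f$frac_no_shows,
      frac_cancellations = f$frac_cancellations,
      frac_refills = f$frac_refills,
      dementia_med_flag = f$dementia_med_flag,
      dementia_med_hits = paste(f$dementia_med_hits, collapse = ";"),
      dementia_icd_flag = f$dementia_icd_flag,
      dementia_icd_hits = paste(f$dementia_icd_hits, collapse = ";"),
      n_relevant_labs = nrow(f$relevant_labs),
      cognition_seq_count = f$cognition_seq_count,
      adl_seq_count = f$adl_seq_count,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
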
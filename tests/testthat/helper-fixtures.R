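# Shared fixtures and independent oracles used across the suite.

make_patient <- function(pid = "p1", birth = "1950-06-15", sex = "female",
                         ethnic = "white", marital = "married",
                         education = "college_or_more", pcp = "pcp1") {
  data.frame(patient_id = pid, birth_date = as.Date(birth), sex = sex,
             ethnic_group = ethnic, marital_status = marital,
             education = education, pcp_id = pcp,
             care_coordination_note = NA_character_, stringsAsFactors = FALSE)
}

make_notes <- function(pid, texts, dates) {
  if (!length(texts)) return(natkit:::empty_table("notes"))
  data.frame(note_id = sprintf("%s-n%02d", pid, seq_along(texts)),
             patient_id = pid, date = as.Date(dates),
             reason_for_visit = "visit", text = texts,
             encounter_type = "office visit", provider_department = "medicine",
             provider_specialty = "primary care", provider_qualifications = "MD",
             stringsAsFactors = FALSE)
}

make_chart <- function(pid = "p1", texts = character(), dates = NULL,
                       meds = character(), dx = NULL, encounters = NULL,
                       period = c("2017-01-01", "2018-12-31"), ...) {
  notes <- make_notes(pid, texts, dates %||% rep("2017-06-01", length(texts)))
  med_tab <- if (length(meds)) {
    data.frame(patient_id = pid, name = meds, date = as.Date(NA), current = TRUE,
               stringsAsFactors = FALSE)
  } else natkit:::empty_table("medications")
  dx_tab <- if (!is.null(dx)) {
    data.frame(patient_id = pid, code = dx$code, system = dx$system,
               description = NA_character_, date = as.Date("2017-05-01"),
               stringsAsFactors = FALSE)
  } else natkit:::empty_table("diagnoses")
  enc_tab <- if (!is.null(encounters)) {
    data.frame(encounter_id = sprintf("%s-e%02d", pid, seq_along(encounters)),
               patient_id = pid, date = as.Date("2017-03-01") + seq_along(encounters),
               status = encounters, kind = "ambulatory", stringsAsFactors = FALSE)
  } else natkit:::empty_table("encounters")
  patient_chart(make_patient(pid), notes = notes, medications = med_tab,
                diagnoses = dx_tab, encounters = enc_tab,
                period_start = period[1], period_end = period[2], ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

WORD_POOL <- c("the", "patient", "was", "seen", "today", "for", "routine",
               "care", "and", "follow", "up", "with", "stable", "vitals",
               "plan", "reviewed", "at", "clinic", "visit", "on", "time")

rand_text <- function(n_words, pool = WORD_POOL) {
  paste(sample(pool, n_words, replace = TRUE), collapse = " ")
}

rand_sentences <- function(n_sentences, words_per = 8) {
  paste(vapply(seq_len(n_sentences), function(i) {
    paste0(rand_text(words_per), ".")
  }, ""), collapse = " ")
}

# Exhaustive case-folded substring scan for literal lexicons: the matcher
# must report exactly these occurrences.
brute_spans <- function(text, entries) {
  low <- tolower(text)
  rows <- list()
  for (i in seq_len(nrow(entries))) {
    pat <- tolower(entries$pattern[i])
    len <- nchar(pat)
    if (len == 0 || len > nchar(low)) next
    starts <- integer(0)
    j <- 1L
    while (j <= nchar(low) - len + 1L) {
      if (substr(low, j, j + len - 1L) == pat) {
        starts <- c(starts, j - 1L)
        j <- j + len  # non-overlapping within an entry
      } else j <- j + 1L
    }
    if (length(starts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts, end = starts + len, entry_id = entries$entry_id[i],
        category = entries$category[i], polarity = entries$polarity[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      entry_id = character(0), category = character(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, -(out$end - out$start), out$entry_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Full 2^n sign enumeration of the signed-rank null: the independent oracle
# for the exact two-sided p-value.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(grid %*% r)
  eps <- 1e-9
  p_le <- mean(Ws <= W + eps)
  p_ge <- mean(Ws >= W - eps)
  min(1, 2 * min(p_le, p_ge))
}

# Direct contingency-table kappa, written independently of cohen_kappa().
kappa_brute <- function(a, b) {
  n <- length(a)
  cats <- sort(unique(c(a, b)))
  po <- sum(a == b) / n
  pe <- 0
  for (k in cats) pe <- pe + (sum(a == k) / n) * (sum(b == k) / n)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

literal_lexicon <- function(words) {
  data.frame(entry_id = sprintf("w%02d", seq_along(words)), pattern = words,
             category = rep_len(c("cognition", "adl"), length(words)),
             polarity = rep_len(c("impaired", "intact"), length(words)),
             stringsAsFactors = FALSE)
}
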
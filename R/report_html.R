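# Static HTML reports: a dashboard page listing every patient and one
# annotation page per patient with demographics, engineered features,
# structured records, and the notes in ranked order with highlighted
# keyword spans. Pages are self-contained (inline CSS, no network assets).

REPORT_CSS <- "
body { font-family: sans-serif; margin: 2em; color: #222; }
table { border-collapse: collapse; margin: 1em 0; }
th, td { border: 1px solid #bbb; padding: 4px 10px; text-align: left; }
th { background: #eee; }
.label-CI { background: #fbd5d5; }
.label-CN { background: #d5fbd9; }
.label-undetermined { background: #f2f2d5; }
.label-unlabeled { background: #fff; }
mark[data-category=cognition] { background: #ffd27f; }
mark[data-category=adl] { background: #a8d8ff; }
.note { border: 1px solid #ccc; padding: 8px; margin: 8px 0; white-space: pre-wrap; }
.meta { color: #666; font-size: 90%; }
"

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
         html_escape(title), "</title><style>", REPORT_CSS,
         "</style></head>\n<body>\n", body, "\n</body></html>\n")
}

html_table <- function(df) {
  if (!nrow(df)) return("<p class=\"meta\">none</p>")
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, , drop = FALSE], function(x) html_escape(format(x)), "")
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, "")
  paste0("<table>", head, paste(rows, collapse = "\n"), "</table>")
}

render_note_html <- function(note, sequences, spans) {
  seqs <- sequences[sequences$note_id == note$note_id, , drop = FALSE]
  pieces <- vapply(seq_len(nrow(seqs)), function(i) {
    sp <- spans[spans$note_id == note$note_id &
                  spans$seq_index == seqs$seq_index[i], , drop = FALSE]
    render_highlights(seqs$text[i], sp)
  }, "")
  paste(pieces, collapse = "")
}

#' Render static HTML reports for a processed bundle
#'
#' Writes `dashboard.html` plus one `patient-<id>.html` page per patient.
#' The dashboard mirrors the workload view (note and keyword-match counts,
#' per-class note counts, colour-coded label); patient pages show
#' demographics, engineered features, diagnoses, medications,
#' labs/imaging, and the notes in ranked order with highlighted spans.
#'
#' @param out_dir output directory for the HTML files.
#' @param charts named list of `patient_chart` objects (period-filtered as
#'   processed).
#' @param results per-patient [process_chart()] results (as returned by
#'   [cmd_process()]).
#' @param store optional `annotation_store` supplying current labels.
#' @return `out_dir`, invisibly.
#' @export
cmd_report <- function(out_dir, charts, results, store = NULL) {
  if (is.null(results) || !length(results)) {
    stop("no processed results supplied; run cmd_process first")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- if (!is.null(store)) latest_annotations(store) else NULL
  current_label <- function(pid) {
    if (!is.null(labels) && nrow(labels)) {
      mine <- labels$label[labels$patient_id == pid]
      if (length(mine)) return(mine[length(mine)])
    }
    "unlabeled"
  }

  rows <- character(0)
  for (pid in sort(names(results))) {
    r <- results[[pid]]
    ch <- charts[[pid]]
    lab <- current_label(pid)
    age <- if (!is.na(ch$period_end) && !is.na(ch$patient$birth_date)) {
      floor(as.numeric(ch$period_end - ch$patient$birth_date) / 365.25)
    } else NA
    rows <- c(rows, sprintf(
      '<tr class="label-%s"><td><a href="patient-%s.html">%s</a></td><td>%s</td><td>%s</td><td>%d</td><td>%d</td><td>%d</td><td>%d</td><td>%d</td><td>%d</td><td>%s</td></tr>',
      lab, pid, pid, format(age), ch$patient$sex, nrow(ch$notes),
      r$match_summary$n_seq_cognition, r$match_summary$n_seq_adl,
      sum(r$ranking$class == "CI"), sum(r$ranking$class == "no_CI"),
      sum(r$ranking$class == "neither"), lab))

    body <- c(
      sprintf("<h1>Patient %s</h1>", html_escape(pid)),
      sprintf('<p class="label-%s">Current label: %s (suggested: %s; %s)</p>',
              lab, lab, r$suggestion$label,
              html_escape(paste(r$suggestion$rationale, collapse = "; "))),
      "<h2>Demographics</h2>",
      html_table(data.frame(
        sex = ch$patient$sex, birth_date = format(ch$patient$birth_date),
        ethnic_group = ch$patient$ethnic_group,
        marital_status = ch$patient$marital_status,
        education = ch$patient$education,
        period = sprintf("%s .. %s", format(ch$period_start), format(ch$period_end)),
        stringsAsFactors = FALSE)),
      "<h2>Engineered features</h2>",
      html_table(feature_table(list(r$features))),
      "<h2>Diagnoses</h2>", html_table(ch$diagnoses[, c("code", "system", "description")]),
      "<h2>Medications</h2>", html_table(ch$medications[, c("name", "current")]),
      "<h2>Relevant labs</h2>",
      html_table(r$features$relevant_labs[, c("test_name", "value", "units")]),
      "<h2>Imaging</h2>", html_table(ch$imaging[, c("modality", "body_site")]),
      "<h2>Notes (ranked)</h2>"
    )
    if (!nrow(ch$notes)) {
      body <- c(body, '<p class="meta">no notes in period</p>')
    } else {
      for (i in seq_len(nrow(r$ranking))) {
        nid <- r$ranking$note_id[i]
        note <- ch$notes[ch$notes$note_id == nid, , drop = FALSE]
        body <- c(body, sprintf(
          '<div class="note"><div class="meta">#%d %s | %s | class %s (p_ci %.3f)</div>%s</div>',
          r$ranking$rank[i], html_escape(nid), format(note$date),
          r$ranking$class[i], r$ranking$score[i],
          render_note_html(note, r$sequences, r$spans)))
      }
    }
    writeLines(html_page(paste("Patient", pid), paste(body, collapse = "\n")),
               file.path(out_dir, sprintf("patient-%s.html", pid)),
               useBytes = TRUE)
  }

  dash <- paste0(
    "<h1>Annotation dashboard</h1>\n<table>",
    "<tr><th>patient</th><th>age</th><th>sex</th><th>notes</th>",
    "<th>cognition seqs</th><th>ADL seqs</th><th>CI notes</th>",
    "<th>no_CI notes</th><th>neither notes</th><th>label</th></tr>\n",
    paste(rows, collapse = "\n"), "</table>")
  writeLines(html_page("Annotation dashboard", dash),
             file.path(out_dir, "dashboard.html"), useBytes = TRUE)
  invisible(out_dir)
}
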
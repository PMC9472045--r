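# Chart-bundle I/O. A bundle is a directory holding one CSV per record kind
# plus a plain-text manifest naming the member tables and the covered date
# range. This is the flat-file stand-in for a warehouse extraction, so the
# same cohort can be shipped and reloaded reproducibly.

read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[trimws(m[2L])]] <- trimws(m[3L])
  out
}

write_manifest_file <- function(path, entries) {
  writeLines(sprintf("%s: %s", names(entries), unlist(entries)), path, useBytes = TRUE)
}

# Parse one bundle table, splitting rows into accepted records and a reject
# report (table, row, reason). Malformed dates reject the row rather than
# silently coercing to NA; genuinely optional dates may be blank.
parse_bundle_table <- function(df, kind) {
  sch <- bundle_schema()[[kind]]
  missing_cols <- setdiff(sch$cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("table '%s' is missing required columns: %s",
                 kind, paste(missing_cols, collapse = ", ")))
  }
  df <- df[, sch$cols, drop = FALSE]
  for (col in setdiff(sch$cols, c(sch$date_cols, "current"))) {
    df[[col]] <- as.character(df[[col]])
  }
  if ("current" %in% sch$cols) {
    df$current <- as.logical(df$current)
  }
  reject_reason <- rep(NA_character_, nrow(df))
  for (col in sch$date_cols) {
    raw <- as.character(df[[col]])
    blank <- is.na(raw) | !nzchar(trimws(raw))
    parsed <- as_date_strict(raw)
    bad <- !blank & is.na(parsed)
    if (!is.null(sch$optional_date) && col %in% sch$optional_date) {
      reject_reason[bad & is.na(reject_reason)] <- sprintf("malformed date in '%s'", col)
    } else {
      reject_reason[(bad | blank) & is.na(reject_reason)] <-
        sprintf("missing or malformed date in '%s'", col)
    }
    df[[col]] <- parsed
  }
  if ("patient_id" %in% sch$cols) {
    bad_pid <- is.na(df$patient_id) | !nzchar(df$patient_id)
    reject_reason[bad_pid & is.na(reject_reason)] <- "missing patient_id"
  }
  if ("status" %in% sch$cols) {
    bad <- !df$status %in% ENCOUNTER_STATUS
    reject_reason[bad & is.na(reject_reason)] <- "unknown encounter status"
  }
  keep <- is.na(reject_reason)
  rejects <- if (all(keep)) NULL else data.frame(
    table = kind, row = which(!keep), reason = reject_reason[!keep],
    stringsAsFactors = FALSE
  )
  list(records = df[keep, , drop = FALSE], rejects = rejects)
}

normalize_enum <- function(x, levels) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | !nzchar(x)] <- "missing"
  if (any(!x %in% levels)) x[!x %in% levels] <- "missing"
  x
}

#' Load a chart bundle from disk
#'
#' Reads a bundle directory (CSV tables plus `manifest.txt`), validates every
#' row, and assembles one [patient_chart()] per patient. Unparseable rows are
#' collected into a reject report attached as `attr(x, "rejects")`, never
#' silently dropped. A missing required table or a duplicated `note_id` is
#' fatal.
#'
#' @param path bundle directory.
#' @return a `chart_bundle`: list of `patient_chart` objects (named by
#'   patient id) with attributes `rejects` and `manifest`.
#' @export
load_chart_bundle <- function(path) {
  if (!dir.exists(path)) stop(sprintf("bundle directory '%s' does not exist", path))
  manifest_path <- file.path(path, "manifest.txt")
  manifest <- if (file.exists(manifest_path)) read_manifest(manifest_path) else list()
  sch <- bundle_schema()
  tables <- list()
  rejects <- list()
  for (kind in names(sch)) {
    f <- file.path(path, sch[[kind]]$file)
    if (!file.exists(f)) {
      if (sch[[kind]]$required) stop(sprintf("required table '%s' missing from bundle", sch[[kind]]$file))
      tables[[kind]] <- empty_table(kind)
      next
    }
    raw <- utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = character(0), fileEncoding = "UTF-8")
    parsed <- parse_bundle_table(raw, kind)
    tables[[kind]] <- parsed$records
    if (!is.null(parsed$rejects)) rejects[[kind]] <- parsed$rejects
  }

  pats <- tables$patients
  if (anyDuplicated(pats$patient_id)) stop("duplicate patient_id in patients table")
  if (anyDuplicated(tables$notes$note_id)) stop("duplicate note_id in bundle")
  pats$sex <- normalize_enum(pats$sex, SEX_LEVELS)
  pats$ethnic_group <- normalize_enum(pats$ethnic_group, ETHNIC_LEVELS)
  pats$marital_status <- normalize_enum(pats$marital_status, MARITAL_LEVELS)
  pats$education <- normalize_enum(pats$education, EDUCATION_LEVELS)
  blank_to_na <- function(x) { x[!is.na(x) & !nzchar(x)] <- NA_character_; x }
  pats$pcp_id <- blank_to_na(pats$pcp_id)
  pats$care_coordination_note <- blank_to_na(pats$care_coordination_note)

  # Child rows that reference an unknown patient are rejected, not fatal.
  known <- pats$patient_id
  for (kind in RECORD_KINDS) {
    tab <- tables[[kind]]
    orphan <- !tab$patient_id %in% known
    if (any(orphan)) {
      rejects[[paste0(kind, "_orphan")]] <- data.frame(
        table = kind, row = which(orphan), reason = "unknown patient_id",
        stringsAsFactors = FALSE)
      tables[[kind]] <- tab[!orphan, , drop = FALSE]
    }
  }

  period_start <- if (!is.null(manifest$period_start)) as_date_strict(manifest$period_start) else as.Date(NA)
  period_end <- if (!is.null(manifest$period_end)) as_date_strict(manifest$period_end) else as.Date(NA)

  charts <- lapply(seq_len(nrow(pats)), function(i) {
    pid <- pats$patient_id[i]
    pick <- function(kind) {
      tab <- tables[[kind]]
      out <- tab[tab$patient_id == pid, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    patient_chart(pats[i, , drop = FALSE],
                  notes = pick("notes"), encounters = pick("encounters"),
                  medications = pick("medications"), diagnoses = pick("diagnoses"),
                  labs = pick("labs"), imaging = pick("imaging"),
                  refills = pick("refills"),
                  period_start = period_start, period_end = period_end)
  })
  names(charts) <- pats$patient_id
  reject_df <- if (length(rejects)) do.call(rbind, c(rejects, make.row.names = FALSE)) else
    data.frame(table = character(0), row = integer(0), reason = character(0),
               stringsAsFactors = FALSE)
  structure(charts, class = "chart_bundle", rejects = reject_df, manifest = manifest)
}

#' Write a chart bundle to disk
#'
#' Inverse of [load_chart_bundle()]: serialises a list of charts back to the
#' CSV-plus-manifest layout so that load -> write -> load is the identity.
#'
#' @param charts a `chart_bundle` or plain list of `patient_chart` objects.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_chart_bundle <- function(charts, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sch <- bundle_schema()
  bind_rows0 <- function(lst, kind) {
    lst <- Filter(function(x) is.data.frame(x) && nrow(x) > 0L, lst)
    if (!length(lst)) return(empty_table(kind))
    do.call(rbind, c(lst, make.row.names = FALSE))
  }
  pats <- bind_rows0(lapply(charts, function(ch) ch$patient), "patients")
  tabs <- list(patients = pats)
  for (kind in RECORD_KINDS) {
    tabs[[kind]] <- bind_rows0(lapply(charts, `[[`, kind), kind)
  }
  for (kind in names(sch)) {
    tab <- tabs[[kind]]
    if (is.null(tab)) tab <- empty_table(kind)
    for (col in sch[[kind]]$date_cols) tab[[col]] <- format(tab[[col]], "%Y-%m-%d")
    utils::write.csv(tab, file.path(path, sch[[kind]]$file), row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  }
  ps <- unique(stats::na.omit(vapply(charts, function(ch) format(ch$period_start), "")))
  pe <- unique(stats::na.omit(vapply(charts, function(ch) format(ch$period_end), "")))
  entries <- list(
    bundle_format = "natkit-chart-bundle/1",
    tables = paste(vapply(sch, `[[`, "", "file"), collapse = ", "),
    n_patients = as.character(nrow(pats))
  )
  if (length(ps) == 1L && ps != "NA") entries$period_start <- ps
  if (length(pe) == 1L && pe != "NA") entries$period_end <- pe
  write_manifest_file(file.path(path, "manifest.txt"), entries)
  invisible(path)
}
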
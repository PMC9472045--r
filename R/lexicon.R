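# Regex lexicon matching and highlighting. Two keyword families are
# supported: "cognition" (memory/cognitive status language) and "adl"
# (activities of daily living), each with an "impaired" or "intact"
# polarity. Matching is case-insensitive, per-entry leftmost-longest and
# non-overlapping within an entry (standard POSIX regex semantics), so the
# result is deterministic and independent of entry order.

LEXICON_CATEGORIES <- c("cognition", "adl")
LEXICON_POLARITIES <- c("impaired", "intact")

#' Read a lexicon file
#'
#' @param path CSV with columns entry_id, pattern, category, polarity.
#' @return data.frame of lexicon entries.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("entry_id", "pattern", "category", "polarity")
  if (!all(need %in% names(df))) {
    stop("lexicon file must have columns entry_id, pattern, category, polarity")
  }
  df[, need]
}

#' Default cognition/ADL lexicon
#'
#' A documented reconstruction of cognition- and ADL-related keyword
#' patterns (memory loss, cognitive decline, dementia, intact-cognition
#' phrasing, dressing/bathing/finances/driving/medication management), meant
#' as a working fixture; studies should supply their own curated lexicon via
#' [read_lexicon()].
#'
#' @return data.frame of lexicon entries.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "cognition_adl_lexicon.csv",
                           package = "natkit", mustWork = TRUE))
}

#' Compile a lexicon into a reusable matcher
#'
#' Validates every pattern; an invalid regular expression raises an error
#' naming the offending `entry_id`.
#'
#' @param entries lexicon data.frame (see [read_lexicon()]).
#' @return an object of class `lexicon_matcher`.
#' @export
compile_lexicon <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1L)
  if (anyDuplicated(entries$entry_id)) stop("duplicate entry_id in lexicon")
  bad_cat <- !entries$category %in% LEXICON_CATEGORIES
  if (any(bad_cat)) stop(sprintf("unknown category for entry '%s'",
                                 entries$entry_id[bad_cat][1L]))
  bad_pol <- !entries$polarity %in% LEXICON_POLARITIES
  if (any(bad_pol)) stop(sprintf("unknown polarity for entry '%s'",
                                 entries$entry_id[bad_pol][1L]))
  for (i in seq_len(nrow(entries))) {
    ok <- tryCatch({ grepl(entries$pattern[i], "probe text"); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("lexicon entry '%s' has an invalid pattern: %s",
                          entries$entry_id[i], entries$pattern[i]))
  }
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "lexicon_matcher")
}

#' @export
print.lexicon_matcher <- function(x, ...) {
  tab <- table(x$entries$category, x$entries$polarity)
  cat(sprintf("<lexicon_matcher> %d entries\n", nrow(x$entries)))
  print(tab)
  invisible(x)
}

empty_spans <- function() {
  data.frame(note_id = character(0), seq_index = integer(0),
             start = integer(0), end = integer(0), entry_id = character(0),
             category = character(0), polarity = character(0),
             stringsAsFactors = FALSE)
}

#' Find lexicon matches in one note sequence
#'
#' Reports every non-overlapping leftmost-longest match of every lexicon
#' entry, case-insensitively. Spans are 0-based half-open offsets into the
#' sequence text, sorted by start with longer spans first on ties.
#'
#' @param sequence one-row data.frame with `note_id`, `seq_index`, `text`
#'   (as produced by [segment_note()]), or a bare string.
#' @param matcher a compiled [compile_lexicon()] handle.
#' @return data.frame of highlight spans.
#' @export
find_spans <- function(sequence, matcher) {
  stopifnot(inherits(matcher, "lexicon_matcher"))
  if (is.character(sequence)) {
    sequence <- data.frame(note_id = NA_character_, seq_index = 0L,
                           text = sequence, stringsAsFactors = FALSE)
  }
  text <- as.character(sequence$text)
  if (is.na(text) || !nchar(text)) return(empty_spans())
  ent <- matcher$entries
  out <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    m <- gregexpr(ent$pattern[i], text, ignore.case = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    keep <- len > 0L
    if (!any(keep)) next
    s <- as.integer(m[keep]) - 1L
    out[[i]] <- data.frame(
      note_id = as.character(sequence$note_id),
      seq_index = as.integer(sequence$seq_index),
      start = s, end = s + len[keep],
      entry_id = ent$entry_id[i], category = ent$category[i],
      polarity = ent$polarity[i], stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_spans())
  spans <- do.call(rbind, c(out, make.row.names = FALSE))
  spans <- spans[stable_order(spans$start, -(spans$end - spans$start), spans$entry_id), ,
                 drop = FALSE]
  rownames(spans) <- NULL
  spans
}

#' Find lexicon matches across many sequences
#'
#' @param sequences data.frame of note sequences ([segment_notes()] output).
#' @inheritParams find_spans
#' @return row-bound [find_spans()] results.
#' @export
find_spans_all <- function(sequences, matcher) {
  if (!nrow(sequences)) return(empty_spans())
  res <- lapply(seq_len(nrow(sequences)), function(i) {
    find_spans(sequences[i, , drop = FALSE], matcher)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Per-patient keyword match summary
#'
#' Counts the sequences with at least one cognition match, the sequences
#' with at least one ADL match, and the total spans in each
#' (category, polarity) cell for one chart.
#'
#' @param chart the `patient_chart` the spans were computed from.
#' @param spans highlight spans for that chart.
#' @return list of class `match_summary` with fields `patient_id`,
#'   `n_seq_cognition`, `n_seq_adl`, and `span_counts` (2x2 matrix).
#' @export
count_matches <- function(chart, spans) {
  stopifnot(inherits(chart, "patient_chart"))
  if (nrow(spans) && !all(spans$note_id %in% chart$notes$note_id)) {
    stop("spans reference a note_id not present in the chart")
  }
  seq_key <- paste(spans$note_id, spans$seq_index)
  counts <- matrix(0L, 2, 2, dimnames = list(LEXICON_CATEGORIES, LEXICON_POLARITIES))
  for (cat in LEXICON_CATEGORIES) for (pol in LEXICON_POLARITIES) {
    counts[cat, pol] <- sum(spans$category == cat & spans$polarity == pol)
  }
  structure(list(
    patient_id = chart$patient$patient_id,
    n_seq_cognition = length(unique(seq_key[spans$category == "cognition"])),
    n_seq_adl = length(unique(seq_key[spans$category == "adl"])),
    span_counts = counts
  ), class = "match_summary")
}

#' Render highlighted text
#'
#' Wraps matched regions in `<mark>` tags carrying category and polarity as
#' data attributes. Overlapping spans of the same category are merged;
#' regions covered by both categories are nested with the cognition tag
#' outermost. Stripping the tags ([strip_highlights()]) reproduces the input
#' text exactly.
#'
#' @param text the sequence text.
#' @param spans highlight spans valid for `text`.
#' @return a single marked-up string.
#' @export
render_highlights <- function(text, spans) {
  text <- as.character(text)
  n <- nchar(text)
  if (!nrow(spans)) return(text)
  if (any(spans$start < 0L | spans$end > n | spans$start >= spans$end)) {
    stop("span out of bounds for the supplied text")
  }
  # Per-character labels: for each category, covered? and by which polarity
  # (earliest-starting covering span wins, longer first on ties).
  label <- list()
  for (cat in LEXICON_CATEGORIES) {
    lab <- rep(NA_character_, n)
    sp <- spans[spans$category == cat, , drop = FALSE]
    if (nrow(sp)) {
      sp <- sp[stable_order(sp$start, -(sp$end - sp$start)), , drop = FALSE]
      for (i in rev(seq_len(nrow(sp)))) {
        lab[(sp$start[i] + 1L):sp$end[i]] <- sp$polarity[i]
      }
    }
    label[[cat]] <- lab
  }
  key <- paste(label$cognition, label$adl)
  runs <- rle(key)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  pieces <- character(length(stops))
  for (r in seq_along(stops)) {
    frag <- substring(text, starts[r], stops[r])
    cg <- label$cognition[starts[r]]
    ad <- label$adl[starts[r]]
    if (!is.na(ad)) frag <- sprintf(
      '<mark data-category="adl" data-polarity="%s">%s</mark>', ad, frag)
    if (!is.na(cg)) frag <- sprintf(
      '<mark data-category="cognition" data-polarity="%s">%s</mark>', cg, frag)
    pieces[r] <- frag
  }
  paste(pieces, collapse = "")
}

#' Strip highlight markup
#'
#' @param x marked-up text from [render_highlights()].
#' @return the underlying text with all `<mark>` tags removed.
#' @export
strip_highlights <- function(x) {
  gsub("</?mark[^>]*>", "", x)
}
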
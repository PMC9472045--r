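# Note triage: pluggable sequence classification over {CI, no_CI, neither},
# a self-contained lexicon-score baseline classifier, note-level class
# aggregation, and CI-first note ranking. The classifier contract is simply
# text -> probability triple, so a trained model can be dropped in without
# touching anything downstream.

SEQ_CLASSES <- c("CI", "no_CI", "neither")

#' Baseline lexicon classifier
#'
#' A deterministic stand-in classifier scoring each sequence from its
#' cognition keyword counts: with `c_imp` cognition/impaired and `c_int`
#' cognition/intact matches, scores are
#' `(w_impaired * c_imp, w_intact * c_int, b_neither)` and the probability
#' triple is their softmax.
#'
#' @param matcher a compiled [compile_lexicon()] handle.
#' @param w_impaired,w_intact,b_neither finite scoring constants.
#' @return a classifier handle: `function(text) -> c(p_ci, p_no_ci, p_neither)`.
#' @export
baseline_lexicon_classifier <- function(matcher, w_impaired = 2, w_intact = 2,
                                        b_neither = 1) {
  stopifnot(inherits(matcher, "lexicon_matcher"),
            is.finite(w_impaired), is.finite(w_intact), is.finite(b_neither))
  function(text) {
    spans <- find_spans(as.character(text), matcher)
    c_imp <- sum(spans$category == "cognition" & spans$polarity == "impaired")
    c_int <- sum(spans$category == "cognition" & spans$polarity == "intact")
    s <- c(w_impaired * c_imp, w_intact * c_int, b_neither)
    e <- exp(s - max(s))
    p <- e / sum(e)
    names(p) <- SEQ_CLASSES
    p
  }
}

predict_class <- function(p_ci, p_no_ci, p_neither) {
  # argmax with ties resolved CI > no_CI > neither
  p <- c(p_ci, p_no_ci, p_neither)
  SEQ_CLASSES[which.max(p)]
}

#' Classify note sequences
#'
#' Applies a classifier handle to each sequence and validates the contract:
#' each probability in [0, 1] and the triple summing to 1 within 1e-9. The
#' predicted class is the argmax with ties resolved CI > no_CI > neither.
#'
#' @param sequences data.frame of note sequences ([segment_notes()] output).
#' @param model classifier handle (`function(text) -> numeric(3)`).
#' @return data.frame with note_id, seq_index, p_ci, p_no_ci, p_neither,
#'   predicted, flagged_incorrect.
#' @export
classify_sequences <- function(sequences, model) {
  stopifnot(is.function(model))
  if (!nrow(sequences)) {
    return(data.frame(note_id = character(0), seq_index = integer(0),
                      p_ci = numeric(0), p_no_ci = numeric(0),
                      p_neither = numeric(0), predicted = character(0),
                      flagged_incorrect = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(sequences)), function(i) {
    p <- as.numeric(model(sequences$text[i]))
    if (length(p) != 3L || anyNA(p) || any(p < 0 | p > 1) ||
        abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("classifier returned a non-normalized triple for note '%s' sequence %d",
                   sequences$note_id[i], sequences$seq_index[i]))
    }
    data.frame(note_id = sequences$note_id[i], seq_index = sequences$seq_index[i],
               p_ci = p[1L], p_no_ci = p[2L], p_neither = p[3L],
               predicted = predict_class(p[1L], p[2L], p[3L]),
               flagged_incorrect = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Aggregate sequence classifications to the note level
#'
#' The note score is the maximum `p_ci` over its sequences; the note class
#' is CI if any sequence predicted CI, else no_CI if any predicted no_CI,
#' else neither.
#'
#' @param classifications [classify_sequences()] rows for one note.
#' @return list(class, score).
#' @export
note_level_class <- function(classifications) {
  if (!nrow(classifications)) stop("note has no sequence classifications")
  if (length(unique(classifications$note_id)) != 1L) {
    stop("note_level_class expects classifications of a single note")
  }
  cls <- if (any(classifications$predicted == "CI")) "CI"
         else if (any(classifications$predicted == "no_CI")) "no_CI"
         else "neither"
  list(class = cls, score = max(classifications$p_ci))
}

#' Note-level results for a chart
#'
#' @param classifications [classify_sequences()] output.
#' @param notes the chart's notes table (for dates).
#' @return data.frame with note_id, class, score, date.
#' @export
note_results <- function(classifications, notes) {
  ids <- unique(classifications$note_id)
  rows <- lapply(ids, function(id) {
    nl <- note_level_class(classifications[classifications$note_id == id, , drop = FALSE])
    data.frame(note_id = id, class = nl$class, score = nl$score,
               date = notes$date[match(id, notes$note_id)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Rank notes CI-first
#'
#' Notes with note-level class CI precede all others; within a class, notes
#' are ordered by descending score, then by later date first (latest
#' evidence reviewed first), then by note_id.
#'
#' @param results [note_results()] data.frame.
#' @return the same rows ordered by rank, with a `rank` column prepended.
#' @export
rank_notes <- function(results) {
  if (!nrow(results)) {
    out <- results
    out$rank <- integer(0)
    return(out)
  }
  if (anyDuplicated(results$note_id)) stop("duplicate note_id in ranking input")
  prio <- match(results$class, SEQ_CLASSES)
  ord <- stable_order(prio, -results$score, -as.numeric(results$date), results$note_id)
  out <- results[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
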
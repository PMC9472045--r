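test_that("matching is case-insensitive and invalid patterns name the entry", {
  lex <- data.frame(entry_id = "e1", pattern = "memory", category = "cognition",
                    polarity = "impaired", stringsAsFactors = FALSE)
  m <- compile_lexicon(lex)
  spans <- find_spans("Memory problems; her memory is poor", m)
  expect_equal(nrow(spans), 2)
  expect_equal(spans$start, c(0L, 21L))

  bad <- data.frame(entry_id = "broken", pattern = "((unbalanced",
                    category = "cognition", polarity = "impaired",
                    stringsAsFactors = FALSE)
  expect_error(compile_lexicon(bad), "broken")
})

test_that("an intact-cognition phrase is spanned with the right tags", {
  lex <- data.frame(entry_id = "int1", pattern = "memory function are intact",
                    category = "cognition", polarity = "intact",
                    stringsAsFactors = FALSE)
  txt <- "language, attention, and memory function are intact with good fund of knowledge"
  spans <- find_spans(txt, compile_lexicon(lex))
  expect_equal(nrow(spans), 1)
  expect_equal(spans$category, "cognition")
  expect_equal(spans$polarity, "intact")
  expect_equal(substr(txt, spans$start + 1, spans$end), "memory function are intact")
})

test_that("find_spans equals brute-force substring enumeration on literal lexicons", {
  set.seed(101)
  words <- sample(WORD_POOL, 12)
  lex <- literal_lexicon(words)
  m <- compile_lexicon(lex)
  for (rep in 1:300) {
    txt <- rand_text(sample(5:40, 1))
    got <- find_spans(txt, m)[, c("start", "end", "entry_id", "category", "polarity")]
    want <- brute_spans(txt, lex)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  expect_equal(nrow(find_spans("", m)), 0)
})

test_that("matching is independent of lexicon entry order", {
  set.seed(5)
  lex <- literal_lexicon(sample(WORD_POOL, 8))
  m1 <- compile_lexicon(lex)
  m2 <- compile_lexicon(lex[sample(nrow(lex)), ])
  for (rep in 1:25) {
    txt <- rand_text(30)
    cols <- c("start", "end", "entry_id")
    expect_equal(find_spans(txt, m1)[, cols], find_spans(txt, m2)[, cols],
                 ignore_attr = TRUE)
  }
})

test_that("count_matches tallies sequences and spans per category cell", {
  chart <- make_chart("p1", texts = c("Memory loss noted. Also memory loss again.",
                                      "Routine visit."),
                      dates = c("2017-03-01", "2017-04-01"))
  seqs <- segment_notes(chart, 512)
  lex <- data.frame(entry_id = "e1", pattern = "memory loss",
                    category = "cognition", polarity = "impaired",
                    stringsAsFactors = FALSE)
  spans <- find_spans_all(seqs, compile_lexicon(lex))
  cm <- count_matches(chart, spans)
  expect_equal(cm$n_seq_cognition, 1)   # one sequence holds both matches
  expect_equal(cm$n_seq_adl, 0)
  expect_equal(cm$span_counts["cognition", "impaired"], 2)
  expect_equal(sum(cm$span_counts), 2)

  empty <- count_matches(chart, spans[0, ])
  expect_equal(sum(empty$span_counts), 0)

  alien <- spans
  alien$note_id <- "nope"
  expect_error(count_matches(chart, alien), "note_id")
})

test_that("count_matches equals a brute-force tally on random spans", {
  set.seed(77)
  chart <- make_chart("p1", texts = replicate(5, rand_sentences(3)),
                      dates = sprintf("2017-0%d-01", 1:5))
  seqs <- segment_notes(chart, 64)
  for (rep in 1:20) {
    n <- 200
    idx <- sample(nrow(seqs), n, replace = TRUE)
    spans <- data.frame(
      note_id = seqs$note_id[idx], seq_index = seqs$seq_index[idx],
      start = 0L, end = 1L,
      entry_id = "e", category = sample(c("cognition", "adl"), n, TRUE),
      polarity = sample(c("impaired", "intact"), n, TRUE),
      stringsAsFactors = FALSE)
    cm <- count_matches(chart, spans)
    key <- paste(spans$note_id, spans$seq_index)
    expect_equal(cm$n_seq_cognition, length(unique(key[spans$category == "cognition"])))
    expect_equal(cm$n_seq_adl, length(unique(key[spans$category == "adl"])))
    for (cat in c("cognition", "adl")) for (pol in c("impaired", "intact")) {
      expect_equal(cm$span_counts[cat, pol],
                   sum(spans$category == cat & spans$polarity == pol))
    }
  }
})

test_that("render_highlights wraps spans and stripping restores the text", {
  txt <- "abcdefghijklm"
  expect_identical(render_highlights(txt, natkit:::empty_spans()), txt)

  one <- data.frame(note_id = "n", seq_index = 0L, start = 4L, end = 10L,
                    entry_id = "e", category = "cognition", polarity = "impaired",
                    stringsAsFactors = FALSE)
  out <- render_highlights(txt, one)
  expect_equal(out, paste0("abcd",
    '<mark data-category="cognition" data-polarity="impaired">efghij</mark>', "klm"))
  expect_identical(strip_highlights(out), txt)

  oob <- one
  oob$end <- 99L
  expect_error(render_highlights(txt, oob), "out of bounds")
})

test_that("rendering never alters the underlying text (random spans, overlaps)", {
  set.seed(31)
  for (rep in 1:100) {
    txt <- rand_text(sample(5:30, 1))
    n <- sample(0:6, 1)
    if (n > 0) {
      start <- sample(0:(nchar(txt) - 2), n, replace = TRUE)
      len <- sample(1:8, n, replace = TRUE)
      spans <- data.frame(
        note_id = "n", seq_index = 0L, start = start,
        end = pmin(start + len, nchar(txt)),
        entry_id = "e", category = sample(c("cognition", "adl"), n, TRUE),
        polarity = sample(c("impaired", "intact"), n, TRUE),
        stringsAsFactors = FALSE)
      spans <- spans[spans$end > spans$start, ]
    } else spans <- natkit:::empty_spans()
    out <- render_highlights(txt, spans)
    expect_identical(strip_highlights(out), txt)
  }
})

test_that("overlapping same-category spans merge and cognition nests outermost", {
  txt <- "0123456789"
  spans <- data.frame(
    note_id = "n", seq_index = 0L,
    start = c(1L, 3L), end = c(5L, 8L), entry_id = c("a", "b"),
    category = "cognition", polarity = "impaired", stringsAsFactors = FALSE)
  out <- render_highlights(txt, spans)
  # merged into one continuous highlighted region: one opening tag
  expect_equal(lengths(regmatches(out, gregexpr("<mark", out))), 1)

  both <- data.frame(
    note_id = "n", seq_index = 0L, start = c(2L, 2L), end = c(6L, 6L),
    entry_id = c("c", "d"), category = c("adl", "cognition"),
    polarity = "impaired", stringsAsFactors = FALSE)
  out2 <- render_highlights(txt, both)
  expect_match(out2, 'data-category="cognition"[^>]*><mark data-category="adl"')
  expect_identical(strip_highlights(out2), txt)
})

test_that("the default lexicon compiles and matches its own domains", {
  lex <- default_lexicon()
  m <- compile_lexicon(lex)
  s1 <- find_spans("Progressive memory loss and confusion.", m)
  expect_true(any(s1$category == "cognition" & s1$polarity == "impaired"))
  s2 <- find_spans("Independent in all ADLs and continues to drive.", m)
  expect_true(any(s2$category == "adl" & s2$polarity == "intact"))
})
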
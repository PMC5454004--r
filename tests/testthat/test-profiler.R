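test_that("filled pauses are counted by lexicon lookup, including inside mazes", {
  u <- parse_transcript("She is uh a very uh lovely girl.")$utterances[[1]]
  expect_identical(detect_filled_pauses(u)$count, 2L)
  expect_identical(detect_filled_pauses(u)$positions, c(3L, 6L))

  expect_identical(
    detect_filled_pauses(parse_transcript("He is John.")$utterances[[1]])$count,
    0L)
  expect_identical(
    detect_filled_pauses(parse_transcript("Um uh um.")$utterances[[1]])$count,
    3L)
  expect_identical(
    detect_filled_pauses(parse_transcript("(um he) he said.")$utterances[[1]])$count,
    1L)
})

test_that("repetition detection reproduces the clinical examples", {
  ev <- detect_repetitions(parse_transcript("(He) He is John.")$utterances[[1]])
  expect_length(ev, 1)
  expect_identical(ev[[1]]$unit_length, 1L)
  expect_identical(ev[[1]]$n_copies, 2L)

  ev <- detect_repetitions(parse_transcript("(He is) He is John.")$utterances[[1]])
  expect_length(ev, 1)
  expect_identical(ev[[1]]$unit_length, 2L)

  # fillers may sit between copies without breaking the duplication
  ev <- detect_repetitions(parse_transcript("she is uh she is nice.")$utterances[[1]])
  expect_length(ev, 1)
  expect_identical(ev[[1]]$unit_length, 2L)
  expect_identical(ev[[1]]$fillers_between, 1L)

  expect_length(detect_repetitions(parse_transcript("He is John.")$utterances[[1]]), 0)
  # fillers themselves never form repetition units
  expect_length(detect_repetitions(parse_transcript("um um um.")$utterances[[1]]), 0)
})

test_that("repetition detection matches the brute-force oracle on small alphabets", {
  # exhaustive over all sequences up to length 6 on {a, b, filler}
  for (len in 2:6) {
    seqs <- all_sequences(len, c("a", "b", "F"))
    for (r in seq_len(nrow(seqs))) {
      symbols <- unname(seqs[r, ])
      got <- detect_repetitions(token_frame(symbols))
      want <- brute_repetitions(symbols, symbols == "F")
      expect_identical(event_signature(got), event_signature(want))
    }
  }
  # random longer sequences over a 5-symbol alphabet (4 words + filler)
  set.seed(42)
  for (r in 1:400) {
    len <- sample(7:12, 1)
    symbols <- sample(c("a", "b", "c", "d", "F"), len, replace = TRUE)
    got <- detect_repetitions(token_frame(symbols))
    want <- brute_repetitions(symbols, symbols == "F")
    expect_identical(event_signature(got), event_signature(want))
  }
})

test_that("morpheme counting follows the inflection rule table", {
  morph <- function(txt) count_morphemes(parse_transcript(txt)$utterances[[1]])
  expect_identical(morph("Yes."), 1L)
  expect_identical(morph("He is John."), 3L)
  expect_identical(morph("dogs running"), 4L)   # dog+s, run+ing
  expect_identical(morph("I don't know."), 4L)  # don't = do + n't
  expect_identical(morph("John's dog walked."), 5L)
  # fillers and maze material count zero
  expect_identical(morph("uh um."), 0L)
  expect_identical(morph("(He is) He is John."), 3L)
})

test_that("segments divide the token stream near-equally, remainder first", {
  words <- function(n) paste(paste(rep("w", n), collapse = " "), ".")
  # 100 tokens in 10-token utterances -> five 20-token segments
  t100 <- parse_transcript(paste(rep(words(10), 10), collapse = "\n"))
  segs <- split_segments(t100, 5)
  expect_identical(vapply(segs, function(s) length(s$utterances), 1L),
                   rep(2L, 5))

  # 103 tokens -> spans 21,21,21,20,20; utterances follow their first token
  t103 <- parse_transcript(paste(rep(words(1), 103), collapse = "\n"))
  segs <- split_segments(t103, 5)
  expect_identical(vapply(segs, function(s) length(s$utterances), 1L),
                   c(21L, 21L, 21L, 20L, 20L))

  expect_length(split_segments(t103, 1), 1)
  expect_length(split_segments(t103, 1)[[1]]$utterances, 103)
  expect_error(split_segments(parse_transcript("a b."), 5), "segments")
})

test_that("the default schema emits 88 features with consistent blocks", {
  schema <- default_feature_schema()
  expect_length(schema$names, 88)
  expect_false(anyDuplicated(schema$names) > 0)

  # empty transcript -> all zeros
  p0 <- profile_transcript(parse_transcript(""))
  expect_length(p0, 88)
  expect_true(all(p0 == 0))

  t <- parse_transcript(paste(
    "She is uh a very uh lovely girl.",
    "(He is) He is John.",
    "What is his name?",
    "I don't know!",
    "Yes.", sep = "\n"))
  p <- profile_transcript(t)
  expect_identical(unname(p["n_utterances"]), 5)
  expect_identical(unname(p["n_statements"]), 3)
  expect_identical(unname(p["n_questions"]), 1)
  expect_identical(unname(p["n_exclamations"]), 1)
  expect_identical(unname(p["n_filled_pauses"]), 2)
  expect_identical(unname(p["n_repetitions"]), 1)
  expect_identical(unname(p["n_phrase_repetitions"]), 1)
  expect_identical(unname(p["n_repeated_words"]), 2)
  expect_identical(unname(p["n_one_word"]), 1)

  # length bins partition the utterances
  expect_equal(unname(p["n_short"] + p["n_medium"] + p["n_long"]),
               unname(p["n_utterances"]))
  # terminators partition too
  expect_equal(unname(p["n_statements"] + p["n_questions"] + p["n_exclamations"]),
               unname(p["n_utterances"]))
  # repeated-word percentage consistency
  expect_equal(unname(p["p_repeated_words"]),
               unname(100 * p["n_repeated_words"] / p["n_words"]))
  # segment blocks sum to the global block
  seg_sum <- function(feat) sum(p[paste0("seg", 1:5, "_", feat)])
  expect_equal(seg_sum("n_words"), unname(p["n_words"]))
  expect_equal(seg_sum("n_filled_pauses"), unname(p["n_filled_pauses"]))
  expect_equal(seg_sum("n_repetitions"), unname(p["n_repetitions"]))
  expect_equal(seg_sum("n_utterances"), unname(p["n_utterances"]))
})

test_that("profiles are invariant to letter case", {
  txt <- "She is uh a VERY uh lovely girl.\n(HE IS) he is John.\nYES.\n"
  expect_equal(profile_transcript(parse_transcript(txt)),
               profile_transcript(parse_transcript(tolower(txt))))
})

test_that("maze tokens are excluded from words/MLU but repetitions still count", {
  p <- profile_transcript(parse_transcript("(He is) He is John.\n"))
  expect_identical(unname(p["n_words"]), 3)     # maze excluded
  expect_identical(unname(p["n_morphemes"]), 3)
  expect_identical(unname(p["n_repeated_words"]), 2)
  expect_identical(unname(p["n_repetitions"]), 1)
})

test_that("profile_corpus reports failures but continues", {
  dir <- withr::local_tempdir()
  writeLines("He is John.", file.path(dir, "ok.txt"))
  manifest <- data.frame(
    participant_id = c("ok", "missing"),
    transcript_path = c(file.path(dir, "ok.txt"), file.path(dir, "nope.txt")),
    group_label = "x", stringsAsFactors = FALSE)
  expect_warning(out <- profile_corpus(manifest), "missing")
  expect_identical(out$participant_id, "ok")
  expect_length(attr(out, "failures"), 1)
  expect_identical(ncol(out), 89L)  # id + 88 features
})
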
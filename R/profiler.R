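# Automatic extraction of the 88-feature linguistic profile.
#
# Feature definitions follow standard clinical language-sample conventions:
# filled pauses are lexicon hits; a repetition is the exact duplication of a
# linguistic unit of any length with only fillers allowed between copies;
# utterance length is measured in morphemes; maze-annotated tokens are
# excluded from word counts, MLU and length bins (dysfluent, not
# propositional material) but their duplicated words still count as repeated
# words.

#' Default morpheme-counting rule table
#'
#' A deterministic approximation of Brown/SALT-style morpheme conventions:
#' every word token counts 1; regular inflections (plural/3rd-person `-s`,
#' `-ed`, `-ing`) and each contraction/possessive part following an
#' apostrophe add 1. Suffix rules require a minimum stem length
#' (so "yes", "is", "red" stay monomorphemic) and honour small exception
#' lists for common non-inflected forms. Fillers count 0.
#'
#' @return list with `min_stem` and per-suffix exception vectors; pass a
#'   modified copy to [count_morphemes()] to change conventions.
#' @export
default_morpheme_rules <- function() {
  list(
    min_stem = 3L,
    s_exceptions = c("this", "his", "hers", "ours", "yours", "theirs", "its",
                     "is", "was", "has", "does", "goes", "yes", "as", "us",
                     "thus", "perhaps", "always", "sometimes", "news",
                     "various", "famous", "nervous"),
    ed_exceptions = c("indeed", "hundred", "need", "feed", "speed", "seed"),
    ing_exceptions = c("thing", "something", "nothing", "anything",
                       "everything", "during", "morning", "evening")
  )
}

count_morphemes_word <- function(w, rules) {
  if (!nzchar(w)) return(0L)
  parts <- strsplit(w, "'", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  extra <- max(length(parts) - 1L, 0L)
  base <- if (length(parts)) parts[1] else w
  m <- 1L + extra
  nb <- nchar(base)
  if (endsWith(base, "ing") && nb - 3L >= rules$min_stem &&
      !(base %in% rules$ing_exceptions)) {
    m <- m + 1L
  } else if (endsWith(base, "ed") && nb - 2L >= rules$min_stem &&
             !(base %in% rules$ed_exceptions)) {
    m <- m + 1L
  } else if (endsWith(base, "s") && !endsWith(base, "ss") &&
             nb - 1L >= rules$min_stem && !(base %in% rules$s_exceptions)) {
    m <- m + 1L
  }
  m
}

#' Count morphemes in an utterance
#'
#' Morphemes are counted over non-maze word tokens only; filler tokens count
#' zero. See [default_morpheme_rules()] for the rule table.
#'
#' @param u an utterance (list with a `tokens` data frame) or a token data
#'   frame.
#' @param rules morpheme rule table.
#' @return nonnegative integer morpheme count.
#' @export
#' @examples
#' u <- parse_transcript("He is John.")$utterances[[1]]
#' count_morphemes(u)  # 3
count_morphemes <- function(u, rules = default_morpheme_rules()) {
  tk <- if (is.data.frame(u)) u else u$tokens
  use <- !tk$in_maze & !tk$is_filler
  if (!any(use)) return(0L)
  sum(vapply(tk$normalized[use], count_morphemes_word, integer(1),
             rules = rules, USE.NAMES = FALSE))
}

#' Detect filled pauses in an utterance
#'
#' Every token whose normalized form is in the lexicon is counted, including
#' tokens inside mazes.
#'
#' @param u utterance or token data frame.
#' @param lexicon filler lexicon.
#' @return list with `count` and integer `positions` (token offsets).
#' @export
detect_filled_pauses <- function(u, lexicon = default_filler_lexicon()) {
  tk <- if (is.data.frame(u)) u else u$tokens
  hit <- tk$normalized %in% tolower(lexicon)
  list(count = sum(hit), positions = which(hit))
}

#' Detect repetition events in an utterance
#'
#' Finds exact duplications of token units of length `1..max_unit`, matching
#' on normalized forms, where only filler tokens may appear between copies.
#' Filler tokens can never be part of a repetition unit. Longest units take
#' precedence and are scanned left to right; tokens consumed by an accepted
#' event cannot seed or extend another event, so word- and phrase-level
#' counts are disjoint.
#'
#' @param u utterance or token data frame.
#' @param max_unit maximum unit length in tokens (default 6).
#' @return list of events, each with `unit_length`, `start_index`,
#'   `n_copies` (>= 2, copies in the maximal run), `fillers_between` (total
#'   interposed fillers) and `positions` (token offsets of all copies). The
#'   conventional repetition count of an event is `n_copies - 1`.
#' @export
#' @examples
#' u <- parse_transcript("(He is) He is John.")$utterances[[1]]
#' detect_repetitions(u)[[1]]$unit_length  # 2
detect_repetitions <- function(u, max_unit = 6L) {
  stopifnot(max_unit >= 1L)
  tk <- if (is.data.frame(u)) u else u$tokens
  norm <- tk$normalized
  filler <- tk$is_filler
  n <- length(norm)
  events <- list()
  if (n < 2L) return(events)
  consumed <- logical(n)
  for (L in seq(min(max_unit, n %/% 2L), 1L)) {
    i <- 1L
    while (i + 2L * L - 1L <= n) {
      idx <- i:(i + L - 1L)
      if (any(filler[idx]) || any(consumed[idx])) {
        i <- i + 1L
        next
      }
      copies <- 1L
      fillers_between <- 0L
      positions <- idx
      j <- i + L
      repeat {
        k <- j
        while (k <= n && filler[k]) k <- k + 1L
        if (k + L - 1L > n) break
        cand <- k:(k + L - 1L)
        if (any(filler[cand]) || any(consumed[cand])) break
        if (!all(norm[cand] == norm[idx])) break
        copies <- copies + 1L
        fillers_between <- fillers_between + (k - j)
        positions <- c(positions, cand)
        j <- k + L
      }
      if (copies >= 2L) {
        events[[length(events) + 1L]] <- list(
          unit_length = L, start_index = i, n_copies = copies,
          fillers_between = fillers_between, positions = positions)
        consumed[positions] <- TRUE
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(events) > 1L) {
    events <- events[order(vapply(events, `[[`, 1L, "start_index"))]
  }
  events
}

#' Split a transcript into contiguous equal-length segments
#'
#' The token stream (all tokens, including mazes) is divided into `k`
#' contiguous spans whose token counts differ by at most one, extra tokens
#' going to the earliest spans. An utterance belongs to the segment that
#' holds its first token. Division is by text length, not time: transcripts
#' carry no timestamps.
#'
#' @param t an `fx_transcript`.
#' @param k number of segments (default 5).
#' @return list of `k` `fx_transcript` objects (participant ids suffixed
#'   `_seg<i>`).
#' @export
split_segments <- function(t, k = 5L) {
  stopifnot(inherits(t, "fx_transcript"), k >= 1L)
  n_tok <- vapply(t$utterances, function(u) nrow(u$tokens), integer(1))
  total <- sum(n_tok)
  if (k > total) {
    stop(sprintf("cannot split %d tokens into %d segments", total, k))
  }
  seg <- segment_assignment(n_tok, k)
  lapply(seq_len(k), function(s) {
    structure(list(participant_id = paste0(t$participant_id, "_seg", s),
                   utterances = t$utterances[seg == s],
                   source_mode = t$source_mode),
              class = "fx_transcript")
  })
}

# assign utterances to k token-quintile segments; returns integer vector.
# Allows empty segments (used by the profiler on very short transcripts).
segment_assignment <- function(n_tok, k) {
  if (!length(n_tok)) return(integer(0))
  total <- sum(n_tok)
  if (total == 0L) return(rep(1L, length(n_tok)))
  base <- total %/% k
  sizes <- rep(base, k)
  rem <- total %% k
  if (rem > 0L) sizes[seq_len(rem)] <- base + 1L
  offsets <- cumsum(sizes)
  first_tok <- cumsum(c(1L, head(n_tok, -1L)))
  # utterances with zero tokens inherit the segment of the previous position
  first_tok <- pmin(first_tok, total)
  vapply(first_tok, function(f) which(f <= offsets)[1L], integer(1))
}

#' Default 88-feature linguistic schema
#'
#' 28 global features plus 12 features for each of 5 token-quintile
#' segments. Length bins are in morphemes: short <= 5, medium 6-10,
#' long >= 11 (so the bins partition the utterances). The schema is
#' versioned; alternative schemas can be passed to [profile_transcript()].
#'
#' @param k number of segments (default 5).
#' @param bins numeric length-bin boundaries `c(short_max, medium_max)`.
#' @return `fx_schema` list with `version`, `names`, `bins`, `k`.
#' @export
default_feature_schema <- function(k = 5L, bins = c(5, 10)) {
  global <- c(
    "n_utterances", "n_statements", "n_questions", "n_exclamations",
    "n_words", "n_morphemes", "mlu", "n_one_word",
    "n_short", "n_medium", "n_long", "p_short", "p_medium", "p_long",
    "n_filled_pauses", "filled_pauses_per_100_words",
    "n_repetitions", "n_word_repetitions", "n_phrase_repetitions",
    "n_repeated_words", "p_repeated_words", "repetitions_per_utterance",
    "n_utt_with_repetition", "p_utt_with_repetition",
    "n_dysfluent_short", "n_dysfluent_medium", "n_dysfluent_long",
    "dysfluencies_per_100_words")
  segment <- c("n_utterances", "n_words", "mlu",
               "n_filled_pauses", "filled_pauses_per_100_words",
               "n_repetitions", "n_repeated_words", "p_repeated_words",
               "n_short", "n_medium", "n_long", "repetitions_per_utterance")
  names <- c(global,
             unlist(lapply(seq_len(k), function(s) paste0("seg", s, "_", segment))))
  structure(list(version = sprintf("fx88-1.0/k%d", k), names = names,
                 bins = bins, k = k,
                 n_global = length(global), n_segment = length(segment)),
            class = "fx_schema")
}

#' @export
print.fx_schema <- function(x, ...) {
  cat(sprintf("<fx_schema> %s: %d features (%d global + %d x %d segment), bins <=%g / %g-%g / >=%g\n",
              x$version, length(x$names), x$n_global, x$k, x$n_segment,
              x$bins[1], x$bins[1] + 1, x$bins[2], x$bins[2] + 1))
  invisible(x)
}

length_bin <- function(morph, bins) {
  ifelse(morph <= bins[1], "short", ifelse(morph <= bins[2], "medium", "long"))
}

# per-utterance raw statistics used by both the global and segment blocks
utterance_stats <- function(t, lexicon, rules, max_unit) {
  n <- length(t$utterances)
  out <- data.frame(
    terminator = character(n), n_words = integer(n), morphemes = integer(n),
    filled_pauses = integer(n), repetitions = integer(n),
    word_repetitions = integer(n), phrase_repetitions = integer(n),
    repeated_words = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    u <- t$utterances[[i]]
    tk <- u$tokens
    ev <- detect_repetitions(tk, max_unit = max_unit)
    extra <- vapply(ev, function(e) e$n_copies - 1L, integer(1))
    lens <- vapply(ev, `[[`, 1L, "unit_length")
    out$terminator[i] <- u$terminator
    out$n_words[i] <- sum(!tk$in_maze)
    out$morphemes[i] <- count_morphemes(tk, rules)
    out$filled_pauses[i] <- detect_filled_pauses(tk, lexicon)$count
    out$repetitions[i] <- sum(extra)
    out$word_repetitions[i] <- sum(extra[lens == 1L])
    out$phrase_repetitions[i] <- sum(extra[lens >= 2L])
    out$repeated_words[i] <- sum(lens * extra)
  }
  out
}

rate <- function(num, den, per = 100) if (den > 0) per * num / den else 0

profile_block <- function(us, bins) {
  n_utt <- nrow(us)
  n_words <- sum(us$n_words)
  n_morph <- sum(us$morphemes)
  bin <- length_bin(us$morphemes, bins)
  dysfluent <- us$repetitions > 0 | us$filled_pauses > 0
  n_rep <- sum(us$repetitions)
  c(n_utterances = n_utt,
    n_statements = sum(us$terminator == "."),
    n_questions = sum(us$terminator == "?"),
    n_exclamations = sum(us$terminator == "!"),
    n_words = n_words,
    n_morphemes = n_morph,
    mlu = rate(n_morph, n_utt, per = 1),
    n_one_word = sum(us$morphemes == 1),
    n_short = sum(bin == "short"),
    n_medium = sum(bin == "medium"),
    n_long = sum(bin == "long"),
    p_short = rate(sum(bin == "short"), n_utt),
    p_medium = rate(sum(bin == "medium"), n_utt),
    p_long = rate(sum(bin == "long"), n_utt),
    n_filled_pauses = sum(us$filled_pauses),
    filled_pauses_per_100_words = rate(sum(us$filled_pauses), n_words),
    n_repetitions = n_rep,
    n_word_repetitions = sum(us$word_repetitions),
    n_phrase_repetitions = sum(us$phrase_repetitions),
    n_repeated_words = sum(us$repeated_words),
    p_repeated_words = rate(sum(us$repeated_words), n_words),
    repetitions_per_utterance = rate(n_rep, n_utt, per = 1),
    n_utt_with_repetition = sum(us$repetitions > 0),
    p_utt_with_repetition = rate(sum(us$repetitions > 0), n_utt),
    n_dysfluent_short = sum(dysfluent & bin == "short"),
    n_dysfluent_medium = sum(dysfluent & bin == "medium"),
    n_dysfluent_long = sum(dysfluent & bin == "long"),
    dysfluencies_per_100_words = rate(sum(us$filled_pauses) + n_rep, n_words))
}

#' Extract the linguistic feature profile of a transcript
#'
#' Computes the 28 global features and the 12-feature sub-block for each of
#' the `k` token-quintile segments defined by the schema (88 features for
#' the default schema). Rates with a zero denominator are emitted as 0; an
#' empty transcript yields an all-zero profile.
#'
#' @param t an `fx_transcript`.
#' @param schema an `fx_schema` (default [default_feature_schema()]).
#' @param lexicon filler lexicon.
#' @param morpheme_rules morpheme rule table.
#' @param max_unit maximum repetition unit length.
#' @return named numeric vector in fixed schema order.
#' @export
#' @examples
#' t <- parse_transcript("She is uh a very uh lovely girl.\nYes.\n")
#' p <- profile_transcript(t)
#' p[["n_filled_pauses"]]  # 2
profile_transcript <- function(t, schema = default_feature_schema(),
                               lexicon = default_filler_lexicon(),
                               morpheme_rules = default_morpheme_rules(),
                               max_unit = 6L) {
  stopifnot(inherits(t, "fx_transcript"), inherits(schema, "fx_schema"))
  us <- utterance_stats(t, lexicon, morpheme_rules, max_unit)
  n_tok <- vapply(t$utterances, function(u) nrow(u$tokens), integer(1))
  global <- profile_block(us, schema$bins)

  seg_names <- c("n_utterances", "n_words", "mlu", "n_filled_pauses",
                 "filled_pauses_per_100_words", "n_repetitions",
                 "n_repeated_words", "p_repeated_words",
                 "n_short", "n_medium", "n_long", "repetitions_per_utterance")
  seg <- segment_assignment(n_tok, schema$k)
  seg_feats <- unlist(lapply(seq_len(schema$k), function(s) {
    block <- profile_block(us[which(seg == s), , drop = FALSE], schema$bins)
    setNames(block[seg_names], paste0("seg", s, "_", seg_names))
  }))
  out <- c(global, seg_feats)
  stopifnot(identical(names(out), schema$names))
  out
}

#' Profile every transcript in a corpus manifest
#'
#' @param manifest data frame or CSV path with columns `participant_id`,
#'   `transcript_path`, `group_label` (paths in a CSV manifest are resolved
#'   relative to it).
#' @param schema,lexicon,morpheme_rules,max_unit passed to
#'   [profile_transcript()].
#' @return data.frame with `participant_id` followed by the schema features,
#'   one row per readable transcript. Unreadable transcripts are reported in
#'   a warning and in the `"failures"` attribute (named character vector of
#'   error messages); processing continues for the others.
#' @export
profile_corpus <- function(manifest, schema = default_feature_schema(),
                           lexicon = default_filler_lexicon(),
                           morpheme_rules = default_morpheme_rules(),
                           max_unit = 6L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$participant_id[i]
    path <- manifest$transcript_path[i]
    res <- tryCatch({
      tr <- read_transcript(path, participant_id = id,
                            filler_lexicon = lexicon,
                            morpheme_rules = morpheme_rules)
      profile_transcript(tr, schema, lexicon, morpheme_rules, max_unit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- sprintf("%s: %s", path, conditionMessage(res))
    } else {
      rows[[id]] <- res
    }
  }
  if (length(failures)) {
    warning("failed to profile ", length(failures), " transcript(s): ",
            paste(names(failures), collapse = ", "), call. = FALSE)
  }
  out <- if (length(rows)) {
    cbind(data.frame(participant_id = names(rows), stringsAsFactors = FALSE),
          as.data.frame(do.call(rbind, rows), row.names = FALSE))
  } else {
    empty <- as.data.frame(matrix(numeric(0), ncol = length(schema$names),
                                  dimnames = list(NULL, schema$names)))
    cbind(data.frame(participant_id = character(0)), empty)
  }
  attr(out, "failures") <- failures
  attr(out, "schema_version") <- schema$version
  out
}
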
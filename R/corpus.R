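# Transcript data model and I/O.
#
# Dialect: plain UTF-8 text, one utterance per line, terminated by `.`, `?`
# or `!` (a missing terminator is read as a statement).  Parenthesized spans
# are SALT-style mazes (false starts, repeated material, fillers) and are
# flagged on the tokens rather than stripped, so downstream feature code can
# treat them as dysfluent, non-propositional material.

#' Default filled-pause lexicon
#'
#' Words or vocalizations that fill a pause. The clinical literature names
#' "um, ah, oh" as canonical examples; the default adds the common
#' transcription variants uh, er, hmm and mm. Matching is case-insensitive on
#' normalized token forms.
#'
#' @return Character vector of filler forms.
#' @export
#' @examples
#' default_filler_lexicon()
default_filler_lexicon <- function() {
  c("um", "uh", "ah", "oh", "er", "hmm", "mm")
}

#' Normalize a token surface form
#'
#' Lower-cases and strips leading/trailing punctuation while keeping
#' intra-word apostrophes (so "don't" and "John's" survive intact).
#' Typographic apostrophes are folded to ASCII.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized forms ("" for punctuation-only
#'   tokens).
#' @export
normalize_token <- function(x) {
  x <- gsub("’", "'", x)
  x <- tolower(x)
  x <- gsub("^[^a-z0-9']+", "", x)
  x <- gsub("[^a-z0-9']+$", "", x)
  # apostrophes are only kept word-internally
  x <- gsub("^'+", "", x)
  x <- gsub("'+$", "", x)
  x
}

terminator_chars <- c(".", "?", "!")

tokenize_line <- function(line, filler_lexicon, line_no = NA_integer_) {
  line <- trimws(line)
  last <- substr(line, nchar(line), nchar(line))
  terminator <- if (last %in% terminator_chars) last else "."
  body <- sub("[.?!]+$", "", line)

  raw <- strsplit(trimws(body), "[[:space:]]+")[[1]]
  raw <- raw[nzchar(raw)]
  if (!length(raw)) {
    return(list(tokens = empty_token_frame(), terminator = terminator))
  }

  opens <- nchar(raw) - nchar(gsub("(", "", raw, fixed = TRUE))
  closes <- nchar(raw) - nchar(gsub(")", "", raw, fixed = TRUE))
  depth_after <- cumsum(opens - closes)
  depth_before <- c(0L, head(depth_after, -1L))
  # balance check: depth may never dip below zero and must close out;
  # within-token order ")(" is not meaningful in the maze dialect
  if (depth_after[length(depth_after)] != 0L || any(depth_after < 0L) ||
      any(depth_before < 0L)) {
    stop(sprintf("unbalanced parentheses on line %d", line_no), call. = FALSE)
  }
  in_maze <- depth_before > 0L | opens > 0L

  surface <- gsub("[()]", "", raw)
  normalized <- normalize_token(surface)
  keep <- nzchar(normalized)
  tokens <- data.frame(
    surface = surface[keep],
    normalized = normalized[keep],
    is_filler = normalized[keep] %in% tolower(filler_lexicon),
    in_maze = in_maze[keep],
    stringsAsFactors = FALSE
  )
  list(tokens = tokens, terminator = terminator)
}

empty_token_frame <- function() {
  data.frame(surface = character(0), normalized = character(0),
             is_filler = logical(0), in_maze = logical(0),
             stringsAsFactors = FALSE)
}

#' Parse a language-sample transcript
#'
#' Reads the one-utterance-per-line transcript dialect into a structured
#' `fx_transcript` object. Each non-blank line becomes one utterance; tokens
#' inside balanced parentheses are flagged as maze (dysfluency annotation)
#' material, and tokens whose normalized form is in `filler_lexicon` are
#' flagged as filled pauses. Lines without a terminal `.`, `?` or `!` are
#' treated as statements.
#'
#' @param text raw transcript text (single string, possibly multi-line).
#' @param filler_lexicon character vector of filler forms
#'   (default [default_filler_lexicon()]).
#' @param participant_id identifier attached to the transcript.
#' @param source_mode optional collection mode, one of `"phone"`,
#'   `"in_person"`, `"synthetic"`.
#' @param morpheme_rules rule table for morpheme counting
#'   (default [default_morpheme_rules()]); used to precompute per-utterance
#'   morpheme counts.
#' @return An `fx_transcript`: list with `participant_id`, `source_mode` and
#'   `utterances`, where each utterance holds a token data frame
#'   (`surface`, `normalized`, `is_filler`, `in_maze`), a `terminator` and a
#'   `morpheme_count`.
#' @export
#' @examples
#' t <- parse_transcript("What is his name? I don't know! He is John.\n")
#' length(t$utterances)
parse_transcript <- function(text, filler_lexicon = default_filler_lexicon(),
                             participant_id = "P1", source_mode = NULL,
                             morpheme_rules = default_morpheme_rules()) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines))
  line_nos <- which(keep)
  lines <- lines[keep]

  utterances <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed <- tokenize_line(lines[i], filler_lexicon, line_no = line_nos[i])
    utt <- list(tokens = parsed$tokens, terminator = parsed$terminator,
                morpheme_count = 0L)
    utt$morpheme_count <- count_morphemes(utt, morpheme_rules)
    utterances[[i]] <- utt
  }
  structure(list(participant_id = participant_id,
                 utterances = utterances,
                 source_mode = source_mode),
            class = "fx_transcript")
}

#' Read a transcript file
#'
#' @param path path to a UTF-8 transcript file.
#' @param participant_id defaults to the file name without extension.
#' @param ... passed to [parse_transcript()].
#' @return An `fx_transcript`.
#' @export
read_transcript <- function(path, participant_id = NULL, ...) {
  if (!file.exists(path)) stop("cannot read transcript file: ", path)
  if (is.null(participant_id)) {
    participant_id <- tools::file_path_sans_ext(basename(path))
  }
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  parse_transcript(txt, participant_id = participant_id, ...)
}

#' Serialize a transcript back to text
#'
#' Inverse of [parse_transcript()] up to token structure: maze runs are
#' re-wrapped in parentheses and the terminator re-attached, so
#' `parse_transcript(write_transcript(t))` reproduces the utterance/token
#' structure of `t`.
#'
#' @param t an `fx_transcript`.
#' @return A single string ("" for an empty transcript); each utterance on
#'   its own line with a trailing newline.
#' @export
write_transcript <- function(t) {
  stopifnot(inherits(t, "fx_transcript"))
  if (!length(t$utterances)) return("")
  lines <- vapply(t$utterances, function(u) {
    tk <- u$tokens
    if (!nrow(tk)) return(u$terminator)
    r <- rle(tk$in_maze)
    stops <- cumsum(r$lengths)
    starts <- c(1L, head(stops, -1L) + 1L)
    groups <- character(length(r$values))
    for (g in seq_along(r$values)) {
      words <- paste(tk$surface[starts[g]:stops[g]], collapse = " ")
      groups[g] <- if (r$values[g]) paste0("(", words, ")") else words
    }
    paste0(paste(groups, collapse = " "), u$terminator)
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.fx_transcript <- function(x, ...) {
  terms <- vapply(x$utterances, `[[`, character(1), "terminator")
  cat(sprintf("<fx_transcript> %s: %d utterances (%d statements, %d questions, %d exclamations), %d tokens\n",
              x$participant_id, length(x$utterances),
              sum(terms == "."), sum(terms == "?"), sum(terms == "!"),
              sum(vapply(x$utterances, function(u) nrow(u$tokens), 1L))))
  invisible(x)
}

# all tokens of a transcript, with utterance index attached
transcript_tokens <- function(t) {
  if (!length(t$utterances)) {
    out <- empty_token_frame()
    out$utterance <- integer(0)
    return(out)
  }
  frames <- lapply(seq_along(t$utterances), function(i) {
    tk <- t$utterances[[i]]$tokens
    if (nrow(tk)) tk$utterance <- i else tk$utterance <- integer(0)
    tk
  })
  do.call(rbind, frames)
}

#' Read a corpus manifest
#'
#' A corpus manifest is a CSV with columns `participant_id`,
#' `transcript_path`, `group_label` and optionally `source_mode`; transcript
#' paths are resolved relative to the manifest location.
#'
#' @param path manifest CSV path.
#' @return data.frame with an added `transcript_path` resolved column.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "transcript_path", "group_label")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$transcript_path)
  m$transcript_path[rel] <- file.path(dirname(path), m$transcript_path[rel])
  m
}
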
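# Synthetic two-group cohorts: transcripts, cognitive tables, labels, and a
# ground-truth sidecar. Everything every pipeline stage needs is generated
# from a seeded specification so the full workflow is testable without
# participant data.
#
# The generator emulates the study contrast: carriers produce more filled
# pauses and repetitions, slightly shorter utterances, concentrate
# dysfluencies in the first and last token-quintiles of the sample, and
# score worse (higher T-scores) on Organization of Materials, Self-Monitor
# and Task Monitor. Utterance counts and lengths are over-dispersed
# (negative binomial), sized so a five-minute-scale monologue has on the
# order of 60 utterances / 600 words. Content words come from a fixed
# Zipf-sampled synthetic vocabulary: they only matter through the morpheme
# rules, which the word list exercises (-s/-ed/-ing forms, contractions).

#' Fixed synthetic vocabulary
#'
#' Deterministic word list: common English function words at the top ranks
#' followed by generated CVCV content words, some carrying regular
#' inflections so morpheme counting is exercised. Filler forms are excluded.
#'
#' @return character vector (most frequent first).
#' @export
fx_vocabulary <- function() {
  fun_words <- c("the", "and", "i", "he", "she", "it", "they", "we", "was",
                 "is", "to", "of", "a", "in", "that", "his", "her", "my",
                 "you", "for", "on", "with", "at", "but", "so", "very",
                 "really", "don't", "it's", "he's", "she's", "i'm", "can't",
                 "didn't", "good", "nice", "now", "then", "when", "there")
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "w")
  vow <- c("a", "e", "i", "o", "u")
  g <- expand.grid(c1 = cons, v1 = vow, c2 = cons, stringsAsFactors = FALSE)
  stems <- paste0(g$c1, g$v1, g$c2, "o")[seq_len(360)]
  inflected <- c(paste0(stems[seq(1, 60, 3)], "s"),
                 paste0(stems[seq(2, 60, 3)], "ed"),
                 paste0(stems[seq(3, 60, 3)], "ing"))
  words <- unique(c(fun_words, stems, inflected))
  setdiff(words, default_filler_lexicon())
}

default_group_params <- function() {
  list(n_utterances_mean = 60, n_utterances_size = 20,
       words_mean = 9, words_size = 8,
       filler_hazard = 0.02, repetition_hazard = 0.08,
       repetition_unit_mix = c(`1` = 0.6, `2` = 0.4),
       segment_multipliers = rep(1, 5),
       terminator_probs = c(0.92, 0.06, 0.02),
       cognitive_means = setNames(rep(50, 9), cognitive_scales()),
       cognitive_sd = 10, validity_mean = 50, validity_sd = 8,
       age_mean = 47.4, age_sd = 6.9,
       education_probs = c(0.02, 0.13, 0.54, 0.31))
}

#' Specify a synthetic two-group cohort
#'
#' The default parameters are the study conditions the package emulates:
#' matched groups of five-minute-scale monologues where, at
#' `effect_scale = 1`, carriers have twice the comparison filled-pause and
#' repetition hazards (0.04 vs 0.02 per token; 0.16 vs 0.08 per utterance),
#' utterances one word shorter on average, dysfluency hazards raised ~30%
#' in the first and last sample quintiles, and a +5 T-score shift (worse)
#' on Organization of Materials, Self-Monitor and Task Monitor.
#' `effect_scale = 0` gives identically distributed groups (the null);
#' larger values scale all group differences up. Ages follow the matched
#' cohort demographics (means ~48.9 vs ~47.4 years); education is drawn
#' from the same ordinal 1-4 distribution in both groups.
#'
#' @param n_per_group samples per group (default 100, the study size).
#' @param seed master seed; the whole corpus is a deterministic function of
#'   the spec.
#' @param effect_scale nonnegative multiplier on all group differences.
#' @param carrier,comparison optional named lists overriding individual
#'   generative parameters per group (see the field names in the returned
#'   object).
#' @return `fx_cohort_spec` list with `n_per_group`, `seed`,
#'   `effect_scale`, per-group parameter lists and the ground-truth
#'   `informative_features` (the five injected mechanisms).
#' @export
cohort_spec <- function(n_per_group = 100L, seed = 1L, effect_scale = 1,
                        carrier = list(), comparison = list()) {
  stopifnot(n_per_group >= 1L, effect_scale >= 0)
  comp <- modifyList(default_group_params(), comparison)
  s <- effect_scale
  carr_defaults <- modifyList(comp, list(
    filler_hazard = comp$filler_hazard * (1 + s),
    repetition_hazard = comp$repetition_hazard * (1 + s),
    words_mean = max(comp$words_mean - s, 2),
    segment_multipliers = pmax(1 + s * c(0.3, -0.1, -0.2, -0.1, 0.3), 0.1),
    # the matched cohorts differ slightly in age (48.9 vs 47.4 years at the
    # study contrast); the difference scales away with the other effects
    age_mean = comp$age_mean + 1.5 * s,
    age_sd = max(comp$age_sd - 0.6 * s, 1),
    cognitive_means = {
      m <- comp$cognitive_means
      shifted <- c("organization_of_materials", "self_monitor", "task_monitor")
      m[shifted] <- m[shifted] + 5 * s
      m
    }))
  carr <- modifyList(carr_defaults, carrier)
  spec <- structure(list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    effect_scale = effect_scale,
    groups = list(carrier = carr, comparison = comp),
    informative_features = c("n_filled_pauses", "n_repetitions",
                             "organization_of_materials", "self_monitor",
                             "task_monitor")),
    class = "fx_cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec an `fx_cohort_spec`.
#' @return the spec, invisibly; errors on invalid parameters (hazards
#'   outside `[0, 1]`, non-positive segment multipliers, bad sizes).
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "fx_cohort_spec"))
  if (spec$n_per_group < 1L) stop("n_per_group must be at least 1")
  for (g in names(spec$groups)) {
    p <- spec$groups[[g]]
    for (h in c("filler_hazard", "repetition_hazard")) {
      if (p[[h]] < 0 || p[[h]] > 1) {
        stop(sprintf("%s %s = %g is outside [0, 1]", g, h, p[[h]]))
      }
    }
    if (length(p$segment_multipliers) != 5L || any(p$segment_multipliers <= 0)) {
      stop(g, " segment_multipliers must be 5 positive numbers")
    }
    if (p$words_mean <= 0 || p$n_utterances_mean <= 0) {
      stop(g, " utterance/word means must be positive")
    }
  }
  invisible(spec)
}

#' @export
print.fx_cohort_spec <- function(x, ...) {
  cat(sprintf("<fx_cohort_spec> %d per group, seed %d, effect_scale %g\n",
              x$n_per_group, x$seed, x$effect_scale))
  for (g in names(x$groups)) {
    p <- x$groups[[g]]
    cat(sprintf("  %-10s filler %.3f/token, repetition %.3f/utterance, words/utt %.1f\n",
                g, p$filler_hazard, p$repetition_hazard, p$words_mean))
  }
  invisible(x)
}

#' Generate one synthetic transcript
#'
#' Draws an utterance count, then per utterance a word count, tokens from
#' the Zipf vocabulary, a repetition event by hazard (written as a maze
#' annotation before the repeated material, so the annotation is
#' ground truth) and filled pauses by per-token hazard. Segment-position
#' multipliers scale both hazards across the five utterance-order
#' quintiles. Hazards of zero produce a fully fluent transcript; the same
#' seed reproduces the transcript byte for byte.
#'
#' @param params a group parameter list (see [cohort_spec()]).
#' @param seed integer seed.
#' @param participant_id id for the returned transcript.
#' @return `fx_transcript` with attributes `"text"` (the raw dialect text)
#'   and `"injected"` (data frame of injected repetition events:
#'   `utterance`, `unit_length`, `word_position`).
#' @export
generate_transcript <- function(params, seed = 1L, participant_id = "synthetic") {
  set.seed(seed)
  vocab <- fx_vocabulary()
  zipf <- 1 / seq_along(vocab)^1.1
  lex <- default_filler_lexicon()
  n_utt <- max(rnbinom(1, mu = params$n_utterances_mean,
                       size = params$n_utterances_size), 5L)
  lines <- character(n_utt)
  injected <- list()
  for (u in seq_len(n_utt)) {
    segment <- ceiling(5 * u / n_utt)
    mult <- params$segment_multipliers[segment]
    fh <- min(params$filler_hazard * mult, 1)
    rh <- min(params$repetition_hazard * mult, 1)
    n_words <- rnbinom(1, mu = params$words_mean, size = params$words_size) + 1L
    words <- sample(vocab, n_words, replace = TRUE, prob = zipf)
    pieces <- as.list(words)
    protected <- integer(0)
    if (runif(1) < rh) {
      unit_len <- as.integer(sample(names(params$repetition_unit_mix), 1,
                                    prob = params$repetition_unit_mix))
      unit_len <- min(unit_len, n_words)
      pos <- sample(n_words - unit_len + 1L, 1)
      unit <- words[pos:(pos + unit_len - 1L)]
      pieces[[pos]] <- c(paste0("(", paste(unit, collapse = " "), ")"),
                         pieces[[pos]])
      # no filler may fall inside a copy of the repeated unit (only between
      # copies), so the interior word slots are shielded from filler draws
      if (unit_len > 1L) protected <- (pos + 1L):(pos + unit_len - 1L)
      injected[[length(injected) + 1L]] <-
        data.frame(utterance = u, unit_length = unit_len, word_position = pos)
    }
    # a filled pause may precede any unshielded word slot
    with_fillers <- lapply(seq_along(pieces), function(i) {
      p <- pieces[[i]]
      if (!(i %in% protected) && runif(1) < fh) c(sample(lex, 1), p) else p
    })
    terminator <- sample(c(".", "?", "!"), 1, prob = params$terminator_probs)
    lines[u] <- paste0(paste(unlist(with_fillers), collapse = " "), terminator)
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  out <- parse_transcript(text, participant_id = participant_id,
                          source_mode = "synthetic")
  attr(out, "text") <- text
  attr(out, "injected") <- if (length(injected)) {
    do.call(rbind, injected)
  } else {
    data.frame(utterance = integer(0), unit_length = integer(0),
               word_position = integer(0))
  }
  out
}

#' Generate a full synthetic cohort
#'
#' `n_per_group` transcripts per group plus matching cognitive and label
#' tables, with the ground truth (injected informative features, per-group
#' parameters, per-transcript injected event counts) in a sidecar. With
#' `dir` given, everything is written to disk in the package's exchange
#' formats: `transcripts/<id>.txt`, `manifest.csv`, `cognitive.csv`,
#' `labels.csv`, `ground_truth.json`.
#'
#' @param spec an [cohort_spec()].
#' @param dir optional output directory (created if needed).
#' @return (invisibly) list with `transcripts` (named list of
#'   `fx_transcript`), `manifest`, `cognitive`, `labels`, `ground_truth`
#'   and the `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  validate_cohort_spec(spec)
  n <- spec$n_per_group
  ids <- c(sprintf("carrier_%03d", seq_len(n)),
           sprintf("comparison_%03d", seq_len(n)))
  groups <- rep(c("carrier", "comparison"), each = n)
  set.seed(spec$seed)
  transcript_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  transcripts <- vector("list", 2L * n)
  names(transcripts) <- ids
  injected_events <- integer(2L * n)
  for (i in seq_along(ids)) {
    tr <- generate_transcript(spec$groups[[groups[i]]],
                              seed = transcript_seeds[i],
                              participant_id = ids[i])
    transcripts[[i]] <- tr
    injected_events[i] <- nrow(attr(tr, "injected"))
  }

  set.seed(spec$seed + 1L)
  cog_rows <- lapply(seq_along(ids), function(i) {
    p <- spec$groups[[groups[i]]]
    scales <- rnorm(9, mean = p$cognitive_means, sd = p$cognitive_sd)
    scales <- round(pmax(scales, 20), 1)
    names(scales) <- cognitive_scales()
    data.frame(participant_id = ids[i], as.list(scales),
               validity = round(rnorm(1, p$validity_mean, p$validity_sd), 1),
               age = round(rnorm(1, p$age_mean, p$age_sd), 1),
               education = sample(1:4, 1, prob = p$education_probs),
               stringsAsFactors = FALSE)
  })
  cognitive <- do.call(rbind, cog_rows)

  manifest <- data.frame(participant_id = ids,
                         transcript_path = file.path("transcripts",
                                                     paste0(ids, ".txt")),
                         group_label = groups, source_mode = "synthetic",
                         stringsAsFactors = FALSE)
  labels <- data.frame(participant_id = ids, group = groups,
                       stringsAsFactors = FALSE)
  ground_truth <- list(informative_features = spec$informative_features,
                       effect_scale = spec$effect_scale,
                       seed = spec$seed,
                       injected_repetition_events =
                         setNames(as.list(injected_events), ids))

  if (!is.null(dir)) {
    dir.create(file.path(dir, "transcripts"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in ids) {
      writeLines(sub("\n$", "", attr(transcripts[[id]], "text")),
                 file.path(dir, "transcripts", paste0(id, ".txt")))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(cognitive, file.path(dir, "cognitive.csv"), row.names = FALSE)
    write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(transcripts = transcripts, manifest = manifest,
                 cognitive = cognitive, labels = labels,
                 ground_truth = ground_truth, spec = spec))
}

#' Serialize / read a cohort spec
#'
#' JSON round-trip: a spec written with `write_cohort_spec()` and read back
#' regenerates an identical corpus.
#'
#' @param spec an `fx_cohort_spec`.
#' @param path file path (`.json`, or `.yaml`/`.yml` for YAML).
#' @return `read_cohort_spec()` returns an `fx_cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(spec), path)
  } else {
    jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  fix_group <- function(p) {
    p$cognitive_means <- unlist(p$cognitive_means)
    if (is.null(names(p$cognitive_means))) {
      names(p$cognitive_means) <- cognitive_scales()
    }
    p$repetition_unit_mix <- unlist(p$repetition_unit_mix)
    if (is.null(names(p$repetition_unit_mix))) {
      names(p$repetition_unit_mix) <- seq_along(p$repetition_unit_mix)
    }
    p
  }
  spec <- structure(list(
    n_per_group = as.integer(raw$n_per_group), seed = as.integer(raw$seed),
    effect_scale = raw$effect_scale,
    groups = lapply(raw$groups, fix_group),
    informative_features = unlist(raw$informative_features)),
    class = "fx_cohort_spec")
  validate_cohort_spec(spec)
  spec
}
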
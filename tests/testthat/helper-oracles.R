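# Independent oracles used across the suite. These deliberately recompute
# quantities by brute force / enumeration, not by the package's own code
# paths.

# token frame from a vector of normalized forms; "F" marks a filler token
token_frame <- function(symbols) {
  data.frame(surface = symbols, normalized = symbols,
             is_filler = symbols == "F", in_maze = FALSE,
             stringsAsFactors = FALSE)
}

# Brute-force repetition finder: iterated best-candidate search. On each
# pass it enumerates EVERY (start, unit-length) pair on the current
# availability mask, computes the maximal copy run by direct comparison,
# and accepts the longest-unit (then leftmost) candidate. Equivalent
# semantics to the detector's precedence rules, arrived at by a different
# mechanism.
brute_repetitions <- function(norm, filler, max_unit = 6L) {
  n <- length(norm)
  consumed <- logical(n)
  events <- list()
  if (n < 2L) return(events)
  repeat {
    best <- NULL
    for (L in seq_len(min(max_unit, n %/% 2L))) {
      for (s in seq_len(n - 2L * L + 1L)) {
        idx <- s:(s + L - 1L)
        if (any(filler[idx]) || any(consumed[idx])) next
        copies <- 1L; fb <- 0L; pos <- idx; j <- s + L
        repeat {
          k <- j
          while (k <= n && filler[k]) k <- k + 1L
          if (k + L - 1L > n) break
          cand <- k:(k + L - 1L)
          if (any(filler[cand]) || any(consumed[cand])) break
          if (!identical(norm[cand], norm[idx])) break
          copies <- copies + 1L; fb <- fb + (k - j)
          pos <- c(pos, cand); j <- k + L
        }
        if (copies >= 2L &&
            (is.null(best) || L > best$unit_length ||
             (L == best$unit_length && s < best$start_index))) {
          best <- list(unit_length = L, start_index = s, n_copies = copies,
                       fillers_between = fb, positions = pos)
        }
      }
    }
    if (is.null(best)) break
    events[[length(events) + 1L]] <- best
    consumed[best$positions] <- TRUE
  }
  events[order(vapply(events, `[[`, 1L, "start_index"))]
}

event_signature <- function(events) {
  if (!length(events)) return(character(0))
  vapply(events, function(e) {
    sprintf("%d:%d:%d:%d", e$start_index, e$unit_length, e$n_copies,
            e$fillers_between)
  }, character(1))
}

# AUC by exhaustive positive-negative pair comparison, ties worth 1/2
auc_pairwise <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# all sequences of given length over an alphabet, as a character matrix
all_sequences <- function(len, alphabet) {
  as.matrix(expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE))
}

make_cognitive_row <- function(id = "P1", value = 50, age = 48, education = 3) {
  scales <- setNames(as.list(rep(value, 9)), cognitive_scales())
  data.frame(participant_id = id, scales, validity = 50, age = age,
             education = education, stringsAsFactors = FALSE)
}
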
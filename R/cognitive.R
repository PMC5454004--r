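# Cognitive/demographic block: BRIEF-A-style scale scores plus maternal age
# and education. Raw item scoring of the instrument is proprietary and out
# of scope; only scale-level scores are ingested. Composite indexes use the
# sum convention (BRI = sum of its four scales, MI = sum of its five, GEC =
# BRI + MI) and, when composite columns are supplied, the recomputed values
# are checked against them.

#' Names of the nine clinical executive-function scales
#'
#' BRI scales first (Inhibit, Shift, Emotional Control, Self-Monitor), then
#' the MI scales (Initiate, Working Memory, Plan/Organize, Task Monitor,
#' Organization of Materials).
#'
#' @return character vector of 9 column names.
#' @export
cognitive_scales <- function() {
  c("inhibit", "shift", "emotional_control", "self_monitor",
    "initiate", "working_memory", "plan_organize", "task_monitor",
    "organization_of_materials")
}

bri_scales <- function() cognitive_scales()[1:4]
mi_scales <- function() cognitive_scales()[5:9]

#' Names of the 15 cognitive/demographic features
#'
#' Nine clinical scales, the BRI/MI/GEC composites, a validity composite,
#' maternal age (years) and maternal education (ordinal 1-4: less than high
#' school / high school graduate / some college or Bachelor's /
#' post-Bachelor's).
#'
#' @return character vector of 15 feature names, in serialization order.
#' @export
cognitive_feature_names <- function() {
  c(cognitive_scales(), "bri", "mi", "gec", "validity", "age", "education")
}

#' Load a cognitive score table
#'
#' Reads one row per participant with the nine scale scores, age and
#' education (plus optional `bri`, `mi`, `gec`, `validity` columns).
#' Composites are recomputed with the sum convention; when the file also
#' provides composite columns they must agree with the recomputed values
#' within `composite_tolerance`. A missing validity column defaults to the
#' T-score midpoint 50.
#'
#' @param x CSV path or data frame.
#' @param composite_tolerance maximum allowed absolute difference between a
#'   provided composite and its recomputed value (default 0.5, i.e. printed
#'   rounding).
#' @return data.frame with `participant_id` plus the 15 features of
#'   [cognitive_feature_names()], in that order.
#' @export
load_cognitive_table <- function(x, composite_tolerance = 0.5) {
  df <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  names(df) <- tolower(names(df))
  required <- c("participant_id", cognitive_scales(), "age", "education")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cognitive table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_edu <- !(df$education %in% 1:4)
  if (any(bad_edu)) {
    stop("education must be an ordinal in 1..4; offending participant(s): ",
         paste(df$participant_id[bad_edu], collapse = ", "))
  }
  bri <- rowSums(df[bri_scales()])
  mi <- rowSums(df[mi_scales()])
  gec <- bri + mi
  for (comp in c("bri", "mi", "gec")) {
    if (comp %in% names(df)) {
      delta <- abs(df[[comp]] - get(comp))
      if (any(delta > composite_tolerance, na.rm = TRUE)) {
        stop(sprintf("provided %s composite disagrees with the sum of its scales (max |diff| = %.3g) for participant(s): %s",
                     toupper(comp), max(delta, na.rm = TRUE),
                     paste(df$participant_id[delta > composite_tolerance],
                           collapse = ", ")))
      }
    }
  }
  validity <- if ("validity" %in% names(df)) df$validity else rep(50, nrow(df))
  out <- data.frame(participant_id = as.character(df$participant_id),
                    df[cognitive_scales()],
                    bri = bri, mi = mi, gec = gec,
                    validity = validity, age = df$age,
                    education = df$education,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$participant_id)) {
    stop("duplicate participant_id in cognitive table")
  }
  out
}

#' Combine linguistic and cognitive blocks into a comprehensive profile
#'
#' @param lp named numeric linguistic profile (88 features for the default
#'   schema) or a single profile row with a `participant_id` column.
#' @param cp named numeric cognitive block (15 features) or a single row of
#'   [load_cognitive_table()] output.
#' @param label optional group label (e.g. `"carrier"` / `"comparison"`).
#' @param participant_id optional id; when both blocks carry ids they must
#'   agree.
#' @return named numeric vector of 103 features (linguistic order then
#'   cognitive order), with `participant_id` and `label` attributes.
#' @export
build_comprehensive_profile <- function(lp, cp, label = NULL,
                                        participant_id = NULL) {
  take <- function(x, drop_cols) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      id <- if ("participant_id" %in% names(x)) x$participant_id else NULL
      v <- unlist(x[setdiff(names(x), drop_cols)])
      list(values = v, id = id)
    } else {
      list(values = x, id = attr(x, "participant_id"))
    }
  }
  l <- take(lp, "participant_id")
  c_ <- take(cp, "participant_id")
  ids <- unique(c(participant_id, l$id, c_$id))
  if (length(ids) > 1L) {
    stop("participant id mismatch between linguistic and cognitive blocks: ",
         paste(ids, collapse = " vs "))
  }
  cog <- c_$values[cognitive_feature_names()]
  if (anyNA(names(cog))) stop("cognitive block is missing features")
  out <- c(l$values, cog)
  attr(out, "participant_id") <- if (length(ids)) ids else NA_character_
  attr(out, "label") <- label
  out
}

#' Join linguistic and cognitive tables into a profile matrix
#'
#' Strict inner structure: every participant in the linguistic table must
#' have a cognitive row (and a label row when labels are supplied);
#' otherwise the missing ids are named in the error.
#'
#' @param linguistic output of [profile_corpus()] (participant_id + 88
#'   features).
#' @param cognitive output of [load_cognitive_table()].
#' @param labels optional data frame with `participant_id` and `group`
#'   columns, or a named character vector.
#' @return data.frame: `participant_id`, 103 feature columns, and `label`
#'   (NA when no labels given), in linguistic row order.
#' @export
assemble_profiles <- function(linguistic, cognitive, labels = NULL) {
  ids <- linguistic$participant_id
  missing_cog <- setdiff(ids, cognitive$participant_id)
  if (length(missing_cog)) {
    stop("no cognitive row for participant(s): ",
         paste(missing_cog, collapse = ", "))
  }
  cog <- cognitive[match(ids, cognitive$participant_id),
                   cognitive_feature_names(), drop = FALSE]
  lab <- rep(NA_character_, length(ids))
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- setNames(as.character(labels$group), labels$participant_id)
    }
    missing_lab <- setdiff(ids, names(labels))
    if (length(missing_lab)) {
      stop("no label for participant(s): ", paste(missing_lab, collapse = ", "))
    }
    lab <- unname(labels[ids])
  }
  out <- cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE),
               linguistic[setdiff(names(linguistic), "participant_id")],
               cog, data.frame(label = lab, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Split a comprehensive profile matrix into a feature subset
#'
#' Subsets follow the profile vocabulary of the screening workflow:
#' `"full"` (all 103), `"linguistic_only"` (88), `"cognitive_only"` (15),
#' `"optimized"` (all features; selection is then performed inside training
#' folds) and `"segment_1"` .. `"segment_5"` (the 12-feature sub-block of one
#' token-quintile segment).
#'
#' @param profiles output of [assemble_profiles()].
#' @param subset subset name.
#' @param schema schema used for the linguistic block.
#' @return data.frame of the selected feature columns (no id/label columns).
#' @export
profile_subset <- function(profiles, subset = "full",
                           schema = default_feature_schema()) {
  feats <- setdiff(names(profiles), c("participant_id", "label"))
  keep <- if (subset %in% c("full", "optimized")) {
    feats
  } else if (subset == "linguistic_only") {
    intersect(feats, schema$names)
  } else if (subset == "cognitive_only") {
    intersect(feats, cognitive_feature_names())
  } else if (grepl("^segment_[1-9][0-9]*$", subset)) {
    s <- sub("^segment_", "", subset)
    grep(paste0("^seg", s, "_"), feats, value = TRUE)
  } else {
    stop("unknown profile subset: ", subset)
  }
  if (!length(keep)) stop("profile subset '", subset, "' selects no features")
  profiles[keep]
}
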
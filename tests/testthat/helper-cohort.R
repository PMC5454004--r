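# profile an in-memory synthetic cohort into the assembled 103-feature matrix
profile_cohort <- function(cohort) {
  prof <- t(vapply(cohort$transcripts, profile_transcript, numeric(88)))
  ling <- cbind(data.frame(participant_id = rownames(prof),
                           stringsAsFactors = FALSE),
                as.data.frame(prof))
  assemble_profiles(ling, load_cognitive_table(cohort$cognitive),
                    cohort$labels)
}
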
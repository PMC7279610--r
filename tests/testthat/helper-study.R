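# Shared Monte-Carlo study for the heavy synthetic-recovery checks.
# Computed once per session and memoised, since several test files assert
# different properties of the same ten pipeline replicates.
.study_cache <- new.env(parent = emptyenv())

acceptance_recovery_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- recovery_study(seeds = 1:10)
  }
  .study_cache$study
}
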
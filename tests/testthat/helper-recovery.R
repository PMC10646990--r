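# The 20-seed staged-fit recovery study takes a few minutes; it is computed
# once per test session and shared between the model tests and the
# acceptance suite.
the_recovery_cache <- new.env(parent = emptyenv())

cached_recovery_study <- function() {
  if (is.null(the_recovery_cache$study)) {
    the_recovery_cache$study <- sans_recovery_study(seeds = 1:20)
  }
  the_recovery_cache$study
}

cached_power_law_study <- function() {
  if (is.null(the_recovery_cache$pl)) {
    the_recovery_cache$pl <- power_law_recovery_study(seeds = 1:20)
  }
  the_recovery_cache$pl
}
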
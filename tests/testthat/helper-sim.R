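# Small simulator configurations shared across test files.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_contigs = 1, contig_length = 3e5, n_ies = 30,
                   ir_jitter = 0, boundary_jitter_wt = 0,
                   intra_dup_fraction = 0, skip_fraction = 0,
                   clip_noise_rate = 0, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Shared PWM instance set whose per-position majority (consensus) is the
# simulator's default planted motif AAAAAGGGGG.
gpwm_instances <- function() {
  c("AAAAAGGGGG", "AAAAAGGGGG", "AAAAAGGGGG", "AAAAAGGGGG",
    "AATAAGGGGG", "AAAACGGGGG", "AAAAAGGGTG", "CAAAAGGGGG")
}
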
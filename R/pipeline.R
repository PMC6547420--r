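# End-to-end driver: simulate -> evidence -> refine -> normalize/filter ->
# cluster. Returns every intermediate so downstream analyses (variation,
# motif discovery, PWM scanning, mutant contrast) can start from any stage.

#' Run the synthetic-data pipeline end to end
#'
#' Generates a genome and truth table, draws every configured strain's
#' deletion forms, emits candidate/clip evidence, refines breakpoints,
#' normalizes junctions, applies the length/N filters and clusters forms
#' into loci.
#'
#' @param config A [sim_config()].
#' @param window Refinement window in bp (default 200).
#' @param min_len Catalogue length filter in bp (default 100).
#' @return List: config, genome, truth, forms_true (planted per-strain
#'   forms), candidates, clips, calls (refined), forms (normalized,
#'   filtered, clustered), loci ([locus_table()] with truth linkage).
#' @export
run_ies_pipeline <- function(config, window = 200, min_len = 100) {
  sim <- generate_mic_genome(config)
  forms_true <- do.call(rbind, lapply(config$strains, function(s) {
    generate_strain_deletions(sim$truth, config, s)
  }))
  ev <- emit_evidence(forms_true, config)
  calls <- refine_calls(ev$candidates, ev$clips, window = window)
  norm <- normalize_calls(calls, sim$genome)
  filt <- filter_calls(norm, sim$genome, min_len = min_len)
  forms <- cluster_forms(filt)
  loci <- match_loci_to_truth(locus_table(forms), sim$truth)
  list(config = config, genome = sim$genome, truth = sim$truth,
       forms_true = forms_true, candidates = ev$candidates, clips = ev$clips,
       calls = calls, forms = forms, loci = loci)
}
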
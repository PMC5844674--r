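# Memoised heavy ensembles shared by the acceptance blocks (computed once
# per test run).
.ens_cache <- new.env(parent = emptyenv())

acceptance_ensemble <- function(which = c("G4", "G6")) {
  which <- match.arg(which)
  key <- paste0("ens_", which)
  if (is.null(.ens_cache[[key]])) {
    strains <- default_airway_strains()
    seed <- if (which == "G4") 1 else 2
    .ens_cache[[key]] <- ventilam::run_ensemble(
      strains[[which]], ventilam::ca_params(),
      n_steps = 10000, n_reps = 20, seed = seed)
  }
  .ens_cache[[key]]
}
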
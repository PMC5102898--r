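# Shared fixtures, built once per test run.

fixture_env <- new.env()

# tiny ground-truth dataset: 1 plasmid per group (the group-A one carries
# the finO-loss ablation) plus one decoy with random proteins
small_dataset <- function() {
  if (is.null(fixture_env$ds)) {
    fixture_env$ds <- make_dataset(n_per_group = 1, seed = 42, n_decoys = 1)
  }
  fixture_env$ds
}

small_panel <- function() small_dataset()$panel_obj

small_classification <- function() {
  if (is.null(fixture_env$cls)) {
    ds <- small_dataset()
    fixture_env$cls <- suppressMessages(
      classify_records(ds$records, ds$panel_obj$profile_panel,
                       ds$typing_panel, run_config(),
                       ds$panel_obj$outgroup))
  }
  fixture_env$cls
}
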
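# shared synthetic fixture, built once per test run
.fx_env <- new.env(parent = emptyenv())

# four phyla with distinct planted defects on the 341f site
fixture_mixed <- function() {
  if (is.null(.fx_env$mixed)) {
    tx <- taxa_spec(
      taxon = c("PhyA", "PhyB", "PhyC", "PhyD"),
      n = 10,
      defect = c("none", "terminal_mismatch", "double_mismatch", "non3p_mismatch"),
      defect_frac = c(0, 0.2, 0.5, 0.4)
    )
    ref <- simulate_reference_set(tx, seed = 1234)
    cfg <- scoring_config()
    hits <- score_primers(ref$records, ref$primers, cfg)
    .fx_env$mixed <- list(ref = ref, hits = hits, cfg = cfg,
                          pair = c("341f", "785r"))
  }
  .fx_env$mixed
}
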
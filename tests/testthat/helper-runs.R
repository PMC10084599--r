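# one shared default-condition pipeline run (2000 genes, 7/7/5/5, batch
# offset, pi ~ 0.216) reused by the recovery checks; cached because several
# test blocks score different aspects of the same run
get_default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(run_config(simulate = sim_config(n_genes = 2000),
                                        seed = 42))
    }
    cache
  }
})

# per-class label recovery among genes with informative F1 coverage (genes
# the low-count rule flags uninformative cannot carry a label by definition)
recovery_rate <- function(run, class) {
  truth <- run$truth$true_inheritance[match(run$inheritance$gene,
                                            run$truth$gene)]
  covered <- run$inheritance$mode != "uninformative"
  idx <- truth == class & covered
  mean(run$inheritance$mode[idx] == class)
}
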
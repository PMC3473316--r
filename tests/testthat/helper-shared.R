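# One full synthetic run under the default study conditions (8 pools, 30X,
# 1% error), shared across test files; computed once per test session.
.shared <- new.env(parent = emptyenv())

shared_run <- function() {
  if (is.null(.shared$res)) {
    .shared$cfg <- sim_config(seed = 101L)
    .shared$res <- run_pool_pipeline(.shared$cfg)
    .shared$eval <- evaluate_calls(.shared$res$variants, .shared$res$truth,
                                   .shared$cfg)
  }
  .shared
}
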
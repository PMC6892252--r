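# One full-scale study run (20 arrangements x 20 scales x 3 scenarios x
# 2 schemes), computed once and shared by the acceptance blocks.
.study_cache <- new.env(parent = emptyenv())

get_full_study <- function() {
  if (is.null(.study_cache$study)) {
    t0 <- Sys.time()
    .study_cache$study <- run_scenarios(study_config(seed = 1),
                                        response = get_test_response())
    .study_cache$elapsed_s <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  .study_cache$study
}

get_full_study_elapsed <- function() {
  get_full_study()
  .study_cache$elapsed_s
}

study_mean <- function(study, scheme, scenario) {
  tab <- summary(study)$table
  tab$mean[tab$scheme == scheme & tab$scenario == scenario]
}
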
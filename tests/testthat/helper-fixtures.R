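# Shared fixtures: one small synthetic deployment (1 individual, 6 days),
# generated and annotated once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(...) {
  generator_config(n_individuals = 1, n_days = 6, seed = 11,
                   nesting_window = c(2, 4), ...)
}

small_run <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- small_config()
    env <- generate_environment(cfg)
    ind <- generate_individual(cfg, 1, env)
    ann <- annotate_deployment(ind$env, ind$accel, ind$meta, env$ref)
    .fixtures$small <- list(cfg = cfg, env = env, ind = ind, ann = ann,
                            eval = evaluate_against_truth(ann, ind$truth))
  }
  .fixtures$small
}

# A deterministic logistic-response simulator for the basking model tests.
simulate_basking_design <- function(n, slopes, n_individuals = 4,
                                    intercept = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(individual = rep(sprintf("I%d", seq_len(n_individuals)),
                                   length.out = n))
  eta <- rep(intercept, n)
  for (nm in names(slopes)) {
    d[[nm]] <- stats::rnorm(n)
    eta <- eta + slopes[[nm]] * d[[nm]]
  }
  d$midday <- stats::rbinom(n, 1, stats::plogis(eta))
  d$date <- as.Date("2017-05-01") + seq_len(n)
  d
}
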
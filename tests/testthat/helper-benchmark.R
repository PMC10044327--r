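# Full-scale synthetic benchmark fixtures (120 s sessions, pattern 6,
# H = 64), generated once per test run and shared by the recovery and
# decoding tests.
benchmark_session <- function(motion) {
  fixture(paste0("bench_", motion), function() {
    generate_session(session_config(motion, duration_s = 120,
                                    seed = if (motion == "pcm") 101 else 102))
  })
}

benchmark_features <- function(motion) {
  fixture(paste0("bench_feat_", motion), function() {
    preprocess_session(benchmark_session(motion))
  })
}

benchmark_fit <- function(motion) {
  fixture(paste0("bench_fit_", motion), function() {
    ds <- build_dataset(benchmark_features(motion), pattern_id = 6)
    model <- fit_grf_lstm(ds, train_config(seed = 101))
    est <- predict(model, ds$test, standardized = TRUE)
    baseline <- vapply(wrench_channels(), function(ch) {
      percent_rmse(rep(mean(ds$train[[ch]]), nrow(ds$test)), ds$test[[ch]])
    }, numeric(1))
    list(dataset = ds, model = model, estimate = est,
         report = evaluate_wrench(est, ds$test[, wrench_channels()],
                                  pattern_id = 6, motion_type = motion),
         baseline = baseline)
  })
}
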
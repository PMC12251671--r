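# Shared fixtures. Everything is generated in code; heavyweight artefacts
# (the ablation training runs) are computed once and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

random_pose3d <- function(seed = 1, scale = 300, frame = "root_relative") {
  poselift:::with_rng(seed, pose3d(matrix(rnorm(133 * 3, 0, scale), 133, 3),
                                   frame = frame))
}

tiny_benchmark <- function(seed = 31) {
  key <- paste0("bench", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_benchmark(
      synth_config(n_train = 64, n_val = 32, n_test = 32, seed = seed),
      poses_per_skeleton = 8)
  .fixture_env[[key]]
}

tiny_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- poselift(tiny_benchmark(),
                                 training = desk_training(seed = 4, epochs = 2))
  .fixture_env$fit
}

# Scaled-down loss ablation: 3 loss configurations x 5 replicate seeds on the
# default synthetic benchmark (2000 train samples, desk profiles), plus the
# same test geometry re-rendered at occlusion 0.30 for the robustness check.
ablation_results <- function() {
  if (!is.null(.fixture_env$ablation)) return(.fixture_env$ablation)
  lay <- wb_layout()
  seeds <- 101:105
  configs <- list(total = c(1, 1, 1), pos_cog = c(1, 1, 0), pos = c(1, 0, 0))
  rows <- list()
  for (seed in seeds) {
    bench <- make_benchmark(synth_config(seed = seed))
    bench_hi <- make_benchmark(synth_config(seed = seed, occlusion_prob = 0.3))
    t_lo <- poselift:::prepare_split(bench$test, lay, 256)
    t_hi <- poselift:::prepare_split(bench_hi$test, lay, 256)
    for (cn in names(configs)) {
      wc <- configs[[cn]]
      w <- loss_weights(w_pos = wc[1], w_cog = wc[2], w_bone = wc[3])
      fit <- poselift(bench, training = desk_training(seed = seed, weights = w))
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, config = cn,
        test_mpjpe = poselift:::eval_mpjpe(fit$params, fit$model, t_lo, lay$edges),
        test_mpjpe_occ30 = poselift:::eval_mpjpe(fit$params, fit$model, t_hi,
                                                 lay$edges),
        val_mpjpe = fit$val_mpjpe,
        val_mpjpe_epoch1 = fit$history$val_mpjpe[1])
    }
  }
  .fixture_env$ablation <- do.call(rbind, rows)
  .fixture_env$ablation
}
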
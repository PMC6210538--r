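# Shared, memoized end-to-end experiments.  The pose-recovery experiment
# (200 training frames, 50-frame evaluation sequence at 120 x 160, the
# standard small-frame detector profile) is expensive, so it is trained once
# and reused by every test that needs a real trained model.

.experiment_cache <- new.env(parent = emptyenv())

recovery_experiment <- function(seed = 1L) {
  key <- paste0("recovery_", seed)
  if (is.null(.experiment_cache[[key]])) {
    cfg <- figure_config()
    tr <- generate_training_frames(200, cfg, seed = seed)
    ng <- generate_negative_frames(10, cfg, seed = seed + 1L)
    sq <- generate_sequence(cfg, n_frames = 50, seed = seed + 2L)
    fit <- train_model(tr, ng, standard_training_config(seed))
    poses <- detect_sequence(fit$model, sq$frames, omega_dist = 30)
    .experiment_cache[[key]] <- list(cfg = cfg, fit = fit, sq = sq,
                                     poses = poses)
  }
  .experiment_cache[[key]]
}

# Separable margin-audit dataset: clean figures vs blank/noise negatives on
# 80 x 80 frames, trained near the hard-margin regime (large C).
margin_experiment <- function(seed = 11L) {
  key <- paste0("margin_", seed)
  if (is.null(.experiment_cache[[key]])) {
    cfg <- small_fig()
    tr <- generate_training_frames(50, cfg, seed = seed)
    ng <- generate_negative_frames(20, cfg, seed = seed + 1L, clutter = FALSE)
    tc <- training_config(C = 10, states_per_part = 3L, max_passes = 4L,
                          feature = feature_config(cell_size_px = 3L, bins = 9L,
                                                   min_level_px = 40L),
                          seed = 1L, cache_cap = 200L, neg_top_k = 15L,
                          mine_rounds = 8L, mine_nms = 0.7,
                          inner_sweeps = 3000L, inner_tol = 5e-5)
    .experiment_cache[[key]] <- train_model(tr, ng, tc)
  }
  .experiment_cache[[key]]
}
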
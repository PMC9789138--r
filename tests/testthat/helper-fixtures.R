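# Shared fixtures, trained once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# the standard pixel model used across tests: trained on the package's
# synthetic training set (one frame per density regime)
cached_model <- function() {
  if (is.null(.fixture_cache$model)) {
    ts <- synthetic_training_set(seed = 11)
    .fixture_cache$model <- train_pixel_classifier(ts$images, ts$labels,
                                                   seed = 11)
  }
  .fixture_cache$model
}

# a quick model on a small bank/canvas for determinism-style tests
small_model <- function() {
  if (is.null(.fixture_cache$small_model)) {
    ts <- synthetic_training_set(regimes = "medium", canvas = 129,
                                 labels_per_class = 400, seed = 5)
    bank <- feature_bank(sigmas = c(0.7, 1.6, 3.5))
    .fixture_cache$small_model <- train_pixel_classifier(
      ts$images, ts$labels, bank = bank, seed = 5, num_trees = 50)
  }
  .fixture_cache$small_model
}

# render a single static frame with the requested per-cell states
render_static_frame <- function(n_cells, detached_frac, canvas = 160,
                                regime = "medium", seed = 3) {
  set.seed(seed)
  geom <- detachmon:::sample_cell_geometry(n_cells, c(canvas, canvas), regime)
  state <- ifelse(seq_len(n_cells) <= round(detached_frac * n_cells),
                  "detached", "attached")
  render_frame(detachmon:::cells_at_state(geom, state),
               canvas = c(canvas, canvas), regime = regime, seed = seed + 1)
}
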
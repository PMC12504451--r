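# Shared fixtures.  The trained model is expensive (a few minutes), so it
# is built lazily once per session and reused by every test that needs a
# fitted network.  Training conditions: 200 records per class from the
# clinical_100 profile (10 s @ 100 Hz), default pipeline preprocessing,
# default model configuration (seed 7).

.fixture_env <- new.env(parent = emptyenv())

clean_beat_signal <- function(hr = 60, duration = 10, fs = 100, seed = 1,
                              class = "norm") {
  out <- synthRecord(synthConfig(class, duration_s = duration, fs = fs,
                                 heart_rate_bpm = hr, seed = seed))
  list(signal = signals(out$record)[[1]], truth = out$truth,
       record = out$record)
}

shared_train_images <- function() {
  if (is.null(.fixture_env$train_images)) {
    ds <- makeDataset(200, "clinical_100", seed = 101)
    .fixture_env$train_images <- recordsToImages(ds$records, pipelineConfig())
  }
  .fixture_env$train_images
}

shared_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    tr <- shared_train_images()
    model <- buildModel(modelConfig())
    .fixture_env$model <- trainModel(model, tr$images, tr$labels)
  }
  .fixture_env$model
}
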
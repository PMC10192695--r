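# Lazily computed fixtures shared across test files (one computation per
# test session). All fixtures are generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 50 segments per class pushed through preprocessing, pooled HHT band
# fractions and thresholded STE networks
contrast_fixture <- function() fixture("contrast", function() {
  seeds <- 1:50
  build <- function(label) {
    lapply(seeds, function(s) {
      gen <- generate_segment(regime_spec(label, seed = 2000 + s))
      seg <- bandpass_filter(gen$segment)
      net <- threshold_network(ste_matrix(seg), 0.02)
      list(delta = segment_band_energies(seg)$fractions[["delta"]],
           net = net,
           metrics = network_metrics(net, label = label))
    })
  }
  list(ictal = build("ictal"), interictal = build("interictal"))
})

# trained classifier on 100 segments per class (spectrogram stacks)
classifier_fixture <- function() fixture("classifier", function() {
  n_per_class <- 100L
  labels <- rep(c("interictal", "ictal"), n_per_class)
  stacks <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    gen <- generate_segment(regime_spec(labels[k], seed = 3000 + k))
    stacks[[k]] <- segment_stack(bandpass_filter(gen$segment))
  }
  model <- train_classifier(stacks, labels = labels,
                            cfg = classifier_config(epochs = 20, seed = 7))
  list(stacks = stacks, labels = labels, model = model)
})

# one preprocessed segment per class
segment_fixture <- function() fixture("segments", function() {
  lapply(c(ictal = "ictal", interictal = "interictal"), function(lbl)
    bandpass_filter(generate_segment(regime_spec(lbl, seed = 11))$segment))
})
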
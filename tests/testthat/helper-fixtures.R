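# Shared fixtures. Expensive objects (synthetic corpora, trained machine
# pools) are built once per test run and memoized here; everything is
# generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small in-memory corpus plus features for unit tests.
tiny_corpus <- function(seed = 11, effect = 1, n_per_class = 4,
                        duration_mean = 22, duration_sd = 4,
                        test_frac = 0.25) {
  simulate_corpus(synth_config(
    n_per_class = n_per_class, duration_mean = duration_mean,
    duration_sd = duration_sd, effect = effect, test_frac = test_frac,
    seed = seed))
}

corpus_durations <- function(corpus) {
  stats::setNames(corpus$roster$duration, corpus$roster$speaker_id)
}

# Random rectangular prediction table: M machines x (speakers x crops).
random_pred_table <- function(M, n_speakers, L, seed) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_speakers))
  do.call(rbind, lapply(seq_len(M), function(m) {
    data.frame(machine_id = m,
               speaker_id = rep(ids, each = L),
               crop_index = rep(seq_len(L), n_speakers),
               prob = stats::runif(n_speakers * L),
               stringsAsFactors = FALSE)
  }))
}

# Fake feature container with arbitrary geometry, for operations that do
# not care about acoustic content.
fake_features <- function(F0, T0, meta, seed = 1) {
  set.seed(seed)
  structure(list(x = array(stats::runif(F0 * T0 * nrow(meta)),
                           c(F0, T0, nrow(meta))),
                 meta = meta, params = list()),
            class = "crop_features")
}

# Spectral-tilt feature of one 4-s crop: mean log energy above 3 kHz minus
# below 1.5 kHz. Independent oracle for the generator's class signal.
band_tilt <- function(crop, rate = 16000) {
  sp <- compute_log_spectrogram(crop, rate = rate)
  f <- seq(0, rate / 2, length.out = nrow(sp))
  mean(sp[f > 3000, ]) - mean(sp[f < 1500, ])
}

# The scaled ensemble pool shared by the heavier end-to-end checks:
# effect = 1, 20 speakers/class, pool of 16 reduced machines.
ensemble_pool <- function() {
  get_fixture("ensemble_pool", function() {
    cfg <- synth_config(n_per_class = 20, duration_mean = 44,
                        duration_sd = 10, effect = 1, test_frac = 0.3,
                        seed = 101)
    corpus <- simulate_corpus(cfg)
    durations <- corpus_durations(corpus)
    loader <- audio_loader_memory(corpus$recordings)
    plan <- materialize_plan(corpus$roster, durations,
                             seed = derive_seed(101, "plan"))
    test_man <- crop_test_speakers(corpus$roster, durations)
    ft_train <- extract_features(loader, plan$manifest)
    ft_test <- extract_features(loader, test_man)
    models <- train_ensemble(
      ft_train, cnn = cnn_config(N = 8, n4 = 16, epochs = 30, batch = 20),
      ens = ensemble_config(M = 16, method = 1, base_seed = 202))
    tbl <- predict_table(models, ft_test)
    truth <- stats::setNames(
      test_man$label[!duplicated(test_man$speaker_id)],
      unique(test_man$speaker_id))
    list(tbl = tbl, truth = truth)
  })
}
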
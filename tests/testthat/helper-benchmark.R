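# Shared synthetic benchmark runs for the end-to-end tests. Training runs
# are memoised so several test blocks can assert on the same fits without
# re-training.

.bench_env <- new.env(parent = emptyenv())

bench_dataset <- function() {
  if (is.null(.bench_env$ds)) {
    .bench_env$ds <- synth_dataset(n_drugs = 300, n_pairs = 3000,
                                   noise = 0.1, seed = 7)
    .bench_env$warm <- make_warm_split(.bench_env$ds$triplets, k = 5, seed = 3)
    .bench_env$cold <- make_cold_split(.bench_env$ds$triplets,
                                       .bench_env$ds$drugs$drug_id,
                                       frac_new = 0.2, seed = 3)
  }
  list(ds = .bench_env$ds, warm = .bench_env$warm, cold = .bench_env$cold)
}

# Desk-scale benchmark configuration: embedding width 32, two layers and four
# heads per encoder, 5 contrastive + 45 supervised epochs (50 total),
# mini-batches of 64 pairs; all other settings at package defaults.
bench_cfg <- function(seed, variant = "full") {
  ddi_config(d = 32, graph = list(heads = 4, layers = 2),
             seq = list(heads = 4, layers = 2),
             fusion = list(d_f = 64), predict = list(hidden = 64),
             train = list(epochs = 45, epochs_cl = 5, batch_size = 64),
             variant = variant, seed = seed)
}

bench_seeds <- c(11L, 22L, 33L)

bench_fit <- function(name) {
  if (!is.null(.bench_env[[name]])) return(.bench_env[[name]])
  b <- bench_dataset()
  parts <- strsplit(name, "_(?=[0-9]+$)", perl = TRUE)[[1]]
  kind <- parts[1]; seed <- as.integer(parts[2])
  fit <- switch(kind,
    warm_full = train_model(b$ds$drugs, b$warm, bench_cfg(seed)),
    cold_full = train_model(b$ds$drugs, b$cold, bench_cfg(seed)),
    cold_nograph = train_model(b$ds$drugs, b$cold,
                               bench_cfg(seed, "no_graph_view")),
    cold_noseq = train_model(b$ds$drugs, b$cold,
                             bench_cfg(seed, "no_sequence_view")),
    warm_permuted = {
      set.seed(99)
      dsp <- b$ds
      dsp$triplets$label <- sample(dsp$triplets$label)
      spp <- make_warm_split(dsp$triplets, k = 5, seed = 3)
      train_model(dsp$drugs, spp, bench_cfg(seed))
    },
    stop("unknown benchmark run: ", name))
  .bench_env[[name]] <- fit
  fit
}
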
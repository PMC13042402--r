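# Shared fixtures, built once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small paired bulk simulation with known coupling
tiny_bulk <- function() {
  fixture("tiny_bulk", function() {
    simulate_bulk_paired(bulk_sim_spec(
      n_samples = 1200, n_genes = 200, n_mirnas = 40, n_families = 8,
      coupling_density = 0.05, noise_sd = 0, n_factors = 20, seed = 101))
  })
}

# model trained on the first 500 rows of tiny_bulk (z-scored internally);
# rows 501:700 are the held-out evaluation set
tiny_fit <- function() {
  fixture("tiny_fit", function() {
    sim <- tiny_bulk()
    fit_mirna_model(unclass(sim$mrna_log2)[1:500, ],
                    unclass(sim$mirna)[1:500, ],
                    model_config(hidden_size = 128, max_epochs = 60,
                                 init_seed = 5))
  })
}

tiny_heldout <- function() {
  sim <- tiny_bulk()
  fit <- tiny_fit()
  X <- unclass(sim$mrna_log2)[501:700, ]
  Y <- unclass(sim$mirna)[501:700, ]
  yz <- sweep(sweep(Y, 2, fit$y_center), 2,
              ifelse(fit$y_scale > 0, fit$y_scale, 1), "/")
  list(X = X, Y = Y, yz = yz)
}

# z-score a matrix with a model's stored training statistics
zscore_with <- function(X, center, scale) {
  out <- sweep(X, 2, center)
  sweep(out, 2, ifelse(scale > 0, scale, 1), "/")
}

# small dense expression matrix with dimnames
toy_matrix <- function(n = 4, g = 5, seed = 1, rownames_prefix = "s") {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * g)), n, g,
              dimnames = list(paste0(rownames_prefix, seq_len(n)),
                              paste0("g", seq_len(g))))
  m
}
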
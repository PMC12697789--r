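# Shared fixtures: a miniature world, its feature bundle and a small model.
# Everything is built in code at test time; sizes are kept tiny so the full
# suite stays fast.

tiny_world <- function(seed = 11) {
  generate_world(n_compounds = 8, n_genes = 12, n_cells = 2, r = 3, seed = seed)
}

tiny_setup <- function(seed = 11, n_singleton_sets = 5, n_multisets = 3,
                       set_size_range = c(2, 4)) {
  world <- tiny_world(seed)
  tabs <- emit_tables(world, n_singleton_sets = n_singleton_sets,
                      n_multisets = n_multisets,
                      set_size_range = set_size_range, seed = seed)
  features <- emit_features(world, tabs$composition)
  list(world = world, tabs = tabs, features = features)
}

tiny_model <- function(seed = 3, variant = "concat", arch = "set", ...) {
  sp_model(d_set = 8, heads = 2, inducing = 2, d_fusion = 8,
           head_dims = c(16, 8, 4), variant = variant, arch = arch,
           seed = seed, ...)
}

tiny_train_config <- function(epochs = 2, seed = 1, ...) {
  train_config(epochs = epochs, batch_size = 64, learning_rate = 3e-3,
               seed = seed, ...)
}

random_feature_set <- function(n, dim = 1181, seed = 1) {
  set.seed(seed)
  if (dim <= 881) return(matrix(rnorm(n * dim), n, dim))
  cbind(matrix(rbinom(n * 881, 1, 0.3), n, 881),
        matrix(rnorm(n * (dim - 881)), n, dim - 881))
}
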
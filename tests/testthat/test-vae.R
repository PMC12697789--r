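# Cell-state VAE: closed-form loss, training sanity, deterministic
# embedding and hyperparameter grid search.

test_that("vae_loss matches hand-computed cases", {
  # perfect reconstruction at the prior: both terms vanish
  x <- matrix(rnorm(6), 2, 3)
  mu <- matrix(0, 2, 2); sig <- matrix(1, 2, 2)
  expect_equal(vae_loss(x, x, mu, sig, beta = 3), 0)
  # N=1, d=1, x=xhat, mu=1, sigma=1, beta=2 -> (2/2)*(1+1-0-1) = 1
  expect_equal(vae_loss(matrix(0), matrix(0), matrix(1), matrix(1), beta = 2), 1)
  expect_error(vae_loss(x, x, mu, matrix(c(1, -1, 1, 1), 2, 2)), "positive")
})

test_that("vae_loss agrees with an elementwise-sum oracle on random batches", {
  oracle <- function(x, xhat, mu, sigma, beta) {
    recon <- 0
    for (i in seq_len(nrow(x))) recon <- recon + sum((x[i, ] - xhat[i, ])^2)
    kl <- 0
    for (i in seq_len(nrow(mu)))
      for (j in seq_len(ncol(mu)))
        kl <- kl + sigma[i, j]^2 + mu[i, j]^2 - log(sigma[i, j]^2) - 1
    recon / nrow(x) + beta / 2 * kl / nrow(mu)
  }
  set.seed(81)
  for (rep in 1:5) {
    n <- sample(2:6, 1); d_in <- sample(3:8, 1); d <- sample(2:4, 1)
    x <- matrix(rnorm(n * d_in), n); xhat <- matrix(rnorm(n * d_in), n)
    mu <- matrix(rnorm(n * d), n); sig <- matrix(rexp(n * d) + 0.1, n)
    beta <- runif(1, 0.5, 3)
    expect_equal(vae_loss(x, xhat, mu, sig, beta),
                 oracle(x, xhat, mu, sig, beta), tolerance = 1e-6)
  }
})

rank2_matrix <- function(n = 60, g = 20, seed = 82) {
  set.seed(seed)
  u <- matrix(rnorm(n * 2), n, 2)
  v <- matrix(rnorm(2 * g), 2, g)
  u %*% v + matrix(rnorm(n * g, sd = 0.05), n, g)
}

test_that("training reduces reconstruction loss on learnable low-rank data", {
  X <- rank2_matrix()
  cfg <- cell_vae_config(batch_size = 16, learning_rate = 1e-2,
                         mlp_dims = c(16, 8, 6), latent_dim = 2, epochs = 8)
  vae <- train_cell_vae(X, cfg, seed = 1)
  expect_lt(tail(vae$losses, 1), vae$losses[1])
  # seeded determinism
  vae2 <- train_cell_vae(X, cfg, seed = 1)
  expect_identical(vae$losses, vae2$losses)
  expect_error(train_cell_vae(rbind(X, NA), cfg), "non-finite")
})

test_that("cell embedding is the deterministic posterior mean of the right length", {
  X <- rank2_matrix()
  cfg <- cell_vae_config(batch_size = 16, learning_rate = 1e-2,
                         mlp_dims = c(16, 8, 6), latent_dim = 4, epochs = 3)
  vae <- train_cell_vae(X, cfg, seed = 2)
  e <- embed_cell(X[1, ], vae, cell_id = "c1")
  expect_s3_class(e, "cell_embedding")
  expect_length(e$latent, 4)
  expect_identical(embed_cell(X[1, ], vae)$latent, e$latent)
  expect_true(all(is.finite(embed_cell(rep(0, ncol(X)), vae)$latent)))
  expect_error(embed_cell(rep(0, 3), vae), "dimension")
  M <- embed_cell(X[1:5, ], vae)
  expect_identical(dim(M), c(5L, 4L))
  expect_equal(M[1, ], e$latent, tolerance = 1e-12)
})

test_that("configuration invariants are enforced and the reference grid is shaped", {
  expect_error(cell_vae_config(mlp_dims = c(64, 64, 16)), "decreasing")
  expect_error(cell_vae_config(mlp_dims = c(64, 32, 16), latent_dim = 16),
               "latent_dim")
  expect_error(cell_vae_config(beta = 0), "beta")
  g <- vae_grid_default()
  expect_identical(g$batch_size, c(32, 64, 128, 256))
  expect_identical(g$latent_dim, c(64, 32, 16))
  expect_identical(prod(lengths(g)), 4 * 3 * 3 * 3 * 3 * 3)
})

test_that("grid search rejects a sabotaged configuration and logs all points", {
  X <- rank2_matrix(n = 60)
  ranges <- list(batch_size = 8, learning_rate = c(1e-2, 0),
                 dim1 = 16, dim2 = 8, dim3 = 6, latent_dim = 2)
  best <- grid_search_vae(X, ranges, epochs = 20, seed = 3)
  expect_identical(best$learning_rate, 1e-2)
  res <- attr(best, "results")
  expect_identical(nrow(res), 2L)
  # selection agrees with re-reading the logged table
  expect_identical(res$learning_rate[which.min(res$val_recon)],
                   best$learning_rate)
})
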
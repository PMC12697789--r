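# Cell-state variational autoencoder.
#
# Encoder: three fully connected layers with progressively reduced widths,
# then linear maps to the posterior mean and log-variance of a diagonal
# Gaussian latent; decoder mirrors the encoder. Trained by minimizing
# reconstruction MSE plus a beta-weighted KL divergence to the standard
# normal prior:
#
#   L = (1/N) sum_i ||x_i - xhat_i||^2
#       + (beta/2) * mean_i sum_j (sigma_ij^2 + mu_ij^2 - log sigma_ij^2 - 1)
#
# (the KL sum over latent dimensions is averaged over the batch, matching
# the 1/N normalization of the reconstruction term). Frozen cell embeddings
# are the posterior mean, so embedding is deterministic.

#' Cell VAE configuration
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param mlp_dims three strictly decreasing encoder widths.
#' @param latent_dim latent dimensionality (must be below the smallest MLP
#'   width; default 64, the reference cell-embedding length).
#' @param beta KL weight (> 0).
#' @param epochs training epochs (reference protocol: 20).
#' @return a `"cell_vae_config"` list.
#' @export
cell_vae_config <- function(batch_size = 128, learning_rate = 1e-3,
                            mlp_dims = c(1024, 512, 256), latent_dim = 64,
                            beta = 1, epochs = 20) {
  if (length(mlp_dims) != 3 || any(diff(mlp_dims) >= 0))
    stop("mlp_dims must be three strictly decreasing widths")
  if (latent_dim >= min(mlp_dims)) stop("latent_dim must be below the smallest MLP width")
  if (beta <= 0) stop("beta must be positive")
  structure(list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 mlp_dims = mlp_dims, latent_dim = as.integer(latent_dim),
                 beta = beta, epochs = as.integer(epochs)),
            class = "cell_vae_config")
}

#' Reference VAE hyperparameter grid
#'
#' The grid searched for the cell-state VAE: batch sizes 32/64/128/256,
#' learning rates 1e-3/1e-4/1e-5, three MLP widths (4096/2048/1024,
#' 1024/512/256, 256/128/64) and latent dimensions 64/32/16; each
#' combination trained for 20 epochs.
#'
#' @return named list of value vectors suitable for [grid_search_vae()].
#' @export
vae_grid_default <- function() {
  list(batch_size = c(32, 64, 128, 256),
       learning_rate = c(1e-3, 1e-4, 1e-5),
       dim1 = c(4096, 2048, 1024),
       dim2 = c(1024, 512, 256),
       dim3 = c(256, 128, 64),
       latent_dim = c(64, 32, 16))
}

#' Closed-form VAE loss
#'
#' Reconstruction MSE plus beta-weighted KL divergence, as defined above.
#'
#' @param x,xhat input and reconstruction batches (`N x d_in` matrices).
#' @param mu,sigma posterior means and standard deviations (`N x d` matrices;
#'   `sigma` strictly positive).
#' @param beta KL weight.
#' @return scalar loss (always `>= 0` for `beta > 0`).
#' @export
vae_loss <- function(x, xhat, mu, sigma, beta = 1) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  stopifnot(all(dim(x) == dim(xhat)), all(dim(mu) == dim(sigma)),
            nrow(x) == nrow(mu))
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  recon <- sum((x - xhat)^2) / nrow(x)
  kl <- (beta / 2) * mean(rowSums(sigma^2 + mu^2 - log(sigma^2) - 1))
  recon + kl
}

vae_params <- function(d_in, cfg) {
  d <- cfg$mlp_dims
  list(enc = list(l1 = init_linear(d_in, d[1]), l2 = init_linear(d[1], d[2]),
                  l3 = init_linear(d[2], d[3])),
       mu = init_linear(d[3], cfg$latent_dim),
       logvar = init_linear(d[3], cfg$latent_dim),
       dec = list(l1 = init_linear(cfg$latent_dim, d[3]),
                  l2 = init_linear(d[3], d[2]), l3 = init_linear(d[2], d[1]),
                  out = init_linear(d[1], d_in)))
}

vae_encode_nodes <- function(wp, X) {
  h <- ag_linear_relu(X, wp$enc$l1)
  h <- ag_linear_relu(h, wp$enc$l2)
  h <- ag_linear_relu(h, wp$enc$l3)
  list(mu = ag_linear(h, wp$mu), logvar = ag_linear(h, wp$logvar))
}

vae_decode_nodes <- function(wp, Z) {
  h <- ag_linear_relu(Z, wp$dec$l1)
  h <- ag_linear_relu(h, wp$dec$l2)
  h <- ag_linear_relu(h, wp$dec$l3)
  ag_linear(h, wp$dec$out)
}

#' Train the cell-state VAE
#'
#' @param matrix numeric samples x genes expression matrix (log scale);
#'   a path to a TSV file (samples in rows, header of gene ids) is also
#'   accepted.
#' @param config a [cell_vae_config()].
#' @param seed integer seed (initialization, shuffling, reparameterization
#'   noise).
#' @return object of class `"cell_vae"`: parameters, config, input dimension
#'   and the per-epoch training loss trajectory.
#' @export
train_cell_vae <- function(matrix, config = cell_vae_config(), seed = 1) {
  if (is.character(matrix))
    matrix <- as.matrix(utils::read.delim(matrix, row.names = NULL, check.names = FALSE))
  X <- as.matrix(matrix)
  if (any(!is.finite(X))) stop("expression matrix contains non-finite values")
  set.seed(seed)
  params <- vae_params(ncol(X), config)
  opt <- adam_new(lr = config$learning_rate)
  n <- nrow(X)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    steps <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot <- 0
    for (rows in steps) {
      xb <- X[rows, , drop = FALSE]
      wp <- wrap_params(params)
      enc <- vae_encode_nodes(wp, as_ag(xb))
      eps <- base::matrix(stats::rnorm(length(ag_value(enc$mu))),
                          nrow(ag_value(enc$mu)))
      z <- ag_add(enc$mu, ag_mul(ag_exp(ag_scale(enc$logvar, 0.5)), as_ag(eps)))
      xhat <- vae_decode_nodes(wp, z)
      recon <- ag_sse_rows_mean(xhat, as_ag(xb))
      # KL per sample: sum_j exp(logvar) + mu^2 - logvar - 1, batch-averaged
      klmat <- ag_sub(ag_add(ag_exp(enc$logvar), ag_square(enc$mu)),
                      ag_add(enc$logvar, as_ag(base::matrix(1, length(rows),
                                                            config$latent_dim))))
      kl <- ag_scale(ag_mean(klmat), config$beta * config$latent_dim / 2)
      loss <- ag_add(recon, kl)
      ag_backward(loss)
      params <- adam_step(opt, params, wp)
      tot <- tot + ag_value(loss)[1] * length(rows)
    }
    losses[epoch] <- tot / n
  }
  structure(list(params = params, config = config, input_dim = ncol(X),
                 losses = losses, seed = seed),
            class = "cell_vae")
}

#' Embed an expression profile with a trained VAE
#'
#' The embedding is the posterior mean, so it is deterministic for a fixed
#' trained VAE and input profile.
#'
#' @param profile numeric expression vector (length = VAE input dimension)
#'   or a samples x genes matrix.
#' @param vae a trained `"cell_vae"`.
#' @param cell_id optional identifier stored in the result.
#' @return for a vector input, a `"cell_embedding"` (list with `cell_id` and
#'   `latent`); for a matrix, a samples x latent_dim matrix.
#' @export
embed_cell <- function(profile, vae, cell_id = NA_character_) {
  single <- !is.matrix(profile)
  X <- if (single) base::matrix(profile, nrow = 1L) else as.matrix(profile)
  if (ncol(X) != vae$input_dim)
    stop("profile length ", ncol(X), " does not match VAE input dimension ",
         vae$input_dim)
  wp <- wrap_params(vae$params)
  mu <- ag_value(vae_encode_nodes(wp, as_ag(X))$mu)
  if (single)
    structure(list(cell_id = cell_id, latent = drop(mu)), class = "cell_embedding")
  else {
    rownames(mu) <- rownames(X)
    mu
  }
}

#' Grid search over VAE hyperparameters
#'
#' Trains one VAE per admissible grid point (strictly decreasing MLP widths,
#' latent below the smallest width) on a 90/10 sample split and returns the
#' configuration with the lowest validation reconstruction loss. The full
#' results table is attached as the `"results"` attribute.
#'
#' @param matrix samples x genes expression matrix.
#' @param ranges named list of value vectors: `batch_size`, `learning_rate`,
#'   `dim1`, `dim2`, `dim3`, `latent_dim` (see [vae_grid_default()]);
#'   optionally `beta`.
#' @param epochs epochs per grid point.
#' @param seed integer seed (split and training).
#' @return the best `"cell_vae_config"` with attribute `"results"`.
#' @export
grid_search_vae <- function(matrix, ranges, epochs = 20, seed = 1) {
  if (!length(ranges)) stop("ranges must be nonempty")
  X <- as.matrix(matrix)
  pts <- expand.grid(ranges, stringsAsFactors = FALSE)
  keep <- with(pts, dim1 > dim2 & dim2 > dim3 & latent_dim < dim3)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) stop("no admissible configuration in the grid")
  set.seed(seed)
  val <- sample.int(nrow(X), max(1L, round(0.1 * nrow(X))))
  res <- pts
  res$val_recon <- NA_real_
  best <- NULL; best_loss <- Inf
  for (i in seq_len(nrow(pts))) {
    cfg <- cell_vae_config(batch_size = pts$batch_size[i],
                           learning_rate = pts$learning_rate[i],
                           mlp_dims = c(pts$dim1[i], pts$dim2[i], pts$dim3[i]),
                           latent_dim = pts$latent_dim[i],
                           beta = if ("beta" %in% names(pts)) pts$beta[i] else 1,
                           epochs = epochs)
    vae <- train_cell_vae(X[-val, , drop = FALSE], cfg, seed = seed)
    wp <- wrap_params(vae$params)
    enc <- vae_encode_nodes(wp, as_ag(X[val, , drop = FALSE]))
    xhat <- ag_value(vae_decode_nodes(wp, enc$mu))
    recon <- sum((X[val, , drop = FALSE] - xhat)^2) / length(val)
    res$val_recon[i] <- recon
    if (recon < best_loss) { best_loss <- recon; best <- cfg }
  }
  attr(best, "results") <- res
  best
}
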
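# Set Transformer building blocks.
#
# MAB(X, Y) = LayerNorm(H + rFF(H)),  H = LayerNorm(X + Multihead(X, Y, Y))
# SAB(X)   = MAB(X, X)
# ISAB(X)  = MAB(X, MAB(I, X))           with m learned inducing rows I
# PMA(X)   = MAB(S, X)                   with k learned seed rows S
#
# All blocks operate on "sets as matrices": one element per row, a fixed
# feature dimension per column. MAB is permutation-equivariant in X and
# invariant to permutations of Y's rows; PMA is therefore fully
# permutation-invariant. Blocks are initialized once (seeded) and applied
# functionally, either inside a training graph (ag nodes) or on plain
# matrices through the exported wrappers.

mab_params <- function(dim, heads) {
  stopifnot(dim %% heads == 0)
  dh <- dim %/% heads
  one <- function() lapply(seq_len(heads), function(h) init_mat(dim, dh))
  list(
    Wq = one(), Wk = one(), Wv = one(),
    Wo = init_mat(dim, dim),
    ff = list(W1 = init_mat(dim, dim), b1 = matrix(0, 1, dim),
              W2 = init_mat(dim, dim), b2 = matrix(0, 1, dim))
  )
}

mab_forward <- function(p, X, Y, heads) {
  dh <- ncol(ag_value(X)) %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    Q <- ag_matmul(X, p$Wq[[h]])
    K <- ag_matmul(Y, p$Wk[[h]])
    V <- ag_matmul(Y, p$Wv[[h]])
    A <- ag_softmax_rows(ag_scaled_matmul_t(Q, K, 1 / sqrt(dh)))
    outs[[h]] <- ag_matmul(A, V)
  }
  MH <- ag_matmul(if (heads == 1L) outs[[1]] else ag_cbind(outs), p$Wo)
  H <- ag_res_layernorm(X, MH)
  FF <- ag_affine(ag_affine(H, p$ff$W1, p$ff$b1, relu = TRUE), p$ff$W2, p$ff$b2)
  ag_res_layernorm(H, FF)
}

isab_params <- function(dim, m, heads) {
  if (m < 1) stop("isab requires at least one inducing point")
  list(I = init_mat(m, dim), mab1 = mab_params(dim, heads),
       mab2 = mab_params(dim, heads))
}

isab_forward <- function(p, X, heads) {
  H <- mab_forward(p$mab1, p$I, X, heads)
  mab_forward(p$mab2, X, H, heads)
}

pma_params <- function(dim, k, heads) {
  if (k < 1) stop("pma requires at least one seed vector")
  list(S = init_mat(k, dim), mab = mab_params(dim, heads))
}

pma_forward <- function(p, X, heads) mab_forward(p$mab, p$S, X, heads)

# ---- exported, plain-matrix interfaces --------------------------------------

check_heads <- function(dim, heads) {
  if (heads < 1 || dim %% heads != 0)
    stop("number of heads (", heads, ") must divide the model dimension (", dim, ")")
}

#' Initialize a Multihead Attention Block
#'
#' Creates the weight set of a MAB: per-head query/key/value projections, an
#' output projection and a row-wise feed-forward layer. The block computes
#' `LayerNorm(H + rFF(H))` with `H = LayerNorm(X + Multihead(X, Y, Y))`.
#'
#' @param dim model (feature) dimension; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param seed integer seed for weight initialization.
#' @return an object of class `"mab_block"`.
#' @export
mab_init <- function(dim, heads = 1, seed = 1) {
  check_heads(dim, heads)
  set.seed(seed)
  structure(list(params = mab_params(dim, heads), dim = dim, heads = heads),
            class = "mab_block")
}

#' Apply a Multihead Attention Block
#'
#' @param block a `"mab_block"` from [mab_init()].
#' @param X query set, one element per row (`n x dim`).
#' @param Y key/value set (`m x dim`).
#' @return transformed query set (`n x dim`). The output has one row per row
#'   of `X` (query equivariance) and is invariant to reordering rows of `Y`.
#' @export
mab <- function(block, X, Y) {
  stopifnot(inherits(block, "mab_block"))
  if (ncol(X) != block$dim || ncol(Y) != block$dim)
    stop("feature dimensions must equal the block dimension (", block$dim, ")")
  ag_value(mab_forward(block$params, as_ag(X), as_ag(Y), block$heads))
}

#' Initialize a Set Attention Block (self-attention MAB)
#' @inheritParams mab_init
#' @return an object of class `"sab_block"`.
#' @export
sab_init <- function(dim, heads = 1, seed = 1) {
  b <- mab_init(dim, heads, seed)
  class(b) <- c("sab_block", "mab_block")
  b
}

#' Apply a Set Attention Block: `sab(X) = mab(X, X)`
#' @param block a `"sab_block"`.
#' @param X set matrix (`n x dim`).
#' @return permutation-equivariant transformed set (`n x dim`).
#' @export
sab <- function(block, X) mab(block, X, X)

#' Initialize an Induced Set Attention Block
#'
#' Attention through `m` learned inducing rows: `ISAB(X) = MAB(X, MAB(I, X))`.
#' Cost is linear in the set cardinality for fixed `m`, and the parameter
#' count does not depend on the cardinality.
#'
#' @inheritParams mab_init
#' @param m number of inducing points (`>= 1`).
#' @return an object of class `"isab_block"`.
#' @export
isab_init <- function(dim, m = 16, heads = 1, seed = 1) {
  check_heads(dim, heads)
  if (m < 1) stop("isab requires m >= 1 inducing points")
  set.seed(seed)
  structure(list(params = isab_params(dim, m, heads), dim = dim, heads = heads, m = m),
            class = "isab_block")
}

#' Apply an Induced Set Attention Block
#' @param block an `"isab_block"`.
#' @param X set matrix (`n x dim`).
#' @return permutation-equivariant transformed set (`n x dim`).
#' @export
isab <- function(block, X) {
  stopifnot(inherits(block, "isab_block"))
  if (ncol(X) != block$dim) stop("feature dimension must equal block dimension")
  ag_value(isab_forward(block$params, as_ag(X), block$heads))
}

#' Initialize Pooling by Multihead Attention
#'
#' Attention pooling with `k` learned seed vectors: `PMA(X) = MAB(S, X)`.
#'
#' @inheritParams mab_init
#' @param k number of seed (output) vectors.
#' @return an object of class `"pma_block"`.
#' @export
pma_init <- function(dim, k = 1, heads = 1, seed = 1) {
  check_heads(dim, heads)
  if (k < 1) stop("pma requires k >= 1 seed vectors")
  set.seed(seed)
  structure(list(params = pma_params(dim, k, heads), dim = dim, heads = heads, k = k),
            class = "pma_block")
}

#' Apply Pooling by Multihead Attention
#' @param block a `"pma_block"`.
#' @param X set matrix (`n x dim`).
#' @return `k x dim` matrix of pooled vectors, invariant to row permutations
#'   of `X`.
#' @export
pma <- function(block, X) {
  stopifnot(inherits(block, "pma_block"))
  if (ncol(X) != block$dim) stop("feature dimension must equal block dimension")
  ag_value(pma_forward(block$params, as_ag(X), block$heads))
}
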
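# Permutation-invariant set embedding of compound mixtures.
#
# A mixture is an unordered collection of compound feature vectors (rows of a
# matrix). The embedding has two branches sharing one element-wise network:
#
#   shallow = rho( pool_i phi(x_i) )                       (Deep Sets)
#   deep    = rFF( PMA( ISAB( ISAB( {phi(x_i)} ) ) ) )     (Set Transformer)
#
# fused either by concatenation (length d_s + d_t) or elementwise addition
# (requires d_s == d_t). Invariance is made bitwise-exact by sorting the set
# elements into a canonical (lexicographic) order before any reduction, so
# floating-point summation order cannot depend on the input ordering.

# Canonical element order: primary key rowSums (exact, permutation-stable);
# ties among non-identical rows fall back to full lexicographic order.
# Identical duplicate rows may keep input order — they are interchangeable.
canonical_order <- function(X) {
  n <- nrow(X)
  if (n == 1L) return(1L)
  key <- rowSums(X)
  if (!anyDuplicated(key)) return(order(key))
  do.call(order, c(lapply(seq_len(ncol(X)), function(j) X[, j]),
                   list(method = "radix")))
}

set_core_params <- function(compound_dim, d, m, heads, n_isab = 2L) {
  p <- list(
    phi = list(l1 = init_linear(compound_dim, d), l2 = init_linear(d, d)),
    rho = list(l1 = init_linear(d, d), l2 = init_linear(d, d)),
    st = c(lapply(seq_len(n_isab), function(i) isab_params(d, m, heads)),
           list(pma = pma_params(d, 1L, heads),
                ff = list(l1 = init_linear(d, d), l2 = init_linear(d, d))))
  )
  names(p$st)[seq_len(n_isab)] <- paste0("isab", seq_len(n_isab))
  p
}

phi_forward <- function(p, F) {
  ag_linear(ag_linear_relu(F, p$phi$l1), p$phi$l2)
}

rho_forward <- function(p, pooled) {
  ag_linear(ag_linear_relu(pooled, p$rho$l1), p$rho$l2)
}

st_forward <- function(p, E, heads) {
  Z <- E
  for (nm in grep("^isab", names(p$st), value = TRUE))
    Z <- isab_forward(p$st[[nm]], Z, heads)
  pooled <- pma_forward(p$st$pma, Z, heads)
  ag_linear(ag_linear_relu(pooled, p$st$ff$l1), p$st$ff$l2)
}

# forward pass of the full set core on one set; F is an n x compound_dim
# constant (or node); returns the fused 1 x d_fused node.
set_core_forward <- function(p, F, pool, variant, heads) {
  Fv <- ag_value(F)
  F <- as_ag(Fv[canonical_order(Fv), , drop = FALSE])
  E <- phi_forward(p, F)
  shallow <- rho_forward(p, ag_rowpool(E, pool))
  deep <- st_forward(p, E, heads)
  if (variant == "concat") ag_cbind(list(shallow, deep)) else ag_add(shallow, deep)
}

#' Deep Sets embedding of a compound set
#'
#' Computes `rho(pool_i phi(x_i))` together with the per-element transformed
#' set `{phi(x_i)}` that feeds the Set Transformer branch. The output is
#' invariant to any permutation of the input rows (elements are canonically
#' ordered before pooling, so invariance is exact to the bit).
#'
#' @param model a fitted or freshly initialized model from [sp_model()].
#' @param features numeric matrix, one compound feature vector per row.
#' @return list with `pooled` (numeric vector, length `d_set`) and
#'   `elements` (matrix of per-element representations, canonical order).
#' @export
deep_sets_embed <- function(model, features) {
  features <- as_set_matrix(features, model$config$compound_dim)
  if (nrow(features) < 1) stop("compound set must contain at least one element")
  p <- model$params$core
  F <- features[canonical_order(features), , drop = FALSE]
  E <- phi_forward(p, as_ag(F))
  pooled <- rho_forward(p, ag_rowpool(E, model$config$pool))
  list(pooled = drop(ag_value(pooled)), elements = ag_value(E))
}

#' Set Transformer embedding of per-element representations
#'
#' Applies the configured ISAB/ISAB/PMA(k=1)/rFF stack to a matrix of
#' per-element representations (e.g. the `elements` output of
#' [deep_sets_embed()]) and returns a single permutation-invariant vector.
#'
#' @param model a model from [sp_model()].
#' @param elements numeric matrix, `n x d_set`.
#' @return numeric vector of length `d_set`.
#' @export
set_transformer_embed <- function(model, elements) {
  if (!is.matrix(elements)) elements <- matrix(elements, nrow = 1L)
  if (nrow(elements) < 1) stop("element collection must be nonempty")
  if (ncol(elements) != model$config$d_set)
    stop("element dimension must equal d_set (", model$config$d_set, ")")
  elements <- elements[canonical_order(elements), , drop = FALSE]
  drop(ag_value(st_forward(model$params$core, as_ag(elements), model$config$heads)))
}

#' Fused set embedding (Concat or Add variant)
#'
#' Runs both branches of the set core and fuses them: the Concat variant
#' concatenates the shallow (Deep Sets) and deep (Set Transformer) vectors,
#' the Add variant sums them elementwise (which requires equal branch
#' dimensions, enforced at model build time).
#'
#' @param model a model from [sp_model()].
#' @param features numeric matrix of compound features, one element per row.
#' @return list of class `"set_embedding"` with fields `shallow`, `deep`,
#'   `fused` (numeric vectors) and `variant`.
#' @export
set_embed <- function(model, features) {
  features <- as_set_matrix(features, model$config$compound_dim)
  if (nrow(features) < 1) stop("compound set must contain at least one element")
  p <- model$params$core
  F <- features[canonical_order(features), , drop = FALSE]
  E <- phi_forward(p, as_ag(F))
  shallow <- drop(ag_value(rho_forward(p, ag_rowpool(E, model$config$pool))))
  deep <- drop(ag_value(st_forward(p, E, model$config$heads)))
  fused <- if (model$config$variant == "concat") c(shallow, deep) else shallow + deep
  structure(list(shallow = shallow, deep = deep, fused = fused,
                 variant = model$config$variant),
            class = "set_embedding")
}

as_set_matrix <- function(x, dim) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != dim)
    stop("compound features have ", ncol(x), " columns; expected ", dim)
  x
}
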
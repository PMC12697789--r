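# The set-cell-gene association classifier.
#
# Pipeline: set core (Deep Sets + Set Transformer, R/set_embedding.R) ->
# projection of the fused set vector plus gene-network, gene-sequence and
# cell-state features into four tokens of a shared fusion dimension ->
# one self-attention block over the four tokens with residual layer
# normalization -> flatten -> three-layer MLP with strictly decreasing
# hidden widths -> 3 logits (0 = up, 1 = down, 2 = no change).
#
# Three architectures share this file:
#   "set"   the full model (default);
#   "noset" ablation: the set core is replaced by the mean of the member
#           compound features, attention and head retained;
#   "flat"  vanilla neural network: the prediction MLP alone on the raw
#           concatenated (mean-compound, gene, cell) features.

#' Construct a set-embedding perturbation classifier
#'
#' @param compound_dim length of one compound feature vector (default 1181 =
#'   881 fingerprint bits + 300 graph-embedding components).
#' @param gene_net_dim,gene_seq_dim gene feature dimensions (defaults 256 and
#'   768; their concatenation is the 1024-long gene feature).
#' @param cell_dim cell-state embedding length (default 64).
#' @param d_set width of both set-core branches (`d_s = d_t`).
#' @param heads attention heads in the set core; must divide `d_set`.
#' @param inducing number of ISAB inducing points.
#' @param n_isab number of stacked ISAB blocks in the deep branch.
#' @param pool Deep Sets pooling, `"mean"` (default, scale-stable across
#'   cardinalities) or `"sum"`.
#' @param variant set fusion, `"concat"` (fused length `2 * d_set`) or
#'   `"add"` (fused length `d_set`; branch widths are equal by construction).
#' @param d_fusion shared token dimension of the fusion attention block.
#' @param head_dims three strictly decreasing hidden widths of the prediction
#'   MLP.
#' @param arch `"set"`, `"noset"` or `"flat"` (see Details above).
#' @param seed integer seed for weight initialization.
#' @return an object of class `"sp_model"`: a list with `config` and `params`.
#' @export
sp_model <- function(compound_dim = 1181, gene_net_dim = 256, gene_seq_dim = 768,
                     cell_dim = 64, d_set = 256, heads = 4, inducing = 16,
                     n_isab = 2, pool = c("mean", "sum"),
                     variant = c("concat", "add"),
                     d_fusion = 128, head_dims = c(512, 128, 32),
                     arch = c("set", "noset", "flat"), seed = 1) {
  pool <- match.arg(pool)
  variant <- match.arg(variant)
  arch <- match.arg(arch)
  check_heads(d_set, heads)
  if (length(head_dims) != 3 || any(diff(head_dims) >= 0))
    stop("head_dims must be three strictly decreasing widths")
  d_fused <- if (variant == "concat") 2L * d_set else d_set
  cfg <- list(compound_dim = compound_dim, gene_net_dim = gene_net_dim,
              gene_seq_dim = gene_seq_dim, cell_dim = cell_dim,
              d_set = d_set, heads = heads, inducing = inducing,
              n_isab = as.integer(n_isab), pool = pool,
              variant = variant, d_fusion = d_fusion, head_dims = head_dims,
              arch = arch, d_fused = d_fused, seed = seed)
  set.seed(seed)
  params <- list()
  if (arch == "set") {
    params$core <- set_core_params(compound_dim, d_set, inducing, heads,
                                   n_isab = as.integer(n_isab))
    set_in <- d_fused
  } else {
    set_in <- compound_dim   # mean of member features stands in for the core
  }
  if (arch == "flat") {
    head_in <- compound_dim + gene_net_dim + gene_seq_dim + cell_dim
  } else {
    params$proj <- list(set = init_linear(set_in, d_fusion),
                        gene_net = init_linear(gene_net_dim, d_fusion),
                        gene_seq = init_linear(gene_seq_dim, d_fusion),
                        cell = init_linear(cell_dim, d_fusion))
    params$attn <- list(Wq = init_mat(d_fusion, d_fusion),
                        Wk = init_mat(d_fusion, d_fusion),
                        Wv = init_mat(d_fusion, d_fusion))
    head_in <- 4L * d_fusion
  }
  params$head <- list(l1 = init_linear(head_in, head_dims[1]),
                      l2 = init_linear(head_dims[1], head_dims[2]),
                      l3 = init_linear(head_dims[2], head_dims[3]),
                      out = init_linear(head_dims[3], 3L))
  structure(list(config = cfg, params = params, history = list()),
            class = "sp_model")
}

#' @export
print.sp_model <- function(x, ...) {
  cfg <- x$config
  cat("Set-embedding perturbation classifier\n")
  cat("  architecture:", cfg$arch, "| variant:", cfg$variant,
      "| d_set:", cfg$d_set, "| heads:", cfg$heads, "\n")
  cat("  parameters:", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model an `"sp_model"`.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

# ---- forward passes ----------------------------------------------------------

head_forward <- function(p, X, dropout = 0, training = FALSE) {
  h <- ag_linear_relu(X, p$l1)
  if (training && dropout > 0) h <- ag_dropout(h, dropout)
  h <- ag_linear_relu(h, p$l2)
  if (training && dropout > 0) h <- ag_dropout(h, dropout)
  h <- ag_linear_relu(h, p$l3)
  ag_linear(h, p$out)
}

# single-head self-attention over the 4 tokens with residual layer norm;
# tokens is a list of 4 B x d nodes. Returns the flattened B x 4d node.
fusion_forward <- function(p, tokens) {
  d <- ncol(ag_value(tokens[[1]]))
  Q <- lapply(tokens, function(t) ag_matmul(t, p$Wq))
  K <- lapply(tokens, function(t) ag_matmul(t, p$Wk))
  V <- lapply(tokens, function(t) ag_matmul(t, p$Wv))
  out <- vector("list", 4L)
  for (i in 1:4) {
    scores <- ag_cbind(lapply(1:4, function(j)
      ag_scale(ag_rowdot(Q[[i]], K[[j]]), 1 / sqrt(d))))
    A <- ag_softmax_rows(scores)
    att <- NULL
    for (j in 1:4) {
      term <- ag_colmul(ag_getcol(A, j), V[[j]])
      att <- if (is.null(att)) term else ag_add(att, term)
    }
    out[[i]] <- ag_res_layernorm(tokens[[i]], att)
  }
  ag_cbind(out)
}

# member feature matrix of one set
set_member_features <- function(set_id, features) {
  ids <- features$composition$compound_id[features$composition$set_id == set_id]
  if (length(ids) == 0) stop("set '", set_id, "' has no member compounds")
  miss <- setdiff(ids, rownames(features$compound))
  if (length(miss)) stop("set '", set_id, "' has members without features: ",
                         paste(miss, collapse = ", "))
  features$compound[ids, , drop = FALSE]
}

# batched forward over a table of (set_id, cell_id, gene_id); params `wp` is
# the wrapped (ag) parameter tree. Returns the B x 3 logits node.
model_forward_batch <- function(cfg, wp, table, features,
                                dropout = 0, training = FALSE) {
  B <- nrow(table)
  gn <- features$gene_network[table$gene_id, , drop = FALSE]
  gs <- features$gene_sequence[table$gene_id, , drop = FALSE]
  ce <- features$cell[table$cell_id, , drop = FALSE]
  usets <- unique(table$set_id)
  idx <- match(table$set_id, usets)
  if (cfg$arch == "set") {
    embs <- lapply(usets, function(s)
      set_core_forward(wp$core, set_member_features(s, features),
                       cfg$pool, cfg$variant, cfg$heads))
    U <- ag_rbind(embs)
    set_rep <- ag_gather_rows(U, idx)
  } else {
    M <- do.call(rbind, lapply(usets, function(s)
      colMeans(set_member_features(s, features))))
    set_rep <- as_ag(M[idx, , drop = FALSE])
  }
  if (cfg$arch == "flat") {
    X <- ag_cbind(list(set_rep, as_ag(gn), as_ag(gs), as_ag(ce)))
    return(head_forward(wp$head, X, dropout, training))
  }
  tokens <- list(ag_linear(set_rep, wp$proj$set),
                 ag_linear(as_ag(gn), wp$proj$gene_net),
                 ag_linear(as_ag(gs), wp$proj$gene_seq),
                 ag_linear(as_ag(ce), wp$proj$cell))
  rep <- fusion_forward(wp$attn, tokens)
  head_forward(wp$head, rep, dropout, training)
}

# ---- exported single-record operations --------------------------------------

#' Fuse set, gene and cell features with self-attention
#'
#' Projects the fused set embedding, the gene network embedding, the gene
#' sequence embedding and the cell embedding into four tokens of the shared
#' fusion dimension, applies one self-attention block with residual layer
#' normalization, and flattens the refined tokens into a single vector.
#'
#' @param model an `"sp_model"` with `arch = "set"` or `"noset"`.
#' @param set_emb fused set embedding vector (`fused` field of [set_embed()],
#'   or the mean compound feature vector for the NoSet ablation).
#' @param gene either a length `gene_net_dim + gene_seq_dim` vector or a list
#'   with elements `network` and `sequence`.
#' @param cell cell embedding vector (length `cell_dim`).
#' @return numeric vector of length `4 * d_fusion`.
#' @export
fuse_and_attend <- function(model, set_emb, gene, cell) {
  cfg <- model$config
  if (cfg$arch == "flat") stop("the flat architecture has no fusion attention block")
  if (is.list(gene)) gene <- c(gene$network, gene$sequence)
  if (inherits(cell, "cell_embedding")) cell <- cell$latent
  if (any(!is.finite(set_emb)) || any(!is.finite(gene)) || any(!is.finite(cell)))
    stop("non-finite values in fusion inputs")
  gn <- gene[seq_len(cfg$gene_net_dim)]
  gs <- gene[cfg$gene_net_dim + seq_len(cfg$gene_seq_dim)]
  wp <- wrap_params(model$params)
  tokens <- list(ag_linear(matrix(set_emb, 1L), wp$proj$set),
                 ag_linear(matrix(gn, 1L), wp$proj$gene_net),
                 ag_linear(matrix(gs, 1L), wp$proj$gene_seq),
                 ag_linear(matrix(cell, 1L), wp$proj$cell))
  drop(ag_value(fusion_forward(wp$attn, tokens)))
}

#' Classify a refined representation
#'
#' Applies the three-layer prediction MLP (strictly decreasing hidden widths)
#' and softmax to produce the three class scores.
#'
#' @param model an `"sp_model"`.
#' @param rep refined representation vector (output of [fuse_and_attend()]),
#'   or a matrix of one representation per row.
#' @return a `"class_scores"` object (vector input) or data frame (matrix
#'   input); see [class_scores()].
#' @export
predict_head <- function(model, rep) {
  if (!is.matrix(rep)) rep <- matrix(rep, nrow = 1L)
  wp <- wrap_params(model$params$head)
  logits <- ag_value(head_forward(wp, as_ag(rep)))
  if (nrow(logits) == 1L) class_scores(drop(logits)) else class_scores(logits)
}

#' Full forward pass for one (set, gene, cell) triple
#'
#' Runs set embedding, fusion attention and the prediction head. The output
#' is invariant to any permutation of the rows of `set_features`.
#'
#' @param model an `"sp_model"`.
#' @param set_features matrix of member compound features (one per row).
#' @param gene gene feature as in [fuse_and_attend()].
#' @param cell cell embedding vector.
#' @return a `"class_scores"` object.
#' @export
predict_effect <- function(model, set_features, gene, cell) {
  cfg <- model$config
  set_features <- as_set_matrix(set_features, cfg$compound_dim)
  set_mean <- colMeans(set_features)
  if (cfg$arch == "flat") {
    if (is.list(gene)) gene <- c(gene$network, gene$sequence)
    if (inherits(cell, "cell_embedding")) cell <- cell$latent
    rep <- matrix(c(set_mean, gene, cell), nrow = 1L)
    wp <- wrap_params(model$params$head)
    return(class_scores(drop(ag_value(head_forward(wp, as_ag(rep))))))
  }
  if (cfg$arch == "set") {
    rep <- fuse_and_attend(model, set_embed(model, set_features)$fused,
                           gene, cell)
  } else {
    rep <- fuse_and_attend(model, set_mean, gene, cell)
  }
  predict_head(model, rep)
}

#' Class scores from logits
#'
#' Converts 3-class logits into softmax probabilities, the predicted class
#' (0 = up, 1 = down, 2 = no change) and the signed ranking score: the softmax
#' probability of the predicted directional class, negated for class 1, and
#' absent (`NA`) for class 2.
#'
#' @param logits numeric vector of length 3, or an `n x 3` matrix.
#' @return for a vector, an object of class `"class_scores"` with fields
#'   `logits`, `probs`, `predicted_class`, `signed_score`; for a matrix, a
#'   data frame with columns `p0`, `p1`, `p2`, `class`, `signed_score`.
#' @export
class_scores <- function(logits) {
  if (is.matrix(logits)) {
    stopifnot(ncol(logits) == 3)
    x <- logits - apply(logits, 1L, max)
    e <- exp(x)
    p <- e / rowSums(e)
    cls <- max.col(p, ties.method = "first") - 1L
    conf <- p[cbind(seq_len(nrow(p)), cls + 1L)]
    signed <- ifelse(cls == 0L, conf, ifelse(cls == 1L, -conf, NA_real_))
    return(data.frame(p0 = p[, 1], p1 = p[, 2], p2 = p[, 3],
                      class = cls, signed_score = signed))
  }
  stopifnot(length(logits) == 3)
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  cls <- which.max(p) - 1L
  signed <- if (cls == 2L) NA_real_ else unname(p[cls + 1L]) * (if (cls == 1L) -1 else 1)
  structure(list(logits = unname(logits), probs = unname(p),
                 predicted_class = cls, signed_score = signed),
            class = "class_scores")
}

#' Rank genes by signed score for enrichment export
#'
#' Keeps genes predicted as directional (class 0 or 1) whose softmax
#' confidence reaches the threshold `tau`, attaches the signed score
#' (probability of the predicted class, negative for down-regulation), and
#' sorts in descending score order, ties broken by gene id. Optionally writes
#' a GSEA-style `.rnk` file (gene_id TAB signed_score, no header).
#'
#' @param scores data frame with columns `gene_id`, `p0`, `p1`, `p2`, `class`
#'   and `signed_score` (as produced by [predict_associations()]).
#' @param tau confidence threshold in `[0, 1]`; the reference operating points
#'   are 0, 0.7 and 0.9.
#' @param path optional output path for the `.rnk` file.
#' @return data frame with columns `gene_id` and `signed_score`, ordered.
#' @export
rank_genes <- function(scores, tau = 0, path = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0 || tau > 1)
    stop("tau must be a single number in [0, 1]")
  keep <- scores$class %in% c(0L, 1L) & abs(scores$signed_score) >= tau
  out <- scores[keep, c("gene_id", "signed_score"), drop = FALSE]
  out <- out[order(-out$signed_score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Predict class scores for a table of associations
#'
#' Batched forward pass over `(set_id, cell_id, gene_id)` rows.
#'
#' @param model an `"sp_model"`.
#' @param table data frame with columns `set_id`, `cell_id`, `gene_id`.
#' @param features feature bundle (see [emit_features()]): compound, gene and
#'   cell feature matrices plus the set composition table.
#' @param batch_size records per forward batch.
#' @return `table` with columns `p0`, `p1`, `p2`, `class`, `signed_score`
#'   appended.
#' @export
predict_associations <- function(model, table, features, batch_size = 1024L) {
  wp <- wrap_params(model$params)
  out <- vector("list", ceiling(nrow(table) / batch_size))
  for (i in seq_along(out)) {
    rows <- ((i - 1L) * batch_size + 1L):min(i * batch_size, nrow(table))
    logits <- ag_value(model_forward_batch(model$config, wp,
                                           table[rows, , drop = FALSE], features))
    out[[i]] <- class_scores(logits)
  }
  cbind(table, do.call(rbind, out))
}
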
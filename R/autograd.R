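# Reverse-mode automatic differentiation over dense matrices.
#
# Every value in a computation graph is a node: an environment holding the
# forward value (a numeric matrix), the accumulated gradient, the parent nodes
# and a backward closure mapping the node's gradient to its parents' gradients.
# Graphs are built eagerly during the forward pass and traversed once, in
# reverse creation order, by ag_backward(). Only subgraphs reaching a parameter
# node carry gradients; constant branches are pruned.
#
# The engine is deliberately small: matrices only (scalars are 1x1), no
# broadcasting beyond explicit row/column helpers, deterministic evaluation
# order throughout so that seeded runs are bit-reproducible.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L
.ag$tape <- vector("list", 4096L)
.ag$tp <- 0L

# drop all recorded nodes; called at the start of every forward pass so the
# tape only ever holds the current graph
ag_tape_reset <- function() {
  if (.ag$tp > 0L) .ag$tape[seq_len(.ag$tp)] <- list(NULL)
  .ag$tp <- 0L
  invisible(NULL)
}

ag_node <- function(value, parents = list(), backfn = NULL, requires = FALSE) {
  if (!is.matrix(value)) value <- as.matrix(value)
  e <- new.env(parent = emptyenv())
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  req <- requires
  if (!req) for (p in parents) if (p$requires) { req <- TRUE; break }
  e$requires <- req
  class(e) <- "ag_node"
  if (req && !is.null(backfn)) {
    tp <- .ag$tp + 1L
    if (tp > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[tp]] <- e
    .ag$tp <- tp
  }
  e
}

is_ag <- function(x) is.environment(x)

as_ag <- function(x) if (is.environment(x)) x else ag_node(x)

ag_param <- function(value) ag_node(value, requires = TRUE)

ag_value <- function(x) if (is_ag(x)) x$value else x

# Backward pass over the recorded tape: nodes were appended in forward
# (topological) order, so one reverse sweep propagates all gradients.
#' @noRd
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  loss$grad <- matrix(1, 1, 1)
  tape <- .ag$tape
  for (i in rev(seq_len(.ag$tp))) {
    n <- tape[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n, n$grad)
    parents <- n$parents
    for (k in seq_along(parents)) {
      p <- parents[[k]]
      if (!p$requires || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(loss)
}

# ---- primitive operations ----------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value %*% b$value, list(a, b), function(n, g) {
    list(tcrossprod(g, n$parents[[2]]$value), crossprod(n$parents[[1]]$value, g))
  })
}

# a %*% t(b)
ag_matmul_t <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(tcrossprod(a$value, b$value), list(a, b), function(n, g) {
    list(g %*% n$parents[[2]]$value, crossprod(g, n$parents[[1]]$value))
  })
}

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value + b$value, list(a, b), function(n, g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value - b$value, list(a, b), function(n, g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value * b$value, list(a, b), function(n, g) {
    list(g * n$parents[[2]]$value, g * n$parents[[1]]$value)
  })
}

# add a 1 x k bias row to every row of a (n x k)
ag_add_bias <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(sweep(a$value, 2L, b$value[1L, ], "+"), list(a, b), function(n, g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ag_scale <- function(a, k) {
  a <- as_ag(a)
  ag_node(a$value * k, list(a), function(n, g) list(g * k))
}

ag_tanh <- function(a) {
  a <- as_ag(a)
  v <- tanh(a$value)
  ag_node(v, list(a), function(n, g) list(g * (1 - n$value^2)))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  ag_node(pmax(a$value, 0), list(a), function(n, g) list(g * (n$parents[[1]]$value > 0)))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  v <- 1 / (1 + exp(-a$value))
  ag_node(v, list(a), function(n, g) list(g * n$value * (1 - n$value)))
}

ag_exp <- function(a) {
  a <- as_ag(a)
  ag_node(exp(a$value), list(a), function(n, g) list(g * n$value))
}

ag_square <- function(a) {
  a <- as_ag(a)
  ag_node(a$value^2, list(a), function(n, g) list(2 * g * n$parents[[1]]$value))
}

row_maxs <- function(x) {
  m <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2:ncol(x)) m <- pmax(m, x[, j])
  m
}

ag_softmax_rows <- function(a) {
  a <- as_ag(a)
  x <- a$value
  x <- x - row_maxs(x)
  e <- exp(x)
  s <- e / rowSums(e)
  ag_node(s, list(a), function(n, g) {
    sm <- n$value
    list((g - rowSums(g * sm)) * sm)
  })
}

# row-wise layer normalization, no learned affine
ag_layernorm_rows <- function(a, eps = 1e-5) {
  a <- as_ag(a)
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  ag_node(y, list(a), function(n, g) {
    d <- ncol(g)
    gy <- g
    list(inv * (gy - rowMeans(gy) - y * rowMeans(gy * y)))
  })
}

ag_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_ag)
  rows <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ag_node(do.call(rbind, lapply(nodes, function(n) n$value)), nodes, function(n, g) {
    out <- vector("list", length(rows))
    at <- 0L
    for (i in seq_along(rows)) {
      out[[i]] <- g[at + seq_len(rows[i]), , drop = FALSE]
      at <- at + rows[i]
    }
    out
  })
}

ag_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_ag)
  cols <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ag_node(do.call(cbind, lapply(nodes, function(n) n$value)), nodes, function(n, g) {
    out <- vector("list", length(cols))
    at <- 0L
    for (i in seq_along(cols)) {
      out[[i]] <- g[, at + seq_len(cols[i]), drop = FALSE]
      at <- at + cols[i]
    }
    out
  })
}

ag_gather_rows <- function(a, idx) {
  a <- as_ag(a)
  idx <- as.integer(idx)
  ag_node(a$value[idx, , drop = FALSE], list(a), function(n, g) {
    gr <- matrix(0, nrow(n$parents[[1]]$value), ncol(g))
    agg <- rowsum(g, group = idx)
    gr[as.integer(rownames(agg)), ] <- agg
    list(gr)
  })
}

ag_getcol <- function(a, j) {
  a <- as_ag(a)
  ag_node(a$value[, j, drop = FALSE], list(a), function(n, g) {
    gr <- matrix(0, nrow(g), ncol(n$parents[[1]]$value))
    gr[, j] <- g
    list(gr)
  })
}

# pool rows to a single 1 x d row
ag_rowpool <- function(a, type = c("mean", "sum")) {
  type <- match.arg(type)
  a <- as_ag(a)
  k <- nrow(a$value)
  v <- matrix(colSums(a$value), 1L)
  if (type == "mean") v <- v / k
  ag_node(v, list(a), function(n, g) {
    gr <- matrix(g, k, length(g), byrow = TRUE)
    if (type == "mean") gr <- gr / k
    list(gr)
  })
}

# row-wise dot product of two conforming matrices -> n x 1 column
ag_rowdot <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(matrix(rowSums(a$value * b$value), ncol = 1L), list(a, b), function(n, g) {
    gv <- g[, 1L]
    list(gv * n$parents[[2]]$value, gv * n$parents[[1]]$value)
  })
}

# multiply every column of a (n x k) by column vector c (n x 1)
ag_colmul <- function(cvec, a) {
  cvec <- as_ag(cvec); a <- as_ag(a)
  ag_node(a$value * cvec$value[, 1L], list(cvec, a), function(n, g) {
    list(matrix(rowSums(g * n$parents[[2]]$value), ncol = 1L),
         g * n$parents[[1]]$value[, 1L])
  })
}

ag_dropout <- function(a, rate) {
  if (rate <= 0) return(as_ag(a))
  a <- as_ag(a)
  mask <- matrix(stats::rbinom(length(a$value), 1L, 1 - rate), nrow(a$value)) / (1 - rate)
  ag_node(a$value * mask, list(a), function(n, g) list(g * mask))
}

ag_sum <- function(a) {
  a <- as_ag(a)
  ag_node(sum(a$value), list(a), function(n, g) {
    list(matrix(g[1L], nrow(n$parents[[1]]$value), ncol(n$parents[[1]]$value)))
  })
}

ag_mean <- function(a) {
  a <- as_ag(a)
  k <- length(a$value)
  ag_node(sum(a$value) / k, list(a), function(n, g) {
    list(matrix(g[1L] / k, nrow(n$parents[[1]]$value), ncol(n$parents[[1]]$value)))
  })
}

# mean over rows of squared row norms: (1/N) sum_i ||a_i - b_i||^2
ag_sse_rows_mean <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  d <- a$value - b$value
  n <- nrow(d)
  ag_node(sum(d^2) / n, list(a, b), function(nn, g) {
    gd <- 2 * g[1L] * d / n
    list(gd, -gd)
  })
}

# mean cross-entropy of softmax(logits) against integer labels in 0..K-1
ag_ce_softmax <- function(logits, labels) {
  logits <- as_ag(logits)
  x <- logits$value
  x <- x - row_maxs(x)
  e <- exp(x)
  p <- e / rowSums(e)
  n <- nrow(p)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  node <- ag_node(loss, list(logits), function(nn, g) {
    gr <- p
    gr[idx] <- gr[idx] - 1
    list(g[1L] * gr / n)
  })
  attr(node, "probs") <- p
  node
}

# ---- parameter trees and Adam ------------------------------------------------

# parameters live as plain matrices in (possibly nested) named lists; each
# forward pass wraps them into fresh ag_param nodes so graphs never persist.

wrap_params <- function(p) {
  ag_tape_reset()   # a fresh parameter wrap starts a fresh graph
  wrap_params_rec(p)
}

wrap_params_rec <- function(p) {
  if (is.list(p)) lapply(p, wrap_params_rec) else ag_param(p)
}

# walk a nested wrapped tree and return the flat named list of nodes
flatten_nodes <- function(w, prefix = "") {
  if (!is.list(w)) return(stats::setNames(list(w), prefix))
  out <- list()
  for (nm in names(w)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    out <- c(out, flatten_nodes(w[[nm]], key))
  }
  out
}

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 0) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$weight_decay <- weight_decay
  e$t <- 0L
  e$m <- list(); e$v <- list()
  e
}

# apply one Adam step: reads grads from the wrapped node tree, returns the
# updated plain parameter tree. `trainable` optionally restricts updates to
# parameter names with a given prefix.
adam_step <- function(opt, params, wrapped, trainable_prefix = NULL) {
  flat <- flatten_nodes(wrapped)
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(flat)) {
    node <- flat[[nm]]
    g <- node$grad
    if (is.null(g)) next
    if (!is.null(trainable_prefix) &&
        !any(startsWith(nm, trainable_prefix))) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * node$value
    m <- if (is.null(opt$m[[nm]])) g * 0 else opt$m[[nm]]
    v <- if (is.null(opt$v[[nm]])) g * 0 else opt$v[[nm]]
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    node$value <- node$value - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  # write updated values back into the plain tree
  unwrap_params(wrapped)
}

unwrap_params <- function(w) {
  if (!is.list(w)) return(w$value)
  lapply(w, unwrap_params)
}

# Xavier/Glorot uniform initialization
init_mat <- function(nin, nout) {
  b <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -b, b), nin, nout)
}

init_linear <- function(nin, nout) {
  list(W = init_mat(nin, nout), b = matrix(0, 1L, nout))
}

# fused affine (+ optional ReLU) layer: one tape node instead of three
ag_affine <- function(x, W, b, relu = FALSE) {
  x <- as_ag(x); W <- as_ag(W); b <- as_ag(b)
  pre <- sweep(x$value %*% W$value, 2L, b$value[1L, ], "+")
  v <- if (relu) pmax(pre, 0) else pre
  ag_node(v, list(x, W, b), function(n, g) {
    if (relu) g <- g * (pre > 0)
    list(tcrossprod(g, n$parents[[2]]$value),
         crossprod(n$parents[[1]]$value, g),
         matrix(colSums(g), 1L))
  })
}

ag_linear <- function(x, lin) ag_affine(x, lin$W, lin$b)

ag_linear_relu <- function(x, lin) ag_affine(x, lin$W, lin$b, relu = TRUE)

# a %*% t(b) * k  (scaled attention scores)
ag_scaled_matmul_t <- function(a, b, k) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(tcrossprod(a$value, b$value) * k, list(a, b), function(n, g) {
    g <- g * k
    list(g %*% n$parents[[2]]$value, crossprod(g, n$parents[[1]]$value))
  })
}

# LayerNorm(x + y): fused residual + row-wise layer normalization
ag_res_layernorm <- function(a, b, eps = 1e-5) {
  a <- as_ag(a); b <- as_ag(b)
  x <- a$value + b$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  ag_node(y, list(a, b), function(n, g) {
    gx <- inv * (g - rowMeans(g) - y * rowMeans(g * y))
    list(gx, gx)
  })
}
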
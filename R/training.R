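# Transfer-learning protocol: pre-train the classifier on singleton-set
# (single compound) association records, then fine-tune on multi-compound
# set records. Both stages minimize softmax cross-entropy with Adam; L2
# regularization is applied as weight decay and dropout inside the
# prediction head. Featurizers are frozen throughout; by default all
# internal modules (set core, fusion attention, head) are trainable, with a
# head-only mode for comparison.

#' Training configuration
#'
#' @param epochs training epochs (default 10, the reference regimen; 0 is
#'   allowed and leaves the model untouched).
#' @param batch_size records per minibatch.
#' @param learning_rate Adam learning rate.
#' @param l2 L2 regularization strength (weight decay).
#' @param dropout dropout rate in `[0, 1)` applied inside the prediction head.
#' @param seed integer seed governing shuffling and dropout.
#' @param trainable_scope `"all-internal"` (default) or `"head-only"`.
#' @return a `"train_config"` list.
#' @export
train_config <- function(epochs = 10, batch_size = 256, learning_rate = 1e-3,
                         l2 = 0, dropout = 0, seed = 1,
                         trainable_scope = c("all-internal", "head-only")) {
  trainable_scope <- match.arg(trainable_scope)
  if (epochs < 0) stop("epochs must be >= 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l2 = l2, dropout = dropout,
                 seed = as.integer(seed), trainable_scope = trainable_scope),
            class = "train_config")
}

train_loop <- function(model, table, features, config, stage) {
  if (config$epochs == 0) return(model)
  params <- model$params
  opt <- adam_new(lr = config$learning_rate, weight_decay = config$l2)
  prefix <- if (config$trainable_scope == "head-only") "head" else NULL
  set.seed(config$seed)
  n <- nrow(table)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    steps <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot <- 0
    for (rows in steps) {
      batch <- table[rows, , drop = FALSE]
      wp <- wrap_params(params)
      logits <- model_forward_batch(model$config, wp, batch, features,
                                    dropout = config$dropout, training = TRUE)
      loss <- ag_ce_softmax(logits, batch$label)
      ag_backward(loss)
      params <- adam_step(opt, params, wp, trainable_prefix = prefix)
      tot <- tot + ag_value(loss)[1] * length(rows)
    }
    losses[epoch] <- tot / n
  }
  model$params <- params
  model$history[[stage]] <- c(model$history[[stage]], list(losses))
  model
}

#' Pre-train on singleton-set associations
#'
#' Cross-entropy training on single-compound records. Guards the transfer
#' protocol: any multi-compound set in the table is an error.
#'
#' @param model an `"sp_model"`.
#' @param table association records (`set_id`, `cell_id`, `gene_id`, `label`).
#' @param features feature bundle (see [emit_features()]).
#' @param config a [train_config()].
#' @return the trained model; per-epoch mean losses are appended to
#'   `model$history$pretrain`.
#' @export
pretrain <- function(model, table, features, config = train_config()) {
  card <- tapply(features$composition$compound_id, features$composition$set_id, length)
  bad <- names(card)[card > 1]
  if (any(unique(table$set_id) %in% bad))
    stop("pre-training table contains multi-compound sets; ",
         "singleton sets only during pre-training")
  train_loop(model, table, features, config, "pretrain")
}

#' Fine-tune on multi-compound set associations
#'
#' Continues training on mixture records. All internal modules are trainable
#' by default (featurizers stay frozen since features enter as fixed
#' matrices); `trainable_scope = "head-only"` restricts updates to the
#' prediction head. `epochs = 0` returns the model unchanged.
#'
#' @inheritParams pretrain
#' @return the trained model.
#' @export
finetune <- function(model, table, features, config = train_config()) {
  train_loop(model, table, features, config, "finetune")
}

# ---- metrics -----------------------------------------------------------------

# rank-based (Mann-Whitney) binary AUC
auc_binary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-wise area under the precision-recall curve)
aupr_binary <- function(score, positive) {
  if (sum(positive) == 0 || sum(!positive) == 0) return(NA_real_)
  ord <- order(-score)
  y <- positive[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y]) / sum(y)
}

#' Evaluate a model on an association table
#'
#' Computes accuracy, macro F1, macro one-vs-rest AUC and macro AUPR over the
#' three classes. If the table contains a single class, AUC and AUPR are
#' undefined and reported as `NA` with a warning.
#'
#' @inheritParams pretrain
#' @param predictions optionally, precomputed [predict_associations()] output
#'   for `table` (skips the forward pass).
#' @return an `"eval_report"` list: `accuracy`, `macro_f1`, `auc`, `aupr`,
#'   `per_class` data frame, `n_eval`.
#' @export
evaluate_model <- function(model, table, features, predictions = NULL) {
  if (is.null(predictions)) predictions <- predict_associations(model, table, features)
  scores <- as.matrix(predictions[, c("p0", "p1", "p2")])
  eval_scores(scores, table$label)
}

eval_scores <- function(scores, labels) {
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  classes <- 0:2
  per <- lapply(classes, function(k) {
    tp <- sum(pred == k & labels == k)
    fp <- sum(pred == k & labels != k)
    fn <- sum(pred != k & labels == k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    pos <- labels == k
    data.frame(class = k, n = sum(pos), precision = prec, recall = rec, f1 = f1,
               auc = auc_binary(scores[, k + 1], pos),
               aupr = aupr_binary(scores[, k + 1], pos))
  })
  per <- do.call(rbind, per)
  present <- per$n > 0
  if (sum(present) < 2) {
    warning("fewer than two classes present; AUC/AUPR undefined")
    auc <- aupr <- NA_real_
  } else {
    auc <- mean(per$auc[present])
    aupr <- mean(per$aupr[present])
  }
  structure(list(accuracy = acc, macro_f1 = mean(per$f1[present]),
                 auc = auc, aupr = aupr, per_class = per,
                 n_eval = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n=%d  accuracy=%.4f  macro-F1=%.4f  AUC=%.4f  AUPR=%.4f\n",
              x$n_eval, x$accuracy, x$macro_f1, x$auc, x$aupr))
  invisible(x)
}

# ---- baselines ---------------------------------------------------------------

# concatenated (mean compound, gene, cell) design matrix for flat baselines
baseline_design <- function(table, features) {
  usets <- unique(table$set_id)
  M <- do.call(rbind, lapply(usets, function(s)
    colMeans(set_member_features(s, features))))
  cbind(M[match(table$set_id, usets), , drop = FALSE],
        features$gene_network[table$gene_id, , drop = FALSE],
        features$gene_sequence[table$gene_id, , drop = FALSE],
        features$cell[table$cell_id, , drop = FALSE])
}

#' Fit and evaluate a baseline classifier
#'
#' Classical baselines (`knn`, `lda`, `dt`) are fitted on a PCA reduction
#' (top `n_pc` components, fitted on the training split only) of the
#' concatenated mean-compound / gene / cell features; the synthetic features
#' are low-rank by construction, so PCA removes the rank deficiency that
#' breaks LDA and is applied identically to all three. `vanilla-mlp` is the
#' package's prediction MLP alone on the raw concatenated features, and
#' `noset` is the ablation retaining fusion attention and head but replacing
#' the set core by the mean of member compound features; both are trained
#' with the same transfer protocol arguments as the full model.
#'
#' @param train_table,test_table association record tables.
#' @param features feature bundle.
#' @param kind one of `"knn"`, `"lda"`, `"dt"`, `"vanilla-mlp"`, `"noset"`.
#' @param n_pc PCA components for the classical baselines.
#' @param pretrain_table optional singleton table: when given, the neural
#'   baselines are pre-trained on it before fine-tuning on `train_table`.
#' @param config [train_config()] for the neural baselines' fine-tuning.
#' @param pretrain_config [train_config()] for their pre-training stage
#'   (defaults to `config`).
#' @param model_args extra arguments to [sp_model()] for the neural baselines.
#' @param seed seed for stochastic fitters.
#' @return an `"eval_report"`.
#' @export
baseline_model <- function(train_table, test_table, features,
                           kind = c("knn", "lda", "dt", "vanilla-mlp", "noset"),
                           n_pc = 40, pretrain_table = NULL,
                           config = train_config(), pretrain_config = config,
                           model_args = list(), seed = 1) {
  kind <- match.arg(kind)
  if (kind %in% c("vanilla-mlp", "noset")) {
    arch <- if (kind == "noset") "noset" else "flat"
    model <- do.call(sp_model, c(list(arch = arch, seed = seed), model_args))
    if (!is.null(pretrain_table))
      model <- pretrain(model, pretrain_table, features, pretrain_config)
    model <- finetune(model, train_table, features, config)
    return(evaluate_model(model, test_table, features))
  }
  Xtr <- baseline_design(train_table, features)
  Xte <- baseline_design(test_table, features)
  pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE, rank. = n_pc)
  keep_pc <- pc$sdev[seq_len(ncol(pc$rotation))] > 1e-8 * pc$sdev[1]
  pc$rotation <- pc$rotation[, keep_pc, drop = FALSE]
  Ztr <- stats::predict(pc, Xtr)
  Zte <- stats::predict(pc, Xte)
  # drop empty classes so the classical fitters see only observed levels;
  # absent classes keep zero probability in the expanded score matrix below
  ytr <- droplevels(factor(train_table$label, levels = 0:2))
  set.seed(seed)
  probs <- switch(kind,
    knn = {
      p <- caret::knn3Train(Ztr, Zte, ytr, k = 15, prob = TRUE)
      attr(p, "prob")
    },
    lda = {
      fit <- MASS::lda(Ztr, grouping = ytr)
      stats::predict(fit, Zte)$posterior
    },
    dt = {
      df <- data.frame(y = ytr, Ztr)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      stats::predict(fit, data.frame(Zte), type = "prob")
    })
  full <- matrix(0, nrow(Zte), 3, dimnames = list(NULL, c("0", "1", "2")))
  full[, colnames(probs)] <- probs
  eval_scores(full, test_table$label)
}

# ---- splits, grid search, correlation ---------------------------------------

#' Hold out whole sets for a generalization split
#'
#' Splits an association table so that a fraction of the distinct
#' multi-compound sets — and all their records — form the test partition;
#' no `set_id` appears on both sides.
#'
#' @param table association records.
#' @param holdout_fraction fraction of distinct sets to hold out.
#' @param seed integer seed.
#' @return list with data frames `train` and `test`.
#' @export
split_unseen_sets <- function(table, holdout_fraction = 0.10, seed = 1) {
  sets <- unique(table$set_id)
  if (length(sets) < 10) stop("need at least 10 distinct sets to split by set")
  set.seed(seed)
  k <- max(1L, round(holdout_fraction * length(sets)))
  held <- sample(sets, k)
  list(train = table[!table$set_id %in% held, , drop = FALSE],
       test = table[table$set_id %in% held, , drop = FALSE])
}

#' Grid search over training hyperparameters
#'
#' Trains one model per grid point (fresh clone of `model`) and selects the
#' configuration with the highest validation AUC. The full results table is
#' attached as the `"results"` attribute.
#'
#' @param model an untrained `"sp_model"` (re-initialized per grid point).
#' @param train_table,val_table record tables.
#' @param features feature bundle.
#' @param grid named list of vectors over [train_config()] fields (e.g.
#'   `list(learning_rate = c(1e-3, 1e-4), batch_size = c(128, 256))`).
#' @param base_config defaults for fields not in the grid.
#' @param stage `"pretrain"` or `"finetune"` (controls the singleton guard).
#' @return the winning `"train_config"` with attribute `"results"`.
#' @export
grid_search_train <- function(model, train_table, val_table, features, grid,
                              base_config = train_config(),
                              stage = c("finetune", "pretrain")) {
  stage <- match.arg(stage)
  if (!length(grid)) stop("grid must be nonempty")
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  res <- pts
  res$val_auc <- NA_real_
  best <- NULL; best_auc <- -Inf
  for (i in seq_len(nrow(pts))) {
    cfg <- unclass(base_config)
    for (nm in names(pts)) cfg[[nm]] <- pts[[nm]][i]
    cfg <- do.call(train_config, cfg)
    fit <- if (stage == "pretrain")
      pretrain(model, train_table, features, cfg)
    else finetune(model, train_table, features, cfg)
    auc <- evaluate_model(fit, val_table, features)$auc
    res$val_auc[i] <- auc
    if (!is.na(auc) && auc > best_auc) { best_auc <- auc; best <- cfg }
  }
  attr(best, "results") <- res
  best
}

#' Correlation between signed scores and true continuous effects
#'
#' Pearson correlation between the model's signed ranking scores and the
#' ground-truth (or measured) continuous effects, optionally restricted to
#' predictions whose confidence reaches a threshold `tau` — mirroring the
#' analysis in which the correlation rises as the threshold increases.
#'
#' @param predictions data frame with `class` and `signed_score` columns.
#' @param truth numeric vector of continuous effects, aligned with
#'   `predictions` rows.
#' @param tau confidence threshold; only class-0/1 records with
#'   `|signed_score| >= tau` enter the correlation.
#' @return Pearson r, or `NA` (with a warning) if fewer than 3 pairs remain
#'   or either side has zero variance.
#' @export
score_fc_correlation <- function(predictions, truth, tau = 0) {
  stopifnot(nrow(predictions) == length(truth))
  keep <- predictions$class %in% c(0L, 1L) &
    !is.na(predictions$signed_score) &
    abs(predictions$signed_score) >= tau
  s <- predictions$signed_score[keep]
  t <- truth[keep]
  if (length(s) < 3 || stats::sd(s) == 0 || stats::sd(t) == 0) {
    warning("correlation undefined (too few pairs or zero variance)")
    return(NA_real_)
  }
  stats::cor(s, t)
}
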
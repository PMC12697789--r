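# Reference experiments on synthetic worlds.
#
# One call of transfer_experiment() reproduces, at desk scale, the designs
# the model is meant to satisfy qualitatively: the transfer benefit
# (pretrain + finetune >= finetune-only >= pretrain-only on held-out
# mixture records), the set-module ablation (full model >= NoSet >=
# vanilla MLP), the fine-tune-fraction sweep, and the signed-score /
# true-effect correlation at rising confidence thresholds. Experiments are
# fully reproducible from the seed; medians over several seeds are taken by
# the caller.

#' Desk-scale model arguments for experiments
#'
#' Reduced widths used by the reference experiments so a full multi-seed
#' suite trains in minutes on one CPU; the architecture is unchanged.
#'
#' @return named list of [sp_model()] arguments.
#' @export
experiment_model_args <- function() {
  list(d_set = 64, heads = 2, inducing = 4, n_isab = 1, d_fusion = 64,
       head_dims = c(128, 64, 32))
}

#' Run the reference transfer / ablation experiment for one seed
#'
#' Generates a synthetic world (reference dimensions), emits singleton and
#' multiset association tables, then trains and evaluates on a 75/25 record
#' split of the multiset table:
#' pretrain-only, finetune-only (from scratch), and pretrain + finetune at
#' fine-tuning fractions of 25/50/100%, plus the NoSet and vanilla-MLP
#' ablations under the identical pretrain + finetune protocol. Signed-score
#' correlations with the ground-truth continuous effect are computed on the
#' test records at thresholds 0, 0.7 and 0.9.
#'
#' @param seed integer seed; determines world, tables, splits and training.
#' @param genes_per_table genes subsampled into each association table.
#' @param n_singleton_sets,n_multisets,set_size_range table composition.
#' @param pre_epochs,ft_epochs epochs for the two stages; the
#'   finetune-only arm trains from random initialization under the identical
#'   fine-tuning configuration (same fine-tune, different initialization).
#' @param variant set-fusion variant for the full model.
#' @param model_args [sp_model()] overrides (default
#'   [experiment_model_args()]).
#' @param include_classical also fit the knn/lda/dt baselines.
#' @return one-row data frame of AUCs, accuracies and correlations.
#' @export
transfer_experiment <- function(seed = 0, genes_per_table = 40,
                                n_singleton_sets = 36, n_multisets = 36,
                                set_size_range = c(2, 6),
                                pre_epochs = 10, ft_epochs = 8,
                                variant = "add",
                                model_args = experiment_model_args(),
                                include_classical = FALSE) {
  world <- generate_world(seed = seed)
  tabs <- emit_tables(world, n_singleton_sets = n_singleton_sets,
                      n_multisets = n_multisets,
                      set_size_range = set_size_range,
                      genes = genes_per_table, seed = seed)
  features <- emit_features(world, tabs$composition)
  set.seed(seed + 7L)
  n <- nrow(tabs$finetune)
  test_rows <- sample.int(n, round(0.25 * n))
  ft_train <- tabs$finetune[-test_rows, , drop = FALSE]
  ft_test <- tabs$finetune[test_rows, , drop = FALSE]

  cfg_pre <- train_config(epochs = pre_epochs, batch_size = 1024,
                          learning_rate = 3e-3, l2 = 1e-5, dropout = 0.1,
                          seed = seed)
  cfg_ft <- train_config(epochs = ft_epochs, batch_size = 1024,
                         learning_rate = 1e-3, l2 = 1e-5, dropout = 0.1,
                         seed = seed + 1L)
  cfg_scratch <- train_config(epochs = ft_epochs, batch_size = 1024,
                              learning_rate = 1e-3, l2 = 1e-5, dropout = 0.1,
                              seed = seed + 1L)

  new_model <- function(arch = "set", s = seed)
    do.call(sp_model, c(list(arch = arch, variant = variant, seed = s),
                        model_args))

  P <- pretrain(new_model(), tabs$pretrain, features, cfg_pre)
  auc_of <- function(model) evaluate_model(model, ft_test, features)
  ev_pre_only <- auc_of(P)

  subsample <- function(tbl, frac, s) {
    if (frac >= 1) return(tbl)
    set.seed(s)
    tbl[sample.int(nrow(tbl), round(frac * nrow(tbl))), , drop = FALSE]
  }
  ft25 <- finetune(P, subsample(ft_train, 0.25, seed + 11L), features, cfg_ft)
  ft50 <- finetune(P, subsample(ft_train, 0.50, seed + 12L), features, cfg_ft)
  ft100 <- finetune(P, ft_train, features, cfg_ft)
  scratch <- finetune(new_model(s = seed + 500L), ft_train, features,
                      cfg_scratch)

  ev25 <- auc_of(ft25); ev50 <- auc_of(ft50); ev100 <- auc_of(ft100)
  ev_scratch <- auc_of(scratch)

  ev_noset <- baseline_model(ft_train, ft_test, features, kind = "noset",
                             pretrain_table = tabs$pretrain, config = cfg_ft,
                             pretrain_config = cfg_pre,
                             model_args = model_args[
                               intersect(names(model_args),
                                         c("d_fusion", "head_dims"))],
                             seed = seed)
  ev_mlp <- baseline_model(ft_train, ft_test, features, kind = "vanilla-mlp",
                           pretrain_table = tabs$pretrain, config = cfg_ft,
                           pretrain_config = cfg_pre,
                           model_args = list(head_dims = model_args$head_dims),
                           seed = seed)

  # score/effect correlation over all mixture records: the mechanism
  # analysis ranks every prediction, it is not a generalization metric
  preds <- predict_associations(ft100, tabs$finetune, features)
  key <- function(d) paste(d$set_id, d$cell_id, d$gene_id)
  truth <- tabs$truth$effect[match(key(tabs$finetune), key(tabs$truth))]
  cors <- vapply(c(0, 0.7, 0.9), function(tau)
    suppressWarnings(score_fc_correlation(preds, truth, tau)), numeric(1))

  out <- data.frame(
    seed = seed,
    auc_pre_only = ev_pre_only$auc, auc_ft_only = ev_scratch$auc,
    auc_pre_ft = ev100$auc, auc_ft25 = ev25$auc, auc_ft50 = ev50$auc,
    acc_pre_ft = ev100$accuracy,
    auc_noset = ev_noset$auc, auc_mlp = ev_mlp$auc,
    cor_tau0 = cors[1], cor_tau07 = cors[2], cor_tau09 = cors[3])
  if (include_classical) {
    for (k in c("knn", "lda", "dt")) {
      ev <- baseline_model(ft_train, ft_test, features, kind = k, seed = seed)
      out[[paste0("auc_", k)]] <- ev$auc
    }
  }
  out
}

#' Run the experiment for several seeds
#'
#' @param seeds integer vector of seeds (reference suite: 0-4).
#' @param ... passed to [transfer_experiment()].
#' @return data frame, one row per seed.
#' @export
experiment_suite <- function(seeds = 0:4, ...) {
  do.call(rbind, lapply(seeds, function(s) transfer_experiment(seed = s, ...)))
}
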
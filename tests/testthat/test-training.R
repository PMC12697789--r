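# Transfer-learning protocol, evaluation metrics, baselines, splits and
# the score/effect correlation.

test_that("pretraining rejects multi-compound sets and learns on singletons", {
  s <- tiny_setup(seed = 101)
  m <- tiny_model(seed = 101)
  expect_error(pretrain(m, s$tabs$finetune, s$features, tiny_train_config()),
               "singleton")
  fit <- pretrain(m, s$tabs$pretrain, s$features, tiny_train_config(epochs = 3))
  losses <- fit$history$pretrain[[1]]
  expect_length(losses, 3)
  expect_lt(tail(losses, 1), losses[1])
})

test_that("training is reproducible from (config, seed) and epochs=0 is identity", {
  s <- tiny_setup(seed = 102)
  cfg <- tiny_train_config(epochs = 2, seed = 7, dropout = 0.2)
  f1 <- pretrain(tiny_model(seed = 9), s$tabs$pretrain, s$features, cfg)
  f2 <- pretrain(tiny_model(seed = 9), s$tabs$pretrain, s$features, cfg)
  expect_identical(f1$history$pretrain, f2$history$pretrain)
  expect_identical(f1$params, f2$params)
  f0 <- finetune(f1, s$tabs$finetune, s$features, tiny_train_config(epochs = 0))
  expect_identical(f0$params, f1$params)
})

test_that("train_config validates its fields", {
  expect_identical(train_config()$epochs, 10L)  # reference regimen
  expect_error(train_config(dropout = 1.5), "dropout")
  expect_error(train_config(epochs = -1), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("head-only scope freezes everything but the prediction head", {
  s <- tiny_setup(seed = 103)
  m <- tiny_model(seed = 103)
  fit <- finetune(m, s$tabs$finetune, s$features,
                  tiny_train_config(epochs = 1, trainable_scope = "head-only"))
  expect_identical(fit$params$core, m$params$core)
  expect_identical(fit$params$proj, m$params$proj)
  expect_false(identical(fit$params$head, m$params$head))
})

test_that("evaluation metrics: perfect predictor, permutation null, degenerate input", {
  s <- tiny_setup(seed = 104)
  tab <- s$tabs$pretrain
  m <- tiny_model(seed = 104)
  # a perfect predictor scores accuracy 1 (injected via precomputed predictions)
  perfect <- predict_associations(m, tab, s$features)
  onehot <- diag(3)[tab$label + 1, ]
  perfect[, c("p0", "p1", "p2")] <- onehot
  ev <- evaluate_model(m, tab, s$features, predictions = perfect)
  expect_equal(ev$accuracy, 1)
  expect_identical(ev$n_eval, nrow(tab))
  # uniform random scores on balanced classes sit at chance
  set.seed(1)
  n <- 3000
  sc <- matrix(runif(n * 3), n); sc <- sc / rowSums(sc)
  labs <- rep(0:2, each = n / 3)
  null_ev <- setperturb:::eval_scores(sc, labs)
  expect_equal(null_ev$auc, 0.5, tolerance = 0.03)
  # single-class tables have undefined AUC
  one <- tab[tab$label == 2L, ][1:10, ]
  expect_warning(ev1 <- evaluate_model(m, one, s$features), "classes")
  expect_true(is.na(ev1$auc))
})

test_that("rank-based AUC and AUPR match pROC on a reference case", {
  skip_if_not_installed("pROC")
  set.seed(2)
  score <- rnorm(200)
  pos <- rbinom(200, 1, plogis(score)) == 1
  expect_equal(setperturb:::auc_binary(score, pos),
               as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("classical baselines fit and a decision tree separates a linear toy", {
  s <- tiny_setup(seed = 105, n_singleton_sets = 6, n_multisets = 4)
  tr <- s$tabs$finetune[1:50, ]
  te <- s$tabs$finetune[51:72, ]
  for (kind in c("knn", "lda", "dt")) {
    ev <- baseline_model(tr, te, s$features, kind = kind, n_pc = 10)
    expect_s3_class(ev, "eval_report")
    expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  }
  # dt on a linearly separable table: labels decided by one feature
  sep <- tr
  split_val <- median(s$features$cell[sep$cell_id, 1])
  sep$label <- as.integer(s$features$gene_network[sep$gene_id, 1] > 0)
  ev <- baseline_model(sep, sep, s$features, kind = "dt", n_pc = 10)
  expect_gt(ev$accuracy, 0.9)
  expect_error(baseline_model(tr, te, s$features, kind = "svm"), "arg")
})

test_that("the NoSet ablation drops exactly the set-embedding core", {
  full <- tiny_model(seed = 106, arch = "set")
  noset <- tiny_model(seed = 106, arch = "noset")
  flat <- tiny_model(seed = 106, arch = "flat")
  expect_true("core" %in% names(full$params))
  expect_false("core" %in% names(noset$params))
  expect_identical(setdiff(names(full$params), names(noset$params)), "core")
  # the vanilla network is the prediction module alone
  expect_identical(names(flat$params), "head")
})

test_that("split_unseen_sets holds out whole sets deterministically", {
  tab <- expand.grid(set_id = sprintf("s%02d", 1:20), cell_id = "c",
                     gene_id = paste0("g", 1:3), stringsAsFactors = FALSE)
  tab$label <- 2L
  sp <- split_unseen_sets(tab, holdout_fraction = 0.10, seed = 3)
  expect_identical(length(unique(sp$test$set_id)), 2L)
  expect_length(intersect(sp$train$set_id, sp$test$set_id), 0)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(tab))
  expect_identical(split_unseen_sets(tab, 0.10, seed = 3)$test$set_id,
                   sp$test$set_id)
  expect_error(split_unseen_sets(tab[tab$set_id %in% sprintf("s%02d", 1:5), ]),
               "at least 10")
})

test_that("grid search rejects a sabotaged learning rate and logs the grid", {
  world <- generate_world(n_compounds = 12, n_genes = 40, n_cells = 2, r = 3,
                          seed = 107)
  tabs <- emit_tables(world, n_singleton_sets = 6, n_multisets = 8,
                      set_size_range = c(2, 4), seed = 107)
  features <- emit_features(world, tabs$composition)
  n <- nrow(tabs$finetune)
  tr <- tabs$finetune[1:480, ]
  va <- tabs$finetune[481:n, ]
  best <- grid_search_train(tiny_model(seed = 107), tr, va, features,
                            grid = list(learning_rate = c(5e-3, 0)),
                            base_config = tiny_train_config(epochs = 6))
  expect_identical(best$learning_rate, 5e-3)
  expect_identical(nrow(attr(best, "results")), 2L)
})

test_that("score/effect correlation behaves at the identity, the null and degeneracy", {
  ident <- data.frame(class = 0L,
                      signed_score = seq(0.5, 0.99, length.out = 50))
  expect_equal(score_fc_correlation(ident, ident$signed_score), 1)
  set.seed(4)
  null <- data.frame(class = rep(0:1, 500),
                     signed_score = runif(1000, -1, 1))
  expect_lt(abs(score_fc_correlation(null, rnorm(1000))), 0.1)
  flatp <- data.frame(class = 0L, signed_score = rep(0.7, 5))
  expect_warning(r <- score_fc_correlation(flatp, rnorm(5)), "undefined")
  expect_true(is.na(r))
  # threshold filtering only keeps confident directional calls
  mix <- data.frame(class = c(0L, 0L, 1L, 2L),
                    signed_score = c(0.95, 0.55, -0.8, NA))
  expect_warning(score_fc_correlation(mix, 1:4, tau = 0.9), "undefined")
})
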
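# Fusion attention, prediction head, end-to-end forward and gene ranking.

test_that("class scores: softmax normalization, argmax class, signed-score convention", {
  set.seed(51)
  L <- matrix(rnorm(60), 20, 3)
  cs <- class_scores(L)
  expect_equal(rowSums(cs[, c("p0", "p1", "p2")]), rep(1, 20), tolerance = 1e-6)
  expect_identical(cs$class, max.col(as.matrix(cs[, 1:3]), "first") - 1L)
  up <- class_scores(c(10, -10, -10))
  expect_identical(up$predicted_class, 0L)
  expect_gt(up$signed_score, 0.99)
  down <- class_scores(c(-10, 10, -10))
  expect_identical(down$predicted_class, 1L)
  expect_lt(down$signed_score, -0.99)
  none <- class_scores(c(-10, -10, 10))
  expect_identical(none$predicted_class, 2L)
  expect_true(is.na(none$signed_score))
  # |signed| equals the winning probability on every row
  expect_equal(abs(cs$signed_score[cs$class == 0]), cs$p0[cs$class == 0])
  expect_equal(abs(cs$signed_score[cs$class == 1]), cs$p1[cs$class == 1])
})

test_that("predict_head applies the decreasing-width MLP and softmax", {
  m <- tiny_model(seed = 52, compound_dim = 10)
  rep_vec <- rnorm(4 * 8)
  cs <- predict_head(m, rep_vec)
  expect_s3_class(cs, "class_scores")
  expect_equal(sum(cs$probs), 1, tolerance = 1e-9)
  expect_identical(predict_head(m, rep_vec)$probs, cs$probs)
  expect_error(sp_model(head_dims = c(64, 64, 32)), "strictly decreasing")
})

test_that("fuse_and_attend is deterministic, cell-sensitive and rejects NaN", {
  m <- tiny_model(seed = 53, compound_dim = 10)
  F <- random_feature_set(3, 10, seed = 3)
  se <- set_embed(m, F)$fused
  sm <- colMeans(F)
  gene <- rnorm(1024); cell <- rnorm(64)
  r1 <- fuse_and_attend(m, se, gene, cell)
  expect_identical(fuse_and_attend(m, se, gene, cell), r1)
  expect_length(r1, 4 * 8)
  expect_false(identical(fuse_and_attend(m, se, gene, rep(0, 64)), r1))
  expect_error(fuse_and_attend(m, se, c(NaN, gene[-1]), cell), "finite")
})

test_that("forward pass is permutation-invariant and consistent with batching", {
  s <- tiny_setup(seed = 54)
  m <- tiny_model(seed = 54, compound_dim = 1181)
  tab <- s$tabs$finetune[1:8, ]
  preds <- predict_associations(m, tab, s$features, batch_size = 3)
  # batched probabilities match the one-record path
  for (i in c(1, 5, 8)) {
    F <- s$features$compound[
      s$features$composition$compound_id[
        s$features$composition$set_id == tab$set_id[i]], , drop = FALSE]
    gene <- c(s$features$gene_network[tab$gene_id[i], ],
              s$features$gene_sequence[tab$gene_id[i], ])
    cell <- s$features$cell[tab$cell_id[i], ]
    one <- predict_effect(m, F, gene, cell)
    expect_equal(unlist(preds[i, c("p0", "p1", "p2")], use.names = FALSE),
                 one$probs, tolerance = 1e-6)
    # permuting the member rows changes nothing
    perm <- predict_effect(m, F[sample(nrow(F)), , drop = FALSE], gene, cell)
    expect_identical(perm$probs, one$probs)
  }
  expect_identical(ncol(as.matrix(preds[, c("p0", "p1", "p2")])), 3L)
})

test_that("rank_genes applies threshold, sign ordering and tie-breaks", {
  scores <- data.frame(
    gene_id = c("g4", "g1", "g2", "g3", "g5"),
    p0 = c(0.71, 0.69, 0.10, 0.20, 0.10),
    p1 = c(0.10, 0.11, 0.85, 0.10, 0.10),
    p2 = c(0.19, 0.20, 0.05, 0.70, 0.80),
    class = c(0L, 0L, 1L, 2L, 2L),
    signed_score = c(0.71, 0.69, -0.85, NA, NA))
  r07 <- rank_genes(scores, tau = 0.7)
  expect_identical(r07$gene_id, c("g4", "g2"))  # 0.69 dropped, class 2 never kept
  r0 <- rank_genes(scores, tau = 0)
  expect_identical(r0$gene_id, c("g4", "g1", "g2"))
  expect_true(all(diff(r0$signed_score) <= 0))
  # raising tau never lengthens the list
  lens <- vapply(c(0, 0.7, 0.9), function(t) nrow(rank_genes(scores, t)), numeric(1))
  expect_true(all(diff(lens) <= 0))
  # all-no-change input gives a valid empty ranking and file
  empty <- scores[scores$class == 2L, ]
  path <- tempfile(fileext = ".rnk")
  out <- rank_genes(empty, tau = 0, path = path)
  expect_identical(nrow(out), 0L)
  expect_true(file.exists(path))
  # ties broken lexicographically by gene id
  tied <- data.frame(gene_id = c("gb", "ga"), p0 = c(0.6, 0.6),
                     p1 = c(0.2, 0.2), p2 = c(0.2, 0.2),
                     class = c(0L, 0L), signed_score = c(0.6, 0.6))
  expect_identical(rank_genes(tied, 0)$gene_id, c("ga", "gb"))
  expect_error(rank_genes(scores, tau = 1.5), "tau")
  expect_error(rank_genes(scores, tau = -0.1), "tau")
})

test_that("rnk export is two tab-separated columns without header", {
  scores <- data.frame(gene_id = c("g1", "g2"), p0 = c(0.9, 0.1),
                       p1 = c(0.05, 0.8), p2 = c(0.05, 0.1),
                       class = c(0L, 1L), signed_score = c(0.9, -0.8))
  path <- tempfile(fileext = ".rnk")
  rank_genes(scores, tau = 0, path = path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_identical(strsplit(lines[1], "\t")[[1]][1], "g1")
})
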
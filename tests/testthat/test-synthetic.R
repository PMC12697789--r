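# Synthetic worlds: reproducibility, the symmetric effect function and the
# emitted tables/features.

test_that("worlds are reproducible and carry the reference default dimensions", {
  w1 <- generate_world(seed = 5)
  w2 <- generate_world(seed = 5)
  expect_identical(w1, w2)
  expect_identical(dim(w1$compound_factors), c(60L, 6L))
  expect_identical(dim(w1$gene_factors), c(200L, 6L))
  expect_identical(dim(w1$cell_factors), c(4L, 6L))
  expect_false(identical(w1, generate_world(seed = 6)))
})

test_that("rank-1 worlds with positive factors share one sign pattern per gene", {
  w <- generate_world(n_compounds = 5, n_genes = 7, n_cells = 2, r = 1, seed = 9)
  w$compound_factors <- abs(w$compound_factors)
  w$cell_factors <- abs(w$cell_factors)
  for (cell in rownames(w$cell_factors)) {
    signs <- sapply(rownames(w$compound_factors), function(cmp)
      sign(set_effect(w, cmp, cell)))
    expect_true(all(apply(signs, 1, function(r) length(unique(r)) == 1)))
    expect_identical(sign(signs[, 1]), sign(w$gene_factors[, 1]))
  }
})

test_that("set effects are symmetric, bounded and reduce correctly", {
  w <- tiny_world(seed = 21)
  cmpds <- rownames(w$compound_factors)[1:4]
  cell <- rownames(w$cell_factors)[1]
  ref <- set_effect(w, cmpds, cell)
  for (k in 1:5) {
    expect_identical(set_effect(w, sample(cmpds), cell), ref)
  }
  expect_true(all(abs(ref) < 1))
  # gamma = 0 singleton: effect is exactly tanh of the latent effect
  w0 <- tiny_world(seed = 21); w0$gamma <- 0
  e <- drop(w0$gene_factors %*%
              (w0$compound_factors[cmpds[1], ] * w0$cell_factors[cell, ]))
  expect_equal(unname(set_effect(w0, cmpds[1], cell)), unname(tanh(e)),
               tolerance = 1e-12)
  expect_error(set_effect(w, "nope", cell), "unknown compound")
  expect_error(set_effect(w, character(0), cell), "nonempty")
})

test_that("emitted tables conserve record counts and approach the noiseless limit", {
  w <- generate_world(n_compounds = 10, n_genes = 15, n_cells = 2, r = 3,
                      noise_sd = 1e-4, seed = 31)
  tabs <- emit_tables(w, n_singleton_sets = 4, n_multisets = 3,
                      set_size_range = c(2, 4), seed = 31)
  expect_identical(nrow(tabs$pretrain), 4L * 2L * 15L)
  expect_identical(nrow(tabs$finetune), 3L * 2L * 15L)
  expect_identical(nrow(tabs$truth), nrow(tabs$pretrain) + nrow(tabs$finetune))
  # with vanishing noise every label matches the sign of the true effect
  all_rec <- rbind(tabs$pretrain, tabs$finetune)
  key <- paste(all_rec$set_id, all_rec$cell_id, all_rec$gene_id)
  tkey <- paste(tabs$truth$set_id, tabs$truth$cell_id, tabs$truth$gene_id)
  eff <- tabs$truth$effect[match(key, tkey)]
  strong <- abs(eff) > 1e-3
  expect_true(all(all_rec$label[strong] == ifelse(eff[strong] > 0, 0L, 1L)))
})

test_that("the no-change fraction rises with the noise level", {
  frac2 <- sapply(c(0.1, 0.5, 2.0), function(ns) {
    w <- generate_world(n_compounds = 10, n_genes = 40, n_cells = 2, r = 3,
                        noise_sd = ns, seed = 32)
    tabs <- emit_tables(w, n_singleton_sets = 6, n_multisets = 3,
                        set_size_range = c(2, 4), seed = 32)
    mean(rbind(tabs$pretrain, tabs$finetune)$label == 2L)
  })
  expect_true(all(diff(frac2) > 0))
})

test_that("emitted features meet the encoder contracts and stay learnable", {
  s <- tiny_setup(seed = 41)
  f <- s$features
  expect_identical(ncol(f$compound), 1181L)
  expect_true(all(f$compound[, 1:881] %in% c(0, 1)))
  expect_identical(ncol(f$gene_network), 256L)
  expect_identical(ncol(f$gene_sequence), 768L)
  expect_identical(ncol(f$cell), 64L)
  # identical seed, identical bundle
  expect_identical(emit_features(s$world, s$tabs$composition)$compound,
                   f$compound)
  # linear probe: latent compound factors are recoverable from the dense part
  dense <- f$compound[, 882:1181]
  for (j in seq_len(ncol(s$world$compound_factors))) {
    fit <- lm.fit(cbind(1, dense[, 1:20]), s$world$compound_factors[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((s$world$compound_factors[, j] -
                                            mean(s$world$compound_factors[, j]))^2)
    expect_gt(r2, 0.5)
  }
})

test_that("feature files round-trip through the TSV reader", {
  s <- tiny_setup(seed = 42)
  dir <- tempfile()
  emit_features(s$world, s$tabs$composition, dir = dir)
  back <- read_features(dir)
  expect_equal(unname(back$compound), unname(s$features$compound),
               tolerance = 1e-9)
  expect_identical(rownames(back$cell), rownames(s$features$cell))
  expect_identical(back$composition$set_id, s$tabs$composition$set_id)
})
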
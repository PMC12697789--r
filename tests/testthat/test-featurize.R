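# Frozen featurizers: compound fingerprint/graph embedding, PPI network
# embedding and protein-sequence embedding.

test_that("featurize_compound yields the 1181-long contract with a binary head", {
  f <- suppressWarnings(featurize_compound("CCO"))
  expect_length(f$full, 1181)
  expect_length(f$fingerprint, 881)
  expect_length(f$graph_embedding, 300)
  expect_true(all(f$fingerprint %in% c(0, 1)))
  expect_identical(f$full, c(f$fingerprint, f$graph_embedding))
  # frozen encoder: identical on repeat
  expect_identical(suppressWarnings(featurize_compound("CCO"))$full, f$full)
})

test_that("SMILES rewritings of one molecule featurize identically", {
  a <- suppressWarnings(featurize_compound("CCO"))
  b <- suppressWarnings(featurize_compound("OCC"))
  expect_identical(a$full, b$full)
  expect_identical(fallback_graph_embed("CCO"), fallback_graph_embed("OCC"))
})

test_that("unparseable SMILES are rejected with the offending string named", {
  expect_error(suppressWarnings(featurize_compound("")), "SMILES")
  expect_error(suppressWarnings(featurize_compound("not-a-molecule((")),
               "not-a-molecule")
  expect_error(fallback_graph_embed(""), "SMILES")
})

test_that("fallback embedding honors dim and separates a panel of molecules", {
  expect_length(fallback_graph_embed("CCO", dim = 4), 4)
  # panel of distinct small molecules: linear chains over C/N/O skeletons
  atoms <- c("C", "N", "O")
  panel <- unique(unlist(lapply(3:6, function(len) {
    vapply(1:12, function(i) {
      set.seed(i * 100 + len)
      paste(sample(atoms, len, replace = TRUE), collapse = "")
    }, character(1))
  })))
  embs <- lapply(panel, function(s)
    tryCatch(fallback_graph_embed(s, dim = 64), error = function(e) NULL))
  keep <- !vapply(embs, is.null, logical(1))
  E <- do.call(rbind, embs[keep])
  canon <- vapply(panel[keep], function(s)
    trimws(ChemmineOB::convertFormat("SMI", "CAN", s)), character(1))
  distinct_mol <- !duplicated(canon)
  E <- E[distinct_mol, , drop = FALSE]
  expect_gt(nrow(E), 20)
  d <- as.matrix(dist(E))
  diag(d) <- Inf
  expect_true(all(d > 1e-8))  # no collisions across distinct molecules
})

test_that("network embedding is seeded-deterministic with the right shape", {
  edges <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g2", "g3"),
                      weight = c(1, 1))
  e1 <- embed_gene_network(edges, dim = 8, seed = 4)
  e2 <- embed_gene_network(edges, dim = 8, seed = 4)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(3L, 8L))
  expect_true(all(is.finite(e1)))
  expect_error(embed_gene_network(edges[0, ]), "nonempty")
})

test_that("structurally equivalent nodes embed closer than distant nodes", {
  # barbell: two 4-cliques joined by a path; the two clique-interior node
  # sets are structurally symmetric
  clique <- function(tag) t(combn(paste0(tag, 1:4), 2))
  edges <- rbind(clique("a"), clique("b"),
                 cbind(c("a1", "p"), c("p", "b1")))
  edges <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2])
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  sims_equiv <- sims_far <- numeric(10)
  for (s in 1:10) {
    emb <- embed_gene_network(edges, dim = 6, seed = s)
    sims_equiv[s] <- cosine(emb["a2", ], emb["a3", ])  # same orbit
    sims_far[s] <- cosine(emb["a2", ], emb["b3", ])    # across the bridge
  }
  expect_gt(mean(sims_equiv), mean(sims_far))
})

test_that("genes absent from the network get zero vectors with a warning", {
  edges <- data.frame(gene_a = "g1", gene_b = "g2")
  expect_warning(
    emb <- embed_gene_network(edges, dim = 4, genes = c("g1", "g2", "gX")),
    "absent")
  expect_identical(emb["gX", ], rep(0, 4))
  expect_false(all(emb["g1", ] == 0))
})

test_that("sequence embedding: contract, determinism, mutation sensitivity", {
  v <- embed_gene_sequence("MKT")
  expect_length(v, 768)
  expect_identical(embed_gene_sequence("MKT"), v)
  expect_length(embed_gene_sequence("MKT", dim = 32), 32)
  expect_error(embed_gene_sequence(""), "nonempty")
  expect_error(embed_gene_sequence("MK7"), "alphabet")
  # 50 random point mutations all change the embedding
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(71)
  base <- paste(sample(aa, 40, replace = TRUE), collapse = "")
  ref <- embed_gene_sequence(base, dim = 128)
  for (k in 1:50) {
    pos <- sample(40, 1)
    sub <- sample(setdiff(aa, substr(base, pos, pos)), 1)
    mut <- base
    substr(mut, pos, pos) <- sub
    expect_false(identical(embed_gene_sequence(mut, dim = 128), ref))
  }
})
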
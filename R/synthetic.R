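# Synthetic worlds with permutation-invariant ground truth.
#
# A world is a low-rank compound x gene x cell effect tensor built from
# latent factor matrices: e[c, g, l] = <compound_c * cell_l, gene_g> (the
# elementwise product of compound and cell factors projected onto the gene
# factor), so effects are compound-, gene- and cell-specific. The effect of
# a compound set is a saturating (tanh) symmetric function of the member
# effects plus a pairwise interaction term, so it is permutation-invariant
# by construction and deliberately sub-additive in cardinality: total effect
# does not scale linearly with the number of compounds.
#
# Factor entries are drawn N(0, r^(-1/6)) so singleton effects have unit
# variance regardless of the rank r.

#' Generate a synthetic world
#'
#' @param n_compounds,n_genes,n_cells world dimensions. The defaults
#'   (60 compounds, 200 genes, 4 cells, rank 6) define the reference world
#'   used throughout the package's experiments.
#' @param r latent rank.
#' @param gamma pairwise interaction strength in set effects.
#' @param noise_sd replicate noise standard deviation on the log2 scale.
#' @param seed integer seed; a world is fully determined by
#'   `(dims, r, gamma, noise_sd, seed)`.
#' @return object of class `"synthetic_world"`.
#' @export
generate_world <- function(n_compounds = 60, n_genes = 200, n_cells = 4,
                           r = 6, gamma = 0.2, noise_sd = 0.3, seed = 1) {
  stopifnot(n_compounds >= 1, n_genes >= 1, n_cells >= 1, r >= 1)
  set.seed(seed)
  sd_f <- r^(-1 / 6)
  cf <- matrix(stats::rnorm(n_compounds * r, sd = sd_f), n_compounds, r,
               dimnames = list(sprintf("cmpd_%03d", seq_len(n_compounds)), NULL))
  gf <- matrix(stats::rnorm(n_genes * r, sd = sd_f), n_genes, r,
               dimnames = list(sprintf("gene_%04d", seq_len(n_genes)), NULL))
  lf <- matrix(stats::rnorm(n_cells * r, sd = sd_f), n_cells, r,
               dimnames = list(sprintf("cell_%02d", seq_len(n_cells)), NULL))
  structure(list(compound_factors = cf, gene_factors = gf, cell_factors = lf,
                 r = r, gamma = gamma, noise_sd = noise_sd, seed = seed),
            class = "synthetic_world")
}

# singleton effect vector over all genes for compound i in cell l
singleton_effects <- function(world, compound, cell) {
  v <- world$compound_factors[compound, ] * world$cell_factors[cell, ]
  drop(world$gene_factors %*% v)
}

#' Ground-truth continuous effect of a compound set
#'
#' `tanh( sum_i e[i,g,l] + gamma * sum_{i<j} <cf_i, cf_j> * sign(e_i + e_j) )`,
#' evaluated for one (set, cell) over one gene or all genes. Symmetric in the
#' set members by construction, bounded in (-1, 1).
#'
#' @param world a `"synthetic_world"`.
#' @param compounds character vector of member compound ids (nonempty).
#' @param cell cell id.
#' @param gene gene id, or `NULL` for the full per-gene effect vector.
#' @return numeric effect(s) in (-1, 1).
#' @export
set_effect <- function(world, compounds, cell, gene = NULL) {
  if (length(compounds) < 1) stop("compound set must be nonempty")
  compounds <- sort(compounds)  # canonical order: bitwise-identical sums
  unknown <- setdiff(compounds, rownames(world$compound_factors))
  if (length(unknown)) stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  if (!cell %in% rownames(world$cell_factors)) stop("unknown cell id: ", cell)
  genes <- rownames(world$gene_factors)
  if (!is.null(gene)) {
    if (!all(gene %in% genes)) stop("unknown gene id(s)")
    genes <- gene
  }
  E <- vapply(compounds, function(i)
    singleton_effects(world, i, cell)[genes], numeric(length(genes)))
  E <- matrix(E, nrow = length(genes))
  total <- rowSums(E)
  inter <- 0
  if (length(compounds) >= 2 && world$gamma != 0) {
    cf <- world$compound_factors[compounds, , drop = FALSE]
    for (i in seq_len(length(compounds) - 1)) {
      for (j in (i + 1):length(compounds)) {
        inter <- inter + sum(cf[i, ] * cf[j, ]) * sign(E[, i] + E[, j])
      }
    }
    inter <- world$gamma * inter
  }
  stats::setNames(tanh(total + inter), genes)
}

#' Emit pre-training / fine-tuning association tables with ground truth
#'
#' Samples singleton sets (for pre-training) and multi-compound sets (for
#' fine-tuning), simulates replicate noisy observations of each set's effect
#' per cell, runs [simple_de()] against matched control replicates, and
#' labels each (set, cell, gene) with [label_association()]. The truth table
#' stores the noiseless continuous effect for score-correlation analyses.
#'
#' @param world a `"synthetic_world"`.
#' @param n_singleton_sets number of single-compound sets (sampled without
#'   replacement from the world's compounds).
#' @param n_multisets number of multi-compound sets.
#' @param set_size_range inclusive cardinality range of multisets (min >= 2;
#'   default 2-20).
#' @param replicates replicate count per arm (default 3).
#' @param genes gene ids to include, or an integer count to subsample
#'   (default: all genes in the world).
#' @param seed integer seed for set sampling and replicate noise.
#' @return list with data frames `pretrain`, `finetune` (association records:
#'   `set_id`, `cell_id`, `gene_id`, `label`, `log2fc`, `p`), `truth`
#'   (`set_id`, `cell_id`, `gene_id`, `effect`) and `composition`
#'   (`set_id`, `compound_id`).
#' @export
emit_tables <- function(world, n_singleton_sets = 36, n_multisets = 18,
                        set_size_range = c(2, 20), replicates = 3,
                        genes = NULL, seed = 1) {
  stopifnot(set_size_range[1] >= 2, replicates >= 2)
  compounds <- rownames(world$compound_factors)
  cells <- rownames(world$cell_factors)
  all_genes <- rownames(world$gene_factors)
  set.seed(seed)
  if (is.null(genes)) {
    genes <- all_genes
  } else if (is.numeric(genes)) {
    genes <- sort(sample(all_genes, min(genes, length(all_genes))))
  }
  n_singleton_sets <- min(n_singleton_sets, length(compounds))
  singles <- sample(compounds, n_singleton_sets)
  comp <- data.frame(
    set_id = sprintf("single_%03d", seq_len(n_singleton_sets)),
    compound_id = singles)
  max_size <- min(set_size_range[2], length(compounds))
  for (k in seq_len(n_multisets)) {
    sz <- sample(seq(set_size_range[1], max_size), 1L)
    comp <- rbind(comp, data.frame(
      set_id = sprintf("multi_%03d", k),
      compound_id = sample(compounds, sz)))
  }
  sets <- unique(comp$set_id)
  rows <- vector("list", length(sets) * length(cells))
  truths <- vector("list", length(rows))
  i <- 0L
  for (s in sets) {
    members <- comp$compound_id[comp$set_id == s]
    for (l in cells) {
      i <- i + 1L
      eff <- set_effect(world, members, l)[genes]
      treated <- matrix(rep(eff, each = replicates), replicates,
                        dimnames = list(NULL, genes)) +
        matrix(stats::rnorm(replicates * length(genes), sd = world$noise_sd),
               replicates)
      control <- matrix(stats::rnorm(replicates * length(genes),
                                     sd = world$noise_sd),
                        replicates, dimnames = list(NULL, genes))
      de <- simple_de(treated, control, min_replicates = 2)
      rows[[i]] <- data.frame(set_id = s, cell_id = l, gene_id = de$gene_id,
                              label = label_association(de$log2fc, de$p),
                              log2fc = de$log2fc, p = de$p)
      truths[[i]] <- data.frame(set_id = s, cell_id = l, gene_id = genes,
                                effect = unname(eff))
    }
  }
  records <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  rownames(records) <- rownames(truth) <- NULL
  is_single <- grepl("^single_", records$set_id)
  list(pretrain = records[is_single, , drop = FALSE],
       finetune = records[!is_single, , drop = FALSE],
       truth = truth, composition = comp, genes = genes)
}

#' Emit frozen feature files for a synthetic world
#'
#' Projects the latent factors through fixed seeded random maps into the
#' encoder-contract dimensions: compounds to 881 binary fingerprint bits plus
#' a 300-long dense part (1181 total), genes to 256 + 768, cells to the
#' latent cell dimension (64). The projections are information-preserving
#' (linear, full column rank with overwhelming probability), so the latent
#' structure remains learnable from the features.
#'
#' @param world a `"synthetic_world"`.
#' @param composition set composition table (`set_id`, `compound_id`), e.g.
#'   from [emit_tables()]; stored in the bundle so the model can resolve sets.
#' @param dims named list overriding feature dimensions
#'   (`fingerprint`, `graph`, `gene_net`, `gene_seq`, `cell`).
#' @param dir optional directory; when given, features are also written as
#'   TSV files (`compound_features.tsv`, `gene_features.tsv`,
#'   `cell_features.tsv`, `composition.tsv`).
#' @return feature bundle: list with matrices `compound`
#'   (`n_compounds x 1181`), `gene_network`, `gene_sequence`, `cell`, and the
#'   `composition` data frame.
#' @export
emit_features <- function(world, composition = NULL,
                          dims = list(fingerprint = 881, graph = 300,
                                      gene_net = 256, gene_seq = 768,
                                      cell = 64),
                          dir = NULL) {
  set.seed(world$seed + 104729L)  # fixed offset: feature maps are frozen per world
  r <- world$r
  proj <- function(F, d, binary = FALSE) {
    P <- matrix(stats::rnorm(r * d), r, d)
    M <- F %*% P
    if (binary) M <- (M > 0) + 0
    M
  }
  compound <- cbind(proj(world$compound_factors, dims$fingerprint, binary = TRUE),
                    proj(world$compound_factors, dims$graph))
  gene_network <- proj(world$gene_factors, dims$gene_net)
  gene_sequence <- proj(world$gene_factors, dims$gene_seq)
  cell <- proj(world$cell_factors, dims$cell)
  bundle <- list(compound = compound, gene_network = gene_network,
                 gene_sequence = gene_sequence, cell = cell,
                 composition = composition)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(m, f) utils::write.table(
      data.frame(id = rownames(m), m, check.names = FALSE),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wr(compound, "compound_features.tsv")
    wr(cbind(gene_network, gene_sequence), "gene_features.tsv")
    wr(cell, "cell_features.tsv")
    if (!is.null(composition))
      utils::write.table(composition, file.path(dir, "composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle
}
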
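# Frozen, deterministic featurizers for compounds and genes.
#
# Compounds: 881 binary fingerprint bits from hashed atom-pair substructure
# descriptors plus a 300-long dense graph embedding from seeded signed
# hashing of the same descriptor multiset (the dense part stands behind a
# pluggable graph-encoder interface so a pretrained encoder can be swapped
# in). Both are functions of the molecule, not of the SMILES writing: atom
# pairs are computed on the parsed structure, so any SMILES of one molecule
# maps to one feature vector.
#
# Genes: a network embedding of the PPI graph (adjacency spectral embedding,
# deterministic under a fixed seed) and a k-mer-hash protein sequence
# embedding standing behind the pluggable sequence-encoder interface.

# atom-pair descriptor multiset of one SMILES; errors on unparseable input
ap_descriptors <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles))
    stop("invalid SMILES string: ", deparse(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "q"))),
    error = function(e) stop("cannot parse SMILES '", smiles, "': ",
                             conditionMessage(e)))
  if (!ChemmineR::validSDF(sdf[1]))
    stop("cannot parse SMILES '", smiles, "'")
  ap <- ChemmineR::sdf2ap(sdf[1])
  codes <- ChemmineR::ap(ap)[[1]]
  if (length(codes) == 0) stop("SMILES '", smiles, "' yields no atom pairs")
  codes
}

# deterministic integer hash of a descriptor code with a salt, kept exact in
# double precision (codes fit in ~2^36). The multiplication modulo a Mersenne
# prime breaks the power-of-two alignment of atom-pair bit fields, which a
# hash linear in the code would propagate into power-of-two table sizes.
hash_code <- function(code, salt, mod) {
  a <- ((code %% 1048573) * 2654435761) %% 2147483647
  b <- ((code %% 65521) * 40503) %% 2147483647
  ((a + b + salt * 7368787) %% 2147483647) %% mod
}

#' Featurize a compound from its SMILES string
#'
#' Produces the 1181-component compound feature: an 881-bit binary
#' substructure-key fingerprint (hashed atom-pair descriptors) concatenated
#' with a 300-long dense graph embedding. The graph embedding comes from
#' `encoder` when supplied (any function `smiles -> numeric(graph_dim)`);
#' otherwise the deterministic [fallback_graph_embed()] is used with a
#' one-time warning. Featurization is idempotent: the same molecule — under
#' any SMILES writing — always yields the identical vector.
#'
#' @param smiles a single SMILES string.
#' @param encoder optional graph-encoder function; `NULL` selects the
#'   deterministic fallback.
#' @param fingerprint_bits,graph_dim feature dimensions (defaults 881, 300).
#' @return object of class `"compound_feature"`: list with `compound_id`
#'   (the input SMILES), `fingerprint` (0/1 vector), `graph_embedding`, and
#'   `full` (their concatenation, length 1181 by default).
#' @export
featurize_compound <- function(smiles, encoder = NULL,
                               fingerprint_bits = 881, graph_dim = 300) {
  codes <- ap_descriptors(smiles)
  fp <- numeric(fingerprint_bits)
  fp[hash_code(unique(codes), 1, fingerprint_bits) + 1] <- 1
  ge <- if (is.null(encoder)) {
    warn_fallback_once()
    fallback_graph_embed(smiles, dim = graph_dim)
  } else {
    v <- encoder(smiles)
    if (length(v) != graph_dim)
      stop("encoder returned length ", length(v), "; expected ", graph_dim)
    v
  }
  structure(list(compound_id = smiles, fingerprint = fp, graph_embedding = ge,
                 full = c(fp, ge)),
            class = "compound_feature")
}

warn_fallback_once <- local({
  done <- FALSE
  function() {
    if (!done) {
      done <<- TRUE
      warning("no graph encoder supplied; using the deterministic fallback ",
              "graph embedding", call. = FALSE)
    }
  }
})

#' Deterministic fallback graph embedding
#'
#' A frozen stand-in for a pretrained graph encoder: the atom-pair descriptor
#' multiset of the parsed molecule is projected into `dim` components by
#' seeded signed hashing of descriptor counts, then L2-normalized. Because
#' atom-pair descriptors are computed on the molecular graph, different
#' SMILES writings of one molecule map to the identical embedding.
#'
#' @param smiles a single SMILES string.
#' @param dim embedding length (default 300).
#' @return numeric vector of length `dim`.
#' @export
fallback_graph_embed <- function(smiles, dim = 300) {
  codes <- ap_descriptors(smiles)
  tab <- table(codes)
  vals <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  v <- numeric(dim)
  for (salt in 1:4) {   # 4 hash repetitions densify the embedding
    idx <- hash_code(vals, salt, dim) + 1
    sgn <- 1 - 2 * (hash_code(vals, salt + 100, 2))
    for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + sgn[i] * cnt[i]
  }
  n <- sqrt(sum(v^2))
  if (n > 0) v <- v / n
  v
}

#' Embed genes from a protein-protein interaction network
#'
#' Deterministic adjacency spectral embedding of the PPI graph: each node
#' receives a `dim`-long coordinate vector such that structurally similar
#' nodes receive nearby embeddings. Reproducible under a fixed seed; genes
#' requested but absent from the graph receive zero vectors with a warning.
#'
#' @param edges data frame edge list with columns `gene_a`, `gene_b` and
#'   optionally `weight`.
#' @param dim embedding length (default 256).
#' @param genes optional character vector of gene ids that must each receive
#'   a vector (absent ones get zeros).
#' @param seed integer seed.
#' @return matrix, one row per gene, `dim` columns.
#' @export
embed_gene_network <- function(edges, dim = 256, genes = NULL, seed = 1) {
  if (is.null(edges) || nrow(edges) == 0) stop("edge list must be nonempty")
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  if ("weight" %in% names(edges)) igraph::E(g)$weight <- edges$weight
  n <- igraph::vcount(g)
  k <- min(dim, max(1L, n - 1L))
  set.seed(seed)
  emb <- igraph::embed_adjacency_matrix(g, no = k)$X
  # canonical sign: largest-magnitude loading of each column positive
  for (j in seq_len(ncol(emb))) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  if (ncol(emb) < dim)
    emb <- cbind(emb, matrix(0, n, dim - ncol(emb)))
  rownames(emb) <- igraph::V(g)$name
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(emb))
    if (length(missing))
      warning(length(missing), " gene(s) absent from the network; ",
              "assigned zero embeddings: ",
              paste(utils::head(missing, 5), collapse = ", "))
    out <- matrix(0, length(genes), dim, dimnames = list(genes, NULL))
    hit <- intersect(genes, rownames(emb))
    out[hit, ] <- emb[hit, ]
    return(out)
  }
  emb
}

#' Embed a protein sequence
#'
#' Deterministic k-mer-hash embedding standing behind the pluggable
#' sequence-encoder interface: counts of overlapping 3-mers are projected to
#' `dim` components by signed hashing and L2-normalized. Any single-residue
#' change alters at least one 3-mer and hence the embedding.
#'
#' @param protein_seq amino-acid string over the 20-letter alphabet
#'   (`X` tolerated).
#' @param dim embedding length (default 768).
#' @return numeric vector of length `dim`.
#' @export
embed_gene_sequence <- function(protein_seq, dim = 768) {
  if (!is.character(protein_seq) || length(protein_seq) != 1 ||
      is.na(protein_seq) || !nzchar(protein_seq))
    stop("protein sequence must be a nonempty string")
  s <- toupper(protein_seq)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s))
    stop("sequence contains characters outside the amino-acid alphabet")
  chars <- utf8ToInt(s)
  k <- 3L
  v <- numeric(dim)
  n <- length(chars)
  kmers <- if (n < k) paste(chars, collapse = "-") else
    vapply(seq_len(n - k + 1L), function(i)
      paste(chars[i:(i + k - 1L)], collapse = "-"), character(1))
  h <- vapply(kmers, str_hash, numeric(1))
  idx <- (h %% dim) + 1
  sgn <- 1 - 2 * ((h %/% dim) %% 2)
  for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + sgn[i]
  nr <- sqrt(sum(v^2))
  if (nr > 0) v <- v / nr
  v
}

# small deterministic polynomial string hash (kept below 2^31)
str_hash <- function(s) {
  h <- 7
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  h
}
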
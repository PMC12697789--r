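# Differential-expression labeling: converts per-gene (log2 fold change,
# p-value) statistics into the 3-class association labels the classifier
# trains on. Classes: 0 = up (log2FC > 0, p < 0.05), 1 = down (log2FC < 0,
# p < 0.05), 2 = no effect (p > 0.05). The boundary cases p == 0.05, and
# log2FC == 0 with p < 0.05, are conservatively assigned to class 2.

#' Label an association from differential-expression statistics
#'
#' @param log2fc log2 fold change(s), treated vs control.
#' @param p raw p-value(s) in `[0, 1]`.
#' @return integer vector of class labels: 0 (up), 1 (down) or 2 (no effect).
#' @export
#' @examples
#' label_association(0.5, 0.01)   # 0: up
#' label_association(-1.2, 0.001) # 1: down
#' label_association(3.0, 0.5)    # 2: no effect
label_association <- function(log2fc, p) {
  if (length(log2fc) != length(p)) stop("log2fc and p must have equal length")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  ifelse(p < 0.05 & log2fc > 0, 0L,
         ifelse(p < 0.05 & log2fc < 0, 1L, 2L))
}

#' Simple per-gene two-sample differential expression
#'
#' A plain Welch two-sample t-test per gene on (already log2-scale) replicate
#' profiles: the log2 fold change is the difference in arm means, the p-value
#' comes from the Welch t statistic. Intended for synthetic and toy data, not
#' as a replacement for a moderated DE model on real counts.
#'
#' Genes with zero variance in both arms get p = 1 when the mean difference is
#' 0 and p = 0 otherwise.
#'
#' @param treated,control numeric matrices, replicates x genes, on log2 scale.
#' @param min_replicates minimum replicates required per arm (default 3,
#'   matching the replicate filter used when curating perturbation profiles;
#'   hard floor of 2 for the test to be defined).
#' @return data frame with columns `gene_id`, `log2fc`, `p`.
#' @export
simple_de <- function(treated, control, min_replicates = 3) {
  treated <- as.matrix(treated); control <- as.matrix(control)
  if (ncol(treated) != ncol(control)) stop("arms must cover the same genes")
  if (nrow(treated) < max(2, min_replicates) || nrow(control) < max(2, min_replicates))
    stop("each arm needs at least ", max(2, min_replicates), " replicates")
  n1 <- nrow(treated); n2 <- nrow(control)
  m1 <- colMeans(treated); m2 <- colMeans(control)
  v1 <- apply(treated, 2L, stats::var); v2 <- apply(control, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  gene_id <- colnames(treated)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_len(ncol(treated)))
  data.frame(gene_id = gene_id, log2fc = unname(diff), p = unname(p),
             t = unname(tstat), row.names = NULL)
}

#' Build the 3-class association table from DE results
#'
#' Joins per-(set, cell) differential-expression tables with the set
#' composition map, applies the labeling rule, and flags each record for the
#' pre-training (singleton sets) or fine-tuning (multi-compound sets)
#' partition. Sets whose members cannot all be resolved to compound features
#' keep their resolvable members; sets with no resolvable member are dropped
#' with a message reporting the dropped record count.
#'
#' @param de_results data frame with columns `set_id`, `cell_id`, `gene_id`,
#'   `log2fc`, `p` (one row per association).
#' @param composition data frame with columns `set_id`, `compound_id`.
#' @param featurized character vector of compound ids with available feature
#'   vectors; defaults to all compounds in `composition`.
#' @return data frame of association records: `set_id`, `cell_id`, `gene_id`,
#'   `label`, `log2fc`, `p`, `partition` (`"pretrain"` or `"finetune"`).
#' @export
build_association_table <- function(de_results, composition,
                                    featurized = unique(composition$compound_id)) {
  comp <- composition[composition$compound_id %in% featurized, , drop = FALSE]
  sizes <- table(comp$set_id)
  resolvable <- names(sizes)
  dropped <- !(de_results$set_id %in% resolvable)
  if (any(dropped))
    message("dropping ", sum(dropped),
            " records whose sets have no featurizable compound")
  out <- de_results[!dropped, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no records remain after dropping unresolvable sets")
    return(data.frame(set_id = character(), cell_id = character(),
                      gene_id = character(), label = integer(),
                      log2fc = numeric(), p = numeric(),
                      partition = character()))
  }
  out$label <- label_association(out$log2fc, out$p)
  card <- as.integer(sizes[out$set_id])
  out$partition <- ifelse(card == 1L, "pretrain", "finetune")
  rownames(out) <- NULL
  out[, c("set_id", "cell_id", "gene_id", "label", "log2fc", "p", "partition")]
}
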
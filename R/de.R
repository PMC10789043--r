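# Nonparametric differential expression by rank-sum AUC.
#
# The AUC for a gene is the probability that a randomly chosen cell of group
# A expresses it more highly than a randomly chosen cell of group B (ties
# counted half); equivalently U / (nA * nB) from the Wilcoxon rank-sum
# statistic with mid-ranks. Nonparametric testing is deliberate: cells of one
# barcode need not follow any parametric count model, e.g. the stochastic
# responders of separation-of-function variants.

#' AUC-based differential expression between two cell groups
#'
#' Per-gene two-sample Wilcoxon rank-sum test with mid-rank tie handling.
#' `AUC = U / (nA * nB)`; p-values from the tie-corrected normal
#' approximation, adjusted across genes by Benjamini-Hochberg.
#'
#' @param expr sparse or dense cells x genes count (or expression) matrix
#'   with cell ids as rownames.
#' @param cells_a,cells_b disjoint, non-empty character vectors of cell ids
#'   (group A first: `AUC > 0.5` means higher in A).
#' @param fdr_level FDR level for the significance flag (default 0.1).
#' @return tibble of class `de_result`: `gene, auc, p_value, q_value,
#'   direction` (`up` if AUC > 0.5, `down` if < 0.5), `significant`.
#' @export
de_auc <- function(expr, cells_a, cells_b, fdr_level = 0.1) {
  assert_that(length(cells_a) > 0 && length(cells_b) > 0,
              "both cell groups must be non-empty")
  if (length(intersect(cells_a, cells_b)) > 0) {
    abort("cell groups overlap")
  }
  missing <- setdiff(c(cells_a, cells_b), rownames(expr))
  assert_that(length(missing) == 0,
              paste0(length(missing), " cell id(s) not found in `expr`"))
  na <- length(cells_a); nb <- length(cells_b); n <- na + nb
  x <- expr[c(cells_a, cells_b), , drop = FALSE]
  in_a <- seq_len(na)
  genes <- colnames(x) %||% paste0("g", seq_len(ncol(x)))

  auc <- numeric(ncol(x)); pval <- numeric(ncol(x))
  block <- 500L
  for (start in seq(1, ncol(x), by = block)) {
    cols <- seq(start, min(start + block - 1L, ncol(x)))
    xb <- as.matrix(x[, cols, drop = FALSE])
    for (j in seq_along(cols)) {
      v <- xb[, j]
      r <- rank(v)           # mid-ranks
      u <- sum(r[in_a]) - na * (na + 1) / 2
      auc[cols[j]] <- u / (na * nb)
      tie <- rle(sort.int(v, method = "quick"))$lengths
      sigma2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
      if (sigma2 <= 0) {
        pval[cols[j]] <- 1
      } else {
        z <- (u - na * nb / 2) / sqrt(sigma2)
        pval[cols[j]] <- 2 * pnorm(-abs(z))
      }
    }
  }
  out <- tibble(gene = genes, auc = auc, p_value = pval,
                q_value = p.adjust(pval, method = "BH")) |>
    mutate(direction = case_when(auc > 0.5 ~ "up", auc < 0.5 ~ "down",
                                 TRUE ~ "none"),
           significant = .data$q_value <= fdr_level)
  class(out) <- c("de_result", class(out))
  attr(out, "fdr_level") <- fdr_level
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  out
}

#' Differential expression of the loss-of-function group against NT cells
#'
#' gRNAs with at least `min_fraction` of their cells and at least
#' `min_cells` cells in the LoF meta-cluster form the LoF group; DE is then
#' computed between all LoF-group cells and all cells with non-targeting
#' gRNAs.
#'
#' @param clusters tibble `cell_id, meta_cluster` (from
#'   [cluster_and_merge()]).
#' @param cells tibble `cell_id, grna_id, is_nt` (per-cell gRNA calls).
#' @param expr cells x genes matrix.
#' @param min_fraction,min_cells LoF-group membership rule (defaults 0.70
#'   and 3).
#' @param fdr_level FDR level (default 0.1).
#' @return list with `lof_grnas` (tibble of gRNAs and their LoF-cluster
#'   occupancy) and `de` (a `de_result`, or `NULL` with a warning when the
#'   LoF group is empty).
#' @export
lof_group_de <- function(clusters, cells, expr, min_fraction = 0.70,
                         min_cells = 3, fdr_level = 0.1) {
  d <- cells |>
    inner_join(clusters, by = "cell_id") |>
    filter(!.data$is_nt, !is.na(.data$grna_id))
  occupancy <- d |>
    group_by(.data$grna_id) |>
    summarise(n_cells = n(),
              n_lof = sum(.data$meta_cluster == "LoF"),
              frac_lof = .data$n_lof / .data$n_cells, .groups = "drop") |>
    mutate(in_lof_group = .data$frac_lof >= min_fraction &
             .data$n_lof >= min_cells)
  lof_cells <- d |>
    filter(.data$grna_id %in% occupancy$grna_id[occupancy$in_lof_group]) |>
    pull("cell_id")
  nt_cells <- cells$cell_id[cells$is_nt]
  if (length(lof_cells) == 0) {
    warn("empty LoF group: no gRNA meets the membership rule")
    return(list(lof_grnas = occupancy, de = NULL))
  }
  list(lof_grnas = occupancy,
       de = de_auc(expr, lof_cells, nt_cells, fdr_level = fdr_level))
}

#' Correlation of per-barcode differential expression profiles
#'
#' For every barcode group with at least `min_cells` cells, computes the
#' per-gene AUC of its cells against the reference cells (wild-type genotype
#' plus non-targeting), restricts to the union of genes significant for at
#' least one barcode, and returns the pairwise Pearson correlation matrix of
#' the AUC vectors, hierarchically ordered for reporting.
#'
#' @param expr cells x genes matrix.
#' @param barcode_cells tibble `cell_id, group_id`.
#' @param reference_cells character vector of reference cell ids.
#' @param min_cells minimum cells per barcode (default 10).
#' @param fdr_level FDR level used for the significant-gene union.
#' @return list with `auc` (genes x barcodes AUC matrix on the significant
#'   union), `correlation` (barcode x barcode matrix), `order` (hierarchical
#'   ordering of barcode ids).
#' @export
barcode_de_correlation <- function(expr, barcode_cells, reference_cells,
                                   min_cells = 10, fdr_level = 0.1) {
  sizes <- count(barcode_cells, .data$group_id)
  keep <- sizes$group_id[sizes$n >= min_cells]
  if (length(keep) == 0) {
    abort(paste0("no barcode group reaches min_cells = ", min_cells))
  }
  de_list <- map(keep, function(g) {
    cl <- setdiff(barcode_cells$cell_id[barcode_cells$group_id == g],
                  reference_cells)
    de_auc(expr, cl, setdiff(reference_cells, cl), fdr_level = fdr_level)
  })
  names(de_list) <- keep
  sig_union <- unique(unlist(map(de_list, function(d) d$gene[d$significant])))
  if (length(sig_union) < 2) {
    warn("fewer than 2 significant genes across barcodes; using all genes")
    sig_union <- de_list[[1]]$gene
  }
  auc_mat <- vapply(de_list, function(d) {
    d$auc[match(sig_union, d$gene)]
  }, numeric(length(sig_union)))
  rownames(auc_mat) <- sig_union
  cm <- cor(auc_mat, method = "pearson")
  ord <- if (ncol(cm) > 2) {
    colnames(cm)[hclust(dist(Matrix::t(cm)), method = "average")$order]
  } else colnames(cm)
  list(auc = auc_mat, correlation = cm, order = ord)
}

#' Gene signature separating SoF from full-impact missense variants
#'
#' Selects genes either significantly upregulated for SoF versus full-impact
#' missense and not downregulated versus benign missense (`AUC > auc_up`),
#' or significantly downregulated versus full-impact and not upregulated
#' versus benign (`AUC < auc_down`). Genes on a simple progressive
#' benign -> LoF trajectory fail both rules.
#'
#' @param de_vs_full `de_result` of SoF cells against full-impact homozygous
#'   missense cells.
#' @param de_vs_benign `de_result` of SoF cells against benign missense
#'   cells.
#' @param auc_up,auc_down AUC-vs-benign floors/ceilings (defaults 0.45 and
#'   0.55).
#' @return list of tibbles `up` and `down` (gene, both AUCs).
#' @export
sof_gene_signature <- function(de_vs_full, de_vs_benign, auc_up = 0.45,
                               auc_down = 0.55) {
  if (is.null(de_vs_full) || is.null(de_vs_benign) ||
      nrow(de_vs_full) == 0 || nrow(de_vs_benign) == 0) {
    warn("empty stratum: returning empty SoF signature")
    empty <- tibble(gene = character(), auc_vs_full = numeric(),
                    auc_vs_benign = numeric())
    return(list(up = empty, down = empty))
  }
  d <- inner_join(
    select(as_tibble(de_vs_full), "gene", auc_vs_full = "auc",
           sig_full = "significant"),
    select(as_tibble(de_vs_benign), "gene", auc_vs_benign = "auc"),
    by = "gene")
  up <- d |>
    filter(.data$sig_full, .data$auc_vs_full > 0.5,
           .data$auc_vs_benign > auc_up) |>
    select("gene", "auc_vs_full", "auc_vs_benign")
  down <- d |>
    filter(.data$sig_full, .data$auc_vs_full < 0.5,
           .data$auc_vs_benign < auc_down) |>
    select("gene", "auc_vs_full", "auc_vs_benign")
  list(up = up, down = down)
}
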
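# Quality control, feature selection, embedding and clustering.

#' MAD-based quality-control filtering of cells
#'
#' Removes low outliers for the total count and for the number of detected
#' features (on the log scale) and high outliers for the percentage of
#' counts from mitochondrial genes (raw scale), each defined as more than
#' `mad_multiplier` median-absolute-deviations from the median in the stated
#' direction.
#'
#' @param counts sparse cells x genes count matrix.
#' @param mito_genes character vector of mitochondrial gene ids (may be
#'   empty, e.g. for synthetic data: the rule then passes vacuously).
#' @param mad_multiplier outlier multiplier (default 3).
#' @return list with `counts` (filtered matrix), `report` (per-rule removal
#'   counts) and `removed` (tibble of removed cells with the rule that
#'   removed them).
#' @export
qc_filter <- function(counts, mito_genes = character(), mad_multiplier = 3) {
  totals <- Matrix::rowSums(counts)
  nfeat <- Matrix::rowSums(counts > 0)
  lt <- log1p(totals); lf <- log1p(nfeat)
  # zero MAD (e.g. saturated feature counts in homogeneous synthetic data)
  # means no measurable spread, hence no outliers under this rule
  low <- function(x) mad(x) > 0 & x < median(x) - mad_multiplier * mad(x)
  high <- function(x) mad(x) > 0 & x > median(x) + mad_multiplier * mad(x)
  rm_total <- low(lt)
  rm_feat <- low(lf)
  mito_genes <- intersect(mito_genes, colnames(counts))
  if (length(mito_genes) > 0) {
    mito_pct <- 100 * Matrix::rowSums(counts[, mito_genes, drop = FALSE]) /
      pmax(totals, 1)
    rm_mito <- high(mito_pct)
  } else {
    rm_mito <- rep(FALSE, nrow(counts))
  }
  drop <- rm_total | rm_feat | rm_mito
  if (all(drop)) abort("QC removed every cell; check the input matrix")
  rule <- case_when(rm_total ~ "low_total", rm_feat ~ "low_features",
                    rm_mito ~ "high_mito", TRUE ~ NA_character_)
  list(counts = counts[!drop, , drop = FALSE],
       report = tibble(rule = c("low_total", "low_features", "high_mito"),
                       n_removed = c(sum(rm_total), sum(rm_feat),
                                     sum(rm_mito))),
       removed = tibble(cell_id = rownames(counts)[drop],
                        rule = rule[drop]))
}

#' Library-size normalize and log-transform a count matrix
#'
#' Counts are scaled so every cell has the median total count, then
#' `log1p`-transformed.
#'
#' @param counts sparse cells x genes count matrix.
#' @return sparse cells x genes matrix of log-normalized expression.
#' @export
normalize_log_counts <- function(counts) {
  totals <- Matrix::rowSums(counts)
  sf <- totals / median(totals[totals > 0])
  sf[sf == 0] <- 1
  out <- Diagonal(x = 1 / sf) %*% counts
  dimnames(out) <- dimnames(counts)
  out@x <- log1p(out@x)
  out
}

#' Select DE + pathway genes and embed cells by PCA
#'
#' Genes differentially expressed for at least one gRNA with at least
#' `min_cells_de` assigned cells (each tested against the non-targeting
#' cells) are united with a supplied pathway gene list; cells are then
#' embedded by PCA of the scaled log-normalized expression restricted to
#' that union. PC signs are fixed (largest-magnitude loading positive) so
#' the embedding is deterministic.
#'
#' @param expr sparse cells x genes count matrix.
#' @param cells tibble `cell_id, grna_id, is_nt` covering the rows of
#'   `expr`.
#' @param pathway_genes character vector of pathway genes (for synthetic
#'   screens, the signature gene list).
#' @param n_pcs number of principal components (default 15).
#' @param min_cells_de minimum cells per gRNA for the DE discovery
#'   (default 10).
#' @param fdr_level FDR level for DE-gene discovery (default 0.1).
#' @return list with `embedding` (cells x n_pcs matrix), `genes_used`,
#'   `de_genes`, `per_grna` (tibble of tested gRNAs).
#' @export
select_features_and_embed <- function(expr, cells, pathway_genes,
                                      n_pcs = 15, min_cells_de = 10,
                                      fdr_level = 0.1) {
  nt_cells <- cells$cell_id[cells$is_nt]
  assert_that(length(nt_cells) > 0, "no non-targeting cells present")
  tested <- cells |>
    filter(!.data$is_nt, !is.na(.data$grna_id)) |>
    count(.data$grna_id, name = "n_cells") |>
    filter(.data$n_cells >= min_cells_de)
  # one dense copy of the tested cells' expression saves a sparse-to-dense
  # conversion per gRNA in the DE discovery loop
  test_cells <- union(nt_cells,
                      cells$cell_id[!is.na(cells$grna_id) &
                                      cells$grna_id %in% tested$grna_id])
  expr_de <- if (length(test_cells) * ncol(expr) <= 1.5e8) {
    as.matrix(expr[test_cells, , drop = FALSE])
  } else expr[test_cells, , drop = FALSE]
  de_genes <- character()
  for (g in tested$grna_id) {
    cl <- cells$cell_id[!is.na(cells$grna_id) & cells$grna_id == g]
    de <- de_auc(expr_de, cl, nt_cells, fdr_level = fdr_level)
    de_genes <- union(de_genes, de$gene[de$significant])
  }
  genes_used <- union(de_genes, intersect(pathway_genes, colnames(expr)))
  if (length(genes_used) == 0) abort("empty feature set: no DE or pathway genes")
  ln <- normalize_log_counts(expr)[, genes_used, drop = FALSE]
  x <- scale(as.matrix(ln))
  x[, attr(x, "scaled:scale") == 0] <- 0
  n_pcs <- max(1, min(n_pcs, ncol(x) - 1, nrow(x) - 1))
  pc <- prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  emb <- sweep(pc$x, 2, flip, "*")
  rownames(emb) <- rownames(expr)
  list(embedding = emb, genes_used = genes_used, de_genes = de_genes,
       per_grna = tested)
}

# exact k-nearest neighbours by blockwise euclidean distances
knn_index <- function(embedding, k) {
  n <- nrow(embedding)
  assert_that(k < n, "k must be smaller than the number of cells")
  sq <- rowSums(embedding^2)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1, n, by = block)) {
    rows <- seq(start, min(start + block - 1L, n))
    d2 <- outer(sq[rows], sq, "+") -
      2 * embedding[rows, , drop = FALSE] %*% t(embedding)
    for (i in seq_along(rows)) {
      v <- d2[i, ]; v[rows[i]] <- Inf
      o <- order(v)[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(pmax(v[o], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' Louvain clustering and merging into two meta-clusters
#'
#' Fine clusters come from Louvain community detection on the unweighted
#' `n_neighbors`-nearest-neighbour graph of the embedding. Fine clusters are
#' merged into exactly two meta-clusters by average-linkage hierarchical
#' clustering of their embedding centroids cut at k = 2; the meta-cluster
#' with the higher percentage of non-targeting cells is labelled `notLoF`.
#'
#' @param embedding cells x dims matrix with cell ids as rownames.
#' @param is_nt logical vector (per row of `embedding`): cell carries a
#'   non-targeting gRNA.
#' @param n_neighbors neighbours for the graph (default 10).
#' @param resolution Louvain resolution (default 1).
#' @param seed seed for the community detection.
#' @return list of class `cluster_result`: `cells` (tibble `cell_id,
#'   cluster, meta_cluster`), `cluster_summary` (per fine cluster: size, NT
#'   percentage, meta-cluster).
#' @export
cluster_and_merge <- function(embedding, is_nt, n_neighbors = 10,
                              resolution = 1, seed = 1L) {
  n <- nrow(embedding)
  assert_that(n >= 2 * n_neighbors,
              "need at least 2 * n_neighbors cells to cluster")
  assert_that(length(is_nt) == n, "`is_nt` must match the embedding rows")
  kn <- knn_index(embedding, n_neighbors)
  edges <- cbind(rep(seq_len(n), n_neighbors), as.vector(kn$idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  fine <- igraph::membership(comm)
  if (length(unique(fine)) < 2) {
    abort("community detection found a single cluster; increase `resolution`")
  }
  centroids <- rowsum(embedding, fine) / as.vector(table(fine))
  hc <- hclust(dist(centroids), method = "average")
  meta_of_fine <- cutree(hc, k = 2)
  meta <- meta_of_fine[as.character(fine)]
  nt_pct <- vapply(1:2, function(m) 100 * mean(is_nt[meta == m]), numeric(1))
  labels <- if (nt_pct[1] >= nt_pct[2]) c("notLoF", "LoF") else c("LoF", "notLoF")
  cells <- tibble(cell_id = rownames(embedding),
                  cluster = as.integer(fine),
                  meta_cluster = labels[meta])
  summary <- cells |>
    mutate(is_nt = is_nt) |>
    group_by(.data$cluster) |>
    summarise(n_cells = n(), nt_pct = 100 * mean(.data$is_nt),
              meta_cluster = .data$meta_cluster[1], .groups = "drop")
  structure(list(cells = cells, cluster_summary = summary),
            class = "cluster_result")
}
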
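# Linking transcriptomes to consensus genotypes through clone barcodes,
# label transfer between datasets, and the evaluation statistics.

#' Link RNA cells to consensus genotypes through their barcodes
#'
#' An RNA cell whose gRNA + iBAR combination (or, failing that, whose mapped
#' puroR) matches a barcode group with a callable consensus genotype inherits
#' that group's genotype and consequence. Unlinked cells are reported with a
#' reason (`no_barcode`, `no_matching_group`, `uncallable_genotype`).
#'
#' @param rna_assignments output of [co_assign()] on the RNA modality.
#' @param consensus output of [call_consensus()] /
#'   [assign_consequence()].
#' @param mapping output of [map_puror_to_grna_ibar()] (from the DNA
#'   modality).
#' @return list with `linked` (tibble `cell_id, group_id, status, zygosity,
#'   consequence`) and `unlinked` (tibble `cell_id, reason`).
#' @export
link_rna_to_genotype <- function(rna_assignments, consensus, mapping) {
  pmap_tbl <- mapping |> filter(.data$mapped) |>
    select("puror", map_grna = "grna", map_ibar = "ibar")
  d <- rna_assignments |>
    left_join(pmap_tbl, by = "puror") |>
    mutate(group_id = case_when(
      .data$unique_grna_ibar ~ paste(.data$grna, .data$ibar, sep = "|"),
      !is.na(.data$map_grna) ~ paste(.data$map_grna, .data$map_ibar,
                                     sep = "|"),
      TRUE ~ NA_character_)) |>
    left_join(select(consensus, "group_id", "status", "zygosity",
                     any_of("consequence"), "variants"),
              by = "group_id")
  linked <- d |>
    filter(!is.na(.data$status), .data$status != "uncallable") |>
    select("cell_id", "group_id", "status", "zygosity",
           any_of("consequence"), "variants")
  unlinked <- d |>
    filter(is.na(.data$status) | .data$status == "uncallable") |>
    mutate(reason = case_when(
      is.na(.data$group_id) ~ "no_barcode",
      is.na(.data$status) ~ "no_matching_group",
      TRUE ~ "uncallable_genotype")) |>
    select("cell_id", "reason")
  list(linked = linked, unlinked = unlinked)
}

#' Transfer meta-cluster labels from a reference to a query dataset
#'
#' Both datasets are centered per gene (a deliberately simple stand-in for a
#' full batch correction) and jointly embedded by PCA; each query cell then
#' receives the coordinates of its single nearest reference cell and the
#' modal meta-cluster label among its `k` nearest reference neighbours, with
#' label ties broken towards the label whose supporting neighbours are
#' nearer (smaller distance-rank sum) and neighbour-distance ties broken by
#' cell id.
#'
#' @param reference_expr,query_expr cells x genes matrices over a shared
#'   gene space (cell ids as rownames).
#' @param reference_labels character vector of labels, one per reference
#'   cell.
#' @param k neighbours for the majority vote (default 10).
#' @param n_pcs dimensionality of the joint embedding (default 15).
#' @return tibble `cell_id, label, nn_cell_id` (the 1-nearest reference
#'   cell) plus `coord_1..coord_d` columns (that neighbour's reference
#'   coordinates).
#' @export
transfer_labels <- function(reference_expr, query_expr, reference_labels,
                            k = 10, n_pcs = 15) {
  assert_that(k <= nrow(reference_expr),
              "`k` exceeds the number of reference cells")
  genes <- intersect(colnames(reference_expr), colnames(query_expr))
  assert_that(length(genes) > 1, "reference and query share too few genes")
  assert_that(length(reference_labels) == nrow(reference_expr),
              "`reference_labels` must match the reference cells")
  r <- scale(as.matrix(normalize_log_counts(reference_expr)[, genes,
                                                            drop = FALSE]),
             scale = FALSE)
  q <- scale(as.matrix(normalize_log_counts(query_expr)[, genes,
                                                        drop = FALSE]),
             scale = FALSE)
  joint <- rbind(r, q)
  n_pcs <- min(n_pcs, ncol(joint) - 1, nrow(joint) - 1)
  pc <- prcomp(joint, rank. = n_pcs, center = FALSE)
  emb_r <- pc$x[seq_len(nrow(r)), , drop = FALSE]
  emb_q <- pc$x[nrow(r) + seq_len(nrow(q)), , drop = FALSE]
  ref_ids <- rownames(reference_expr)
  emb_rt <- t(emb_r)
  out <- map(seq_len(nrow(emb_q)), function(i) {
    d2 <- colSums((emb_rt - emb_q[i, ])^2)
    # deterministic neighbour order: distance, then reference cell id
    o <- order(d2, ref_ids)
    nn <- o[seq_len(k)]
    votes <- table(reference_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      ranksum <- vapply(top, function(lb) {
        sum(which(reference_labels[nn] == lb))
      }, numeric(1))
      top <- top[which.min(ranksum)]
    }
    list(label = top[1], nn = o[1])
  })
  coords <- emb_r[map_dbl(out, "nn"), , drop = FALSE]
  colnames(coords) <- paste0("coord_", seq_len(ncol(coords)))
  bind_cols(tibble(cell_id = rownames(query_expr),
                   label = map_chr(out, "label"),
                   nn_cell_id = ref_ids[map_dbl(out, "nn")]),
            as_tibble(coords))
}

#' Remove cells that are the lone representative of their barcode in a
#' cluster
#'
#' Denoises barcode misassignment: a cell is dropped when it is the only
#' cell with its barcode inside its (meta-)cluster.
#'
#' @param linked tibble with `cell_id`, `group_id` and a cluster label
#'   column.
#' @param cluster_col name of the cluster label column (default
#'   `"meta_cluster"`).
#' @return the filtered tibble.
#' @export
filter_lone_barcode_cells <- function(linked, cluster_col = "meta_cluster") {
  linked |>
    group_by(.data$group_id, .data[[cluster_col]]) |>
    filter(n() > 1) |>
    ungroup()
}

#' Evaluate genotype calls against phenotype classes
#'
#' Restricts to barcodes called wild-type or a definite-LoF genotype (stop
#' codon / splice) and counts: true positives (stop/splice with a LoF
#' phenotype), false positives (stop/splice but notLoF), false negatives
#' (WT with a LoF phenotype) and true negatives (WT, notLoF). Precision and
#' recall are reported as exact fractions and as percentages rounded to the
#' nearest integer; an empty positive class is an error rather than a
#' silent zero.
#'
#' @param barcode_classes tibble `group_id, genotype_class, phenotype_class`
#'   with `genotype_class` in `WT | stop_gained | splice` and
#'   `phenotype_class` in `LoF | notLoF`.
#' @return list of class `eval_report`: confusion counts, `precision`,
#'   `recall`, `precision_pct`, `recall_pct`, and the classified table.
#' @export
evaluate_classification <- function(barcode_classes) {
  d <- barcode_classes |>
    filter(.data$genotype_class %in% c("WT", "stop_gained", "splice"))
  pos <- d$genotype_class != "WT"
  lof <- d$phenotype_class == "LoF"
  tp <- sum(pos & lof); fp <- sum(pos & !lof)
  fn <- sum(!pos & lof); tn <- sum(!pos & !lof)
  if (tp + fp == 0) abort("no barcodes in the positive (stop/splice) class: precision undefined")
  if (tp + fn == 0) abort("no barcodes with a LoF phenotype: recall undefined")
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall,
                 precision_pct = round(100 * precision),
                 recall_pct = round(100 * recall),
                 table = d),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Genotype-vs-phenotype evaluation (positive class: stop/splice)\n")
  cat("  TP", x$tp, " FP", x$fp, " FN", x$fn, " TN", x$tn, "\n")
  cat("  precision", x$precision_pct, "% recall", x$recall_pct, "%\n")
  invisible(x)
}

#' Summarize the overlap of puroR and gRNA + iBAR assignments
#'
#' @param co_assignments output of [co_assign()] (one row per cell).
#' @return tibble with `n_unique_puror`, `n_unique_grna_ibar`, `n_both`, the
#'   two overlap fractions, and their nearest-integer percentages.
#' @export
summarize_linkage <- function(co_assignments) {
  if (nrow(co_assignments) == 0) abort("no cells to summarize")
  n_p <- sum(co_assignments$unique_puror)
  n_gi <- sum(co_assignments$unique_grna_ibar)
  n_b <- sum(co_assignments$both)
  if (n_p == 0 || n_gi == 0) abort("no cells with assigned barcodes")
  tibble(n_unique_puror = n_p, n_unique_grna_ibar = n_gi, n_both = n_b,
         frac_puror_with_grna_ibar = n_b / n_p,
         frac_grna_ibar_with_puror = n_b / n_gi,
         pct_puror_with_grna_ibar = round(100 * n_b / n_p),
         pct_grna_ibar_with_puror = round(100 * n_b / n_gi))
}

#' Summarize concordance between called and predicted genotypes
#'
#' @param records output of [compare_to_prediction()].
#' @return tibble with the fractions of nucleotide-exact and protein-level
#'   concordant records and the breakdown of protein-discordance reasons.
#' @export
concordance_summary <- function(records) {
  assert_that(nrow(records) >= 1, "need at least one comparison record")
  disc <- filter(records, !.data$protein_match)
  breakdown <- disc |>
    count(.data$reason, name = "n") |>
    mutate(frac_of_discordant = .data$n / max(1, nrow(disc)))
  tibble(n = nrow(records),
         frac_nucleotide_exact = mean(records$nucleotide_match),
         frac_protein_concordant = mean(records$protein_match),
         pct_nucleotide_exact = round(100 * mean(records$nucleotide_match)),
         pct_protein_concordant = round(100 * mean(records$protein_match)),
         breakdown = list(breakdown))
}
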
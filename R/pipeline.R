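# End-to-end orchestration on a synthetic screen: simulate -> call barcodes
# -> consensus genotypes -> transcriptome analysis -> linkage -> evaluation.

class_counts <- function(bc, class) {
  keep <- bc$features$feature_id[bc$features$class == class]
  bc$counts[, keep, drop = FALSE]
}

assign_modality <- function(bc, min_count = 2, seed = 1L) {
  per_class <- lapply(c(gRNA = "gRNA", iBAR = "iBAR", puroR = "puroR"),
                      function(cl) {
    m <- class_counts(bc, cl)
    fit <- fit_count_mixture(m@x, min_count = min_count, seed = seed)
    # when no ambient cluster is identifiable (ambient posterior never
    # drops to p_hi, e.g. ambient-free simulations) fall back to the
    # degenerate pair: every count above the floor is signal
    degenerate <- structure(list(t_lo = min_count, t_hi = min_count,
                                 p_lo = 0.9, p_hi = 0.1),
                            class = "threshold_pair")
    thr <- tryCatch(assignment_thresholds(fit), error = function(e) {
      if (!grepl("never reaches", conditionMessage(e))) abort(conditionMessage(e))
      warn(paste0(cl, ": no ambient cluster identifiable; treating all ",
                  "counts above min_count as signal"))
      degenerate
    })
    # an upper threshold above the bulk of observed counts, or an ambient
    # component sitting on top of the nearest signal component, means no
    # ambient cluster separated (e.g. ambient-free simulations)
    xi_sorted <- sort(fit$xi)
    if (thr$t_hi > quantile(m@x[m@x > min_count], 0.90) ||
        xi_sorted[2] - xi_sorted[1] < 0.5) {
      warn(paste0(cl, ": upper threshold excludes almost all counts; ",
                  "treating all counts above min_count as signal"))
      thr <- degenerate
    }
    list(fit = fit, thresholds = thr,
         assignments = assign_features(m, thr))
  })
  co <- co_assign(per_class$gRNA$assignments, per_class$iBAR$assignments,
                  per_class$puroR$assignments)
  list(per_class = per_class, co = co)
}

#' Run the full pipeline on a synthetic screen
#'
#' Simulates a coupled scDNA + scRNA screen from `config`, then runs every
#' stage: skew-normal mixture barcode calling on both modalities, puroR
#' mapping and barcode-group formation, edit-type and recurrence filtering,
#' consensus genotyping with consequence assignment, expression QC /
#' embedding / clustering / diffusion scoring, genotype-transcriptome
#' linkage, per-barcode classification and the evaluation summaries.
#'
#' @param config a [sim_config()].
#' @param consensus_pars a [consensus_params()].
#' @param n_pcs,n_neighbors embedding dimensionality and neighbourhood size.
#' @param fdr_level FDR level for differential expression.
#' @param min_cells_de minimum cells per gRNA for DE-gene discovery.
#' @param outdir optional directory; when given, all stage outputs are
#'   written there.
#' @return list of class `pipeline_result` with each stage's output and a
#'   `report` tibble of stage-level counts.
#' @export
run_pipeline <- function(config = sim_config(), consensus_pars = consensus_params(),
                         n_pcs = 15, n_neighbors = 10, fdr_level = 0.1,
                         min_cells_de = 10, outdir = NULL) {
  screen <- generate_screen(config)
  truth <- screen$truth

  # --- barcode calling, both modalities
  dna <- assign_modality(screen$dna_barcode_counts, seed = config$seed + 11L)
  rna <- assign_modality(screen$rna_barcode_counts, seed = config$seed + 12L)
  linkage_summary <- summarize_linkage(dna$co)

  # --- barcode groups and consensus genotypes
  mapping <- map_puror_to_grna_ibar(dna$co)
  groups <- form_barcode_groups(dna$co, mapping)
  variants <- filter_edit_types(screen$variants,
                                consensus_pars$allowed_substitutions)
  variants <- remove_recurrent_artifacts(variants, groups$membership,
                                         consensus_pars$recurrence_fraction)
  consensus <- call_consensus(groups, variants, consensus_pars,
                              ploidy = config$ploidy)
  consensus <- assign_consequence(consensus, truth$annotation,
                                  truth$promoter_interval,
                                  ploidy = config$ploidy)

  # --- transcriptome
  qc <- qc_filter(screen$rna_gene_counts)
  expr <- qc$counts
  rna_cells <- tibble(cell_id = rownames(expr)) |>
    left_join(select(rna$co, "cell_id", grna_id = "grna"), by = "cell_id") |>
    mutate(is_nt = !is.na(.data$grna_id) & grepl("^NT-", .data$grna_id))
  emb <- select_features_and_embed(expr, rna_cells,
                                   truth$signature_genes$gene,
                                   n_pcs = n_pcs, min_cells_de = min_cells_de,
                                   fdr_level = fdr_level)
  clusters <- cluster_and_merge(emb$embedding, rna_cells$is_nt,
                                n_neighbors = n_neighbors,
                                seed = config$seed + 13L)
  nt_cells <- rna_cells$cell_id[rna_cells$is_nt]
  # well-separated expression states can disconnect the kNN kernel graph at
  # any practical k; bridging restores the dense-kernel behaviour
  diffusion <- diffusion_score(emb$embedding, nt_cells,
                               n_neighbors = n_neighbors,
                               bridge_components = TRUE)

  # --- linkage and classification
  link <- link_rna_to_genotype(rna$co, consensus, mapping)
  linked <- link$linked |>
    inner_join(clusters$cells, by = "cell_id") |>
    inner_join(diffusion, by = "cell_id")
  linked <- filter_lone_barcode_cells(linked)
  barcode_scores <- select(linked, "group_id", "cell_id", "score")
  wt_groups <- intersect(consensus$group_id[consensus$status == "WT"],
                         barcode_scores$group_id)
  stop_groups <- intersect(
    consensus$group_id[!is.na(consensus$consequence) &
                         consensus$consequence == "stop_gained"],
    barcode_scores$group_id)
  classes <- if (length(wt_groups) > 0 && length(stop_groups) > 0) {
    classify_barcodes(barcode_scores, wt_groups = wt_groups,
                      stop_groups = stop_groups)
  } else {
    warn("no WT or stop-codon reference barcodes; skipping classification")
    NULL
  }

  eval_input <- if (is.null(classes)) NULL else consensus |>
    filter(.data$status != "uncallable") |>
    mutate(genotype_class = case_when(
      .data$status == "WT" ~ "WT",
      .data$consequence %in% c("stop_gained", "splice") ~ .data$consequence,
      TRUE ~ "other")) |>
    inner_join(select(classes, "group_id", "class"), by = "group_id") |>
    mutate(phenotype_class = ifelse(.data$class == "LoF", "LoF", "notLoF")) |>
    select("group_id", "genotype_class", "phenotype_class")
  evaluation <- if (is.null(eval_input)) NULL else {
    tryCatch(evaluate_classification(eval_input),
             error = function(e) {
               warn(conditionMessage(e)); NULL
             })
  }

  # --- concordance with gRNA-based prediction
  guides <- truth$barcodes |>
    distinct(.data$grna_id, .data$protospacer, .data$strand,
             chrom = "chr1", site_pos = .data$site_pos,
             targeting = .data$targeting)
  predicted <- predict_genotype_from_grna(guides,
                                          window = truth$editing_window,
                                          ploidy = config$ploidy)
  called_for_cmp <- consensus |>
    filter(.data$status != "uncallable") |>
    inner_join(select(groups$groups, "group_id", grna_id = "grna"),
               by = "group_id") |>
    filter(!is.na(.data$grna_id), !grepl("^NT-", .data$grna_id))
  comparison <- compare_to_prediction(called_for_cmp, predicted,
                                      truth$annotation,
                                      truth$promoter_interval,
                                      ploidy = config$ploidy)
  concordance <- if (nrow(comparison)) concordance_summary(comparison) else NULL

  report <- tibble(
    stage = c("barcodes_simulated", "dna_cells", "rna_cells",
              "dna_cells_both_barcodes", "rna_cells_grna_ibar",
              "barcode_groups", "groups_min_size", "callable_groups",
              "rna_cells_linked", "barcodes_classified"),
    n = c(nrow(truth$barcodes), nrow(truth$cells_dna), nrow(truth$cells_rna),
          sum(dna$co$both), sum(rna$co$unique_grna_ibar),
          nrow(groups$groups),
          sum(groups$groups$size >= consensus_pars$min_group_size),
          sum(consensus$status != "uncallable"),
          nrow(linked), if (is.null(classes)) 0L else nrow(classes)))

  out <- structure(list(
    config = config, screen = screen, dna = dna, rna = rna,
    linkage_summary = linkage_summary, mapping = mapping, groups = groups,
    filtered_variants = variants, consensus = consensus, qc = qc,
    rna_cells = rna_cells, embedding = emb, clusters = clusters,
    diffusion = diffusion, link = link, linked = linked, classes = classes,
    evaluation = evaluation, comparison = comparison,
    concordance = concordance, report = report), class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_screen(screen, file.path(outdir, "screen"))
    readr::write_tsv(consensus |> select(-"variants"),
                     file.path(outdir, "consensus.tsv"))
    write_consensus_vcf(consensus, file.path(outdir, "consensus.vcf"),
                        ploidy = config$ploidy)
    readr::write_tsv(clusters$cells, file.path(outdir, "clusters.tsv"))
    readr::write_tsv(diffusion, file.path(outdir, "diffusion_scores.tsv"))
    if (!is.null(classes)) {
      readr::write_tsv(classes, file.path(outdir, "barcode_classes.tsv"))
    }
    readr::write_tsv(report, file.path(outdir, "run_report.tsv"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("snvscreen pipeline run (seed ", x$config$seed, ")\n", sep = "")
  print(as.data.frame(x$report), row.names = FALSE)
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
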
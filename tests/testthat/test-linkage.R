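test_that("RNA cells link through callable barcodes with reasons for the rest", {
  consensus <- tibble::tibble(
    group_id = c("g1|i1", "g2|i2"),
    status = c("edited", "uncallable"),
    zygosity = c("homozygous", NA),
    consequence = c("missense", NA),
    variants = list(tibble::tibble(chrom = "chr1", pos = 5L, ref = "C",
                                   alt = "T", dosage = 3L),
                    NULL))
  rna <- tibble::tibble(
    cell_id = c("r1", "r2", "r3", "r4"),
    grna = c("g1", "g2", NA, "g9"),
    ibar = c("i1", "i2", NA, "i9"),
    puror = c(NA, NA, "P1", NA),
    unique_grna_ibar = c(TRUE, TRUE, FALSE, TRUE),
    unique_puror = c(FALSE, FALSE, TRUE, FALSE),
    both = FALSE)
  mapping <- tibble::tibble(puror = "P1", grna = "g1", ibar = "i1",
                            n_cells = 4L, mapped = TRUE)
  out <- link_rna_to_genotype(rna, consensus, mapping)
  expect_setequal(out$linked$cell_id, c("r1", "r3"))  # r3 via the puroR map
  expect_identical(out$unlinked$reason[out$unlinked$cell_id == "r2"],
                   "uncallable_genotype")
  expect_identical(out$unlinked$reason[out$unlinked$cell_id == "r4"],
                   "no_matching_group")
})

test_that("noise-free screens link every assigned RNA cell to its true genotype", {
  res <- noisefree_run()
  truth_bc <- res$screen$truth$barcodes
  truth_of_cell <- stats::setNames(
    paste(truth_bc$grna_id, truth_bc$ibar, sep = "|")[
      match(res$screen$truth$cells_rna$barcode_id, truth_bc$barcode_id)],
    res$screen$truth$cells_rna$cell_id)
  linked <- res$link$linked
  expect_gt(nrow(linked), 0)
  expect_true(all(linked$group_id == truth_of_cell[linked$cell_id]))
  # assigned cells (gRNA+iBAR, or a mapped puroR) of callable groups all link
  callable <- res$consensus$group_id[res$consensus$status != "uncallable"]
  co <- res$rna$co
  mapped_purors <- res$mapping$puror[res$mapping$mapped]
  assigned <- co$cell_id[co$unique_grna_ibar |
                           (!is.na(co$puror) & co$puror %in% mapped_purors)]
  should_link <- assigned[truth_of_cell[assigned] %in% callable]
  expect_setequal(linked$cell_id, should_link)
})

test_that("label transfer matches the exhaustive k-NN oracle on a small fixture", {
  withr::with_seed(81, {
    n_ref <- 120; n_q <- 40; n_genes <- 25
    ref <- matrix(rpois(n_ref * n_genes, 5), nrow = n_ref)
    ref[1:60, 1:5] <- ref[1:60, 1:5] + 20
    rownames(ref) <- sprintf("ref%03d", seq_len(n_ref))
    colnames(ref) <- sprintf("g%02d", seq_len(n_genes))
    labels <- rep(c("LoF", "notLoF"), each = 60)
    q <- matrix(rpois(n_q * n_genes, 5), nrow = n_q)
    q[1:20, 1:5] <- q[1:20, 1:5] + 20
    rownames(q) <- sprintf("q%02d", seq_len(n_q))
    colnames(q) <- colnames(ref)
  })
  got <- transfer_labels(ref, q, labels, k = 10, n_pcs = 24)
  # oracle: same centering + joint PCA, then exhaustive distances
  norm_center <- function(m) {
    tot <- rowSums(m)
    m2 <- log1p(m / (tot / median(tot)))
    sweep(m2, 2, colMeans(m2))
  }
  joint <- rbind(norm_center(ref), norm_center(q))
  pc <- prcomp(joint, rank. = 24, center = FALSE)
  want <- brute_knn_labels(pc$x[1:n_ref, ], pc$x[n_ref + (1:n_q), ],
                           labels, rownames(ref), k = 10)
  expect_identical(got$label, want)
  # majority rule: mostly-LoF neighbourhoods inherit LoF
  expect_identical(got$label[1:20], rep("LoF", 20))
  # a query identical to the reference inherits each twin's label and
  # coordinates cell by cell
  got1 <- transfer_labels(ref, ref, labels, k = 10)
  expect_identical(got1$nn_cell_id, rownames(ref))
  expect_identical(got1$label, labels)
  expect_error(transfer_labels(ref, q, labels, k = 500), "exceeds")
})

test_that("lone barcode cells within a cluster are filtered", {
  linked <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:10),
    group_id = c(rep("b1", 6), rep("b2", 4)),
    meta_cluster = c(rep("LoF", 5), "notLoF", rep("LoF", 2), rep("notLoF", 2)))
  out <- filter_lone_barcode_cells(linked)
  expect_false("c06" %in% out$cell_id)        # b1's lone notLoF cell
  expect_setequal(out$cell_id, setdiff(linked$cell_id, "c06"))
  # brute-force oracle on a random fixture
  withr::with_seed(82, {
    r <- tibble::tibble(cell_id = sprintf("r%03d", 1:200),
                        group_id = sample(sprintf("b%d", 1:8), 200, TRUE),
                        meta_cluster = sample(c("LoF", "notLoF"), 200, TRUE))
  })
  got <- filter_lone_barcode_cells(r)
  keep <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    keep[i] <- sum(r$group_id == r$group_id[i] &
                     r$meta_cluster == r$meta_cluster[i]) > 1
  }
  expect_setequal(got$cell_id, r$cell_id[keep])
})

test_that("evaluation reproduces the printed confusion statistics", {
  d <- tibble::tibble(
    group_id = sprintf("b%03d", 1:104),
    genotype_class = c(rep("stop_gained", 12), rep("splice", 15),
                       rep("WT", 77)),
    phenotype_class = c(rep("LoF", 12),              # all stops high
                        rep("LoF", 14), "notLoF",    # one splice FP
                        "LoF", rep("notLoF", 76)))   # one WT FN
  ev <- evaluate_classification(d)
  expect_identical(ev$tp, 26L)
  expect_identical(ev$fp, 1L)
  expect_identical(ev$fn, 1L)
  expect_identical(ev$precision_pct, 96)
  expect_identical(ev$recall_pct, 96)
  expect_error(
    evaluate_classification(d[d$genotype_class == "WT", ]),
    "positive")
})

test_that("evaluation metrics equal the closed formulas on random tables", {
  withr::with_seed(83, {
    for (rep in 1:200) {
      n <- sample(4:40, 1)
      d <- tibble::tibble(
        group_id = sprintf("b%02d", 1:n),
        genotype_class = sample(c("WT", "stop_gained", "splice", "missense"),
                                n, TRUE),
        phenotype_class = sample(c("LoF", "notLoF"), n, TRUE))
      pos <- d$genotype_class %in% c("stop_gained", "splice")
      wt <- d$genotype_class == "WT"
      tp <- sum(pos & d$phenotype_class == "LoF")
      fp <- sum(pos & d$phenotype_class == "notLoF")
      fn <- sum(wt & d$phenotype_class == "LoF")
      if (tp + fp == 0 || tp + fn == 0) {
        expect_error(evaluate_classification(d))
      } else {
        ev <- evaluate_classification(d)
        expect_identical(ev$precision, tp / (tp + fp))
        expect_identical(ev$recall, tp / (tp + fn))
        expect_true(ev$precision >= 0 && ev$precision <= 1)
        expect_true(ev$recall >= 0 && ev$recall <= 1)
        # permutation invariance
        ev2 <- evaluate_classification(d[sample(n), ])
        expect_identical(tidy(ev), tidy(ev2))
      }
    }
  })
})

test_that("linkage summary reproduces the printed overlap percentages", {
  n_both <- 10112; n_p_only <- 13102 - 10112; n_gi_only <- 10869 - 10112
  co <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(n_both + n_p_only + n_gi_only + 500)),
    unique_grna_ibar = c(rep(TRUE, n_both), rep(FALSE, n_p_only),
                         rep(TRUE, n_gi_only), rep(FALSE, 500)),
    unique_puror = c(rep(TRUE, n_both), rep(TRUE, n_p_only),
                     rep(FALSE, n_gi_only), rep(FALSE, 500)))
  co$both <- co$unique_grna_ibar & co$unique_puror
  s <- summarize_linkage(co)
  expect_identical(s$n_unique_puror, 13102L)
  expect_identical(s$n_unique_grna_ibar, 10869L)
  expect_identical(s$n_both, 10112L)
  expect_identical(s$pct_puror_with_grna_ibar, 77)
  expect_identical(s$pct_grna_ibar_with_puror, 93)
  # degenerate identity case
  co2 <- co[co$both, ]
  s2 <- summarize_linkage(co2)
  expect_identical(s2$pct_puror_with_grna_ibar, 100)
  expect_identical(s2$pct_grna_ibar_with_puror, 100)
  expect_error(summarize_linkage(co[0, ]), "no cells")
})

test_that("concordance summary matches truth-derived expectations noise-free", {
  cfg <- sim_config(n_barcodes = 60, cells_per_barcode_dna = 12,
                    dropout_rate = 0, het_noise_rate = 0,
                    recurrent_artifact_sites = 0,
                    genotype_class_probs = c(WT = 0.2, het1 = 0.3, het2 = 0,
                                             hom = 0.5),
                    ambient_mixture = list(pi = c(0, 0.6, 0.4),
                                           xi = c(1.25, 3.2, 4.6),
                                           omega = c(0.3, 0.45, 0.4),
                                           alpha = c(2, 0, -1)),
                    cells_per_barcode_rna = 5, n_genes = 100,
                    n_signature_genes = 10, seed = 85)
  scr <- generate_screen(cfg)
  tb <- scr$truth$barcodes
  # form groups directly from truth and call consensus
  co <- tibble::tibble(cell_id = scr$truth$cells_dna$cell_id,
                       grna = tb$grna_id[match(scr$truth$cells_dna$barcode_id,
                                               tb$barcode_id)],
                       ibar = tb$ibar[match(scr$truth$cells_dna$barcode_id,
                                            tb$barcode_id)],
                       puror = NA_character_,
                       unique_grna_ibar = TRUE, unique_puror = FALSE,
                       both = FALSE)
  grp <- form_barcode_groups(co, map_puror_to_grna_ibar(co))
  cons <- call_consensus(grp, filter_edit_types(scr$variants))
  called <- dplyr::inner_join(
    cons[cons$status != "uncallable", ],
    dplyr::mutate(tb[tb$targeting, c("grna_id", "ibar")],
                  group_id = paste(.data$grna_id, .data$ibar, sep = "|")),
    by = "group_id")
  guides <- dplyr::distinct(tb[tb$targeting, ],
                            .data$grna_id, .data$protospacer, .data$strand,
                            .data$site_pos, targeting = TRUE, chrom = "chr1")
  pred <- predict_genotype_from_grna(guides)
  cmp <- compare_to_prediction(called, pred, scr$truth$annotation,
                               scr$truth$promoter_interval)
  out <- concordance_summary(cmp)
  # truth-derived expectation: noise-free consensus equals the simulated
  # class per barcode, so concordance follows directly from the class and
  # whether the guide has any editable window cytosine
  tb_key <- paste(tb$grna_id, tb$ibar, sep = "|")
  cls <- tb$genotype_class[match(called$group_id, tb_key)]
  pred_n <- vapply(called$grna_id, function(g) {
    nrow(pred$predicted[[match(g, pred$grna_id)]])
  }, integer(1))
  want_nuc <- cls == "hom" | pred_n == 0
  expect_equal(out$frac_nucleotide_exact, mean(want_nuc))
  reasons <- out$breakdown[[1]]
  n_het_disc <- sum(cls == "het1" & pred_n > 0 & !cmp$protein_match)
  expect_identical(reasons$n[reasons$reason == "heterozygous"], n_het_disc)
})
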
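test_that("identical config and seed give bit-identical screens", {
  cfg <- small_config()
  a <- generate_screen(cfg)
  b <- generate_screen(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$rna_gene_counts, b$rna_gene_counts)
  expect_identical(a$dna_barcode_counts$counts, b$dna_barcode_counts$counts)
  expect_identical(a$truth$barcodes, b$truth$barcodes)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(dropout_rate = 1.2), "dropout_rate")
  expect_error(sim_config(ploidy = 0), "ploidy")
  expect_error(sim_config(n_signature_genes = 50, n_genes = 10),
               "n_signature_genes")
  expect_error(sim_config(ambient_mixture = list(pi = c(0.5, 0.5),
                                                 xi = c(1, 2),
                                                 omega = c(1, 1),
                                                 alpha = c(0, 0))),
               "3 components")
  expect_error(sim_config(genotype_class_probs = c(WT = 0.5, het1 = 0.1,
                                                   het2 = 0.1, hom = 0.1)),
               "sum to 1")
})

test_that("every simulated cell maps to one barcode and NT truth is empty", {
  scr <- small_screen()
  tb <- scr$truth$barcodes
  expect_equal(anyDuplicated(scr$truth$cells_dna$cell_id), 0)
  expect_true(all(scr$truth$cells_dna$barcode_id %in% tb$barcode_id))
  nt <- tb[!tb$targeting, ]
  expect_true(all(vapply(nt$variants, nrow, integer(1)) == 0))
  expect_true(all(vapply(tb$variants, function(v) {
    nrow(v) == 0 || all(v$dosage <= scr$config$ploidy)
  }, logical(1))))
})

test_that("noise-free genotyping reproduces each barcode's truth exactly", {
  cfg <- noisefree_config()
  scr <- generate_screen(cfg)
  keys <- truth_genotype_keys(scr)
  names(keys) <- scr$truth$barcodes$barcode_id
  obs <- split(scr$variants, scr$variants$cell_id)
  for (i in seq_len(nrow(scr$truth$cells_dna))) {
    cell <- scr$truth$cells_dna$cell_id[i]
    bc <- scr$truth$cells_dna$barcode_id[i]
    got <- obs[[cell]]
    got_key <- if (is.null(got)) "" else
      variant_key(got[order(got$pos), ])
    truth_sorted <- scr$truth$barcodes$variants[[
      match(bc, scr$truth$barcodes$barcode_id)]]
    expect_identical(got_key,
                     variant_key(truth_sorted[order(truth_sorted$pos), ]))
  }
})

test_that("true dosage is kept at zero dropout and lost at total dropout", {
  scr <- small_screen()
  cells <- scr$truth$cells_dna
  v0 <- simulate_cell_genotypes(scr$truth, cells, dropout_rate = 0,
                                het_noise_rate = 0, seed = 5)
  hom_bc <- scr$truth$barcodes$barcode_id[
    scr$truth$barcodes$genotype_class == "hom" &
      vapply(scr$truth$barcodes$variants, nrow, integer(1)) > 0]
  hom_cells <- cells$cell_id[cells$barcode_id %in% hom_bc]
  hom_rows <- v0[v0$cell_id %in% hom_cells &
                   v0$pos < 64990000, ]   # true sites only
  expect_true(all(hom_rows$dosage == scr$config$ploidy))

  v1 <- simulate_cell_genotypes(scr$truth, cells, dropout_rate = 1,
                                het_noise_rate = 0, seed = 5)
  expect_true(all(v1$pos >= 64990000))  # only planted artifact sites remain
  expect_error(simulate_cell_genotypes(scr$truth, cells, dropout_rate = -1),
               "dropout_rate")
})

test_that("empirical dropout rate sits in the exact binomial 99% CI", {
  cfg <- sim_config(n_barcodes = 120, cells_per_barcode_dna = 20,
                    cells_per_barcode_rna = 5, n_genes = 100,
                    n_signature_genes = 10,
                    genotype_class_probs = c(WT = 0, het1 = 0, het2 = 0,
                                             hom = 1),
                    seed = 17)
  scr <- generate_screen(cfg)
  cells <- scr$truth$cells_dna
  delta <- 0.10
  v <- simulate_cell_genotypes(scr$truth, cells, dropout_rate = delta,
                               het_noise_rate = 0, seed = 21)
  truth_long <- tidyr::unnest(
    dplyr::inner_join(cells[, c("cell_id", "barcode_id")],
                      scr$truth$barcodes[, c("barcode_id", "variants")],
                      by = "barcode_id"), "variants")
  obs <- dplyr::left_join(
    truth_long,
    dplyr::rename(v, obs_dosage = "dosage"),
    by = c("cell_id", "chrom", "pos", "ref", "alt"))
  obs$obs_dosage[is.na(obs$obs_dosage)] <- 0L
  n_alleles <- sum(obs$dosage)
  expect_gt(n_alleles, 5000)
  missed <- n_alleles - sum(obs$obs_dosage)
  region <- binom_region(n_alleles, delta)
  expect_gte(missed, region[1])
  expect_lte(missed, region[2])
})

test_that("spurious heterozygous noise matches the configured rate", {
  cfg <- small_config()
  scr <- generate_screen(cfg)
  eps <- 0.05
  big_cells <- scr$truth$cells_dna
  v <- simulate_cell_genotypes(scr$truth, big_cells, dropout_rate = 0,
                               het_noise_rate = eps, seed = 31)
  decoys <- scr$truth$noise_sites$pos[scr$truth$noise_sites$type == "decoy"]
  n_draws <- nrow(big_cells) * length(decoys)
  expect_gt(n_draws, 5000)
  n_spur <- sum(v$pos %in% decoys)
  region <- binom_region(n_draws, eps)
  expect_gte(n_spur, region[1])
  expect_lte(n_spur, region[2])
  expect_true(all(v$dosage[v$pos %in% decoys] == 1))
})

test_that("with zero ambient weight every nonzero count is the cell's own", {
  cfg <- noisefree_config()
  scr <- generate_screen(cfg)
  bc <- scr$truth$barcodes
  m <- scr$dna_barcode_counts$counts
  own <- bc[match(scr$truth$cells_dna$barcode_id, bc$barcode_id), ]
  for (i in sample(nrow(m), 25)) {
    nz <- colnames(m)[m[i, ] > 0]
    expect_setequal(nz, c(own$grna_id[i], own$ibar[i], own$puror[i]))
  }
})

test_that("null effect sizes leave LoF and baseline cells exchangeable", {
  cfg <- sim_config(n_barcodes = 40, frac_nt = 0.5, cells_per_barcode_rna = 30,
                    n_genes = 200, n_signature_genes = 40,
                    lof_logfc = rep(0, 40),
                    missense_phenotype_probs = c(notLoF = 0, SoF = 0, LoF = 1),
                    consequence_probs = c(stop_gained = 1, splice = 0,
                                          missense = 0, synonymous = 0,
                                          intron = 0, promoter = 0),
                    genotype_class_probs = c(WT = 0, het1 = 0, het2 = 0,
                                             hom = 1),
                    seed = 41)
  scr <- generate_screen(cfg)
  pheno <- truth_phenotypes(scr)
  names(pheno) <- scr$truth$barcodes$barcode_id
  state <- pheno[scr$truth$cells_rna$barcode_id]
  lof_cells <- scr$truth$cells_rna$cell_id[state == "LoF"][1:500]
  wt_cells <- scr$truth$cells_rna$cell_id[state == "notLoF"][1:500]
  de <- de_auc(scr$rna_gene_counts, lof_cells, wt_cells)
  expect_lt(mean(abs(de$auc - 0.5)), 0.02)
})

test_that("default effects give strong signature AUCs between LoF and WT", {
  cfg <- sim_config(n_barcodes = 40, frac_nt = 0.4, cells_per_barcode_rna = 40,
                    n_genes = 300, n_signature_genes = 30,
                    missense_phenotype_probs = c(notLoF = 0, SoF = 0, LoF = 1),
                    consequence_probs = c(stop_gained = 1, splice = 0,
                                          missense = 0, synonymous = 0,
                                          intron = 0, promoter = 0),
                    genotype_class_probs = c(WT = 0, het1 = 0, het2 = 0,
                                             hom = 1),
                    seed = 42)
  scr <- generate_screen(cfg)
  pheno <- truth_phenotypes(scr)
  names(pheno) <- scr$truth$barcodes$barcode_id
  state <- pheno[scr$truth$cells_rna$barcode_id]
  lof_cells <- scr$truth$cells_rna$cell_id[state == "LoF"][1:500]
  wt_cells <- scr$truth$cells_rna$cell_id[state == "notLoF"][1:500]
  de <- de_auc(scr$rna_gene_counts, lof_cells, wt_cells)
  sig <- de[de$gene %in% scr$truth$signature_genes$gene, ]
  oriented <- ifelse(scr$truth$signature_genes$lof_logfc > 0, sig$auc,
                     1 - sig$auc)
  expect_true(all(oriented >= 0.8))
})
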
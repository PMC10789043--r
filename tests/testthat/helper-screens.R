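# Shared simulated screens, memoized so expensive runs happen once per
# test session.

.screen_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .screen_cache)) {
    assign(key, force(expr), envir = .screen_cache)
  }
  get(key, envir = .screen_cache)
}

# small screen for module tests
small_config <- function(seed = 11, ...) {
  sim_config(n_barcodes = 60, cells_per_barcode_rna = 20, n_genes = 400,
             n_signature_genes = 40, seed = seed, ...)
}

small_screen <- function() cached("small_screen", generate_screen(small_config()))

# noise-free variant of the small screen (dropout, het noise, ambient and
# artifacts all off)
noisefree_config <- function(seed = 12, ...) {
  sim_config(n_barcodes = 60, cells_per_barcode_rna = 20, n_genes = 400,
             n_signature_genes = 40, dropout_rate = 0, het_noise_rate = 0,
             recurrent_artifact_sites = 0,
             ambient_mixture = list(pi = c(0, 0.6, 0.4),
                                    xi = c(1.6, 3.2, 4.6),
                                    omega = c(0.35, 0.45, 0.40),
                                    alpha = c(2, 0, -1)),
             seed = seed, ...)
}

# the default study-scale configuration, shared by the acceptance checks
default_run <- function() cached("default_run", run_pipeline(sim_config(seed = 1)))

noisefree_run <- function() {
  cached("noisefree_run", run_pipeline(noisefree_config()))
}

# a small two-state expression screen with NT flags, used across the
# embedding / clustering / diffusion tests
two_state_fixture <- function() {
  cached("two_state_fixture", {
    cfg <- sim_config(n_barcodes = 40, frac_nt = 0.3, cells_per_barcode_rna = 20,
                      n_genes = 300, n_signature_genes = 30,
                      missense_phenotype_probs = c(notLoF = 0.5, SoF = 0,
                                                   LoF = 0.5),
                      seed = 51)
    scr <- generate_screen(cfg)
    tb <- scr$truth$barcodes
    cells <- tibble::tibble(
      cell_id = scr$truth$cells_rna$cell_id,
      barcode_id = scr$truth$cells_rna$barcode_id,
      grna_id = tb$grna_id[match(scr$truth$cells_rna$barcode_id,
                                 tb$barcode_id)])
    cells$is_nt <- grepl("^NT-", cells$grna_id)
    pheno <- stats::setNames(tb$phenotype_class, tb$barcode_id)
    cells$state <- pheno[cells$barcode_id]
    emb <- select_features_and_embed(scr$rna_gene_counts, cells,
                                     scr$truth$signature_genes$gene,
                                     n_pcs = 10)
    list(screen = scr, cells = cells, emb = emb)
  })
}

# truth lookup helpers
variant_key <- function(v) {
  paste(sprintf("%s:%d:%s>%s:%d", v$chrom, v$pos, v$ref, v$alt, v$dosage),
        collapse = ";")
}

truth_genotype_keys <- function(screen) {
  tb <- screen$truth$barcodes
  stats::setNames(vapply(tb$variants, variant_key, character(1)),
                  paste(tb$grna_id, tb$ibar, sep = "|"))
}

truth_phenotypes <- function(screen) {
  tb <- screen$truth$barcodes
  stats::setNames(tb$phenotype_class, paste(tb$grna_id, tb$ibar, sep = "|"))
}

# exact-match rate of callable consensus genotypes against simulation truth
consensus_match_rate <- function(res) {
  keys <- truth_genotype_keys(res$screen)
  cons <- res$consensus[res$consensus$status != "uncallable" &
                          res$consensus$group_id %in% names(keys), ]
  called <- vapply(cons$variants, variant_key, character(1))
  list(rate = mean(called == keys[cons$group_id]), n = nrow(cons))
}
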
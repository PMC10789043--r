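# Configuration for the coupled scDNA + scRNA screen simulator.

#' Simulation configuration for a coupled genotyping + transcriptomics screen
#'
#' Builds and validates the configuration of the synthetic screen generator.
#' The defaults encode the experimental design the pipeline assumes: triploid
#' cells, per-allele dropout around 10%, clone barcode groups genotyped
#' across ~10 cells with transcriptomes measured across ~50 cells, and
#' barcode UMI counts arising from a three-component (one ambient, two
#' signal) skew-normal mixture on the log scale.
#'
#' @param n_barcodes number of clone barcodes (transduced parent cells).
#' @param frac_nt fraction of barcodes carrying non-targeting control gRNAs.
#' @param cells_per_barcode_dna,cells_per_barcode_rna mean cells per barcode
#'   in the DNA / RNA modality (zero-truncated Poisson).
#' @param ploidy copies of the genome per cell (default 3, the cell line is
#'   triploid); dosages never exceed it.
#' @param dropout_rate per-allele probability that an allele is missed during
#'   single-cell amplification (default 0.10).
#' @param het_noise_rate per cell, per eligible decoy site probability of a
#'   spurious heterozygous (dosage 1) call.
#' @param n_noise_sites number of shared decoy sites at which spurious
#'   heterozygous noise can appear.
#' @param recurrent_artifact_sites number of artifact sites planted across
#'   >10% of barcode groups (removed downstream by the recurrence filter).
#' @param artifact_barcode_frac fraction of barcode groups carrying each
#'   artifact site.
#' @param genotype_class_probs named probabilities over the realized edit
#'   classes `WT`, `het1`, `het2`, `hom` (dosage 0 / 1 / 2 / ploidy at every
#'   editable window position).
#' @param consequence_probs named probabilities over the functional class of
#'   each targeting gRNA's site: `stop_gained`, `splice`, `missense`,
#'   `synonymous`, `intron`, `promoter`.
#' @param missense_phenotype_probs named probabilities that a homozygous
#'   missense barcode is `notLoF` (benign), `SoF` (stochastic
#'   separation-of-function) or `LoF`.
#' @param sof_responder_prob per-cell probability that a SoF cell responds to
#'   stimulation (i.e. expresses the wild-type-like state).
#' @param n_genes,n_signature_genes total genes and response-signature genes.
#' @param lof_logfc natural-log fold changes of the signature genes in the
#'   LoF state (length `n_signature_genes`); default alternates
#'   `+log(3)` / `-log(3)`.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param ambient_mixture list with `pi`, `xi`, `omega`, `alpha` (length-3
#'   each; component 1 is ambient) describing log-scale barcode UMI counts.
#' @param p_ambient per foreign barcode probability that a cell receives
#'   ambient counts for it (Binomial subset of foreign barcodes).
#' @param doublet_rate fraction of cells carrying a second barcode's signal.
#' @param editing_window protospacer positions efficiently edited by the
#'   cytidine editor (default 4-8).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_barcodes = 250,
                       frac_nt = 0.10,
                       cells_per_barcode_dna = 10,
                       cells_per_barcode_rna = 50,
                       ploidy = 3,
                       dropout_rate = 0.10,
                       het_noise_rate = 0.02,
                       n_noise_sites = 10,
                       recurrent_artifact_sites = 3,
                       artifact_barcode_frac = 0.20,
                       genotype_class_probs = c(WT = 0.25, het1 = 0.20,
                                                het2 = 0.10, hom = 0.45),
                       consequence_probs = c(stop_gained = 0.10, splice = 0.10,
                                             missense = 0.40, synonymous = 0.15,
                                             intron = 0.15, promoter = 0.10),
                       missense_phenotype_probs = c(notLoF = 0.40, SoF = 0.20,
                                                    LoF = 0.40),
                       sof_responder_prob = 0.5,
                       n_genes = 2000,
                       n_signature_genes = 100,
                       lof_logfc = NULL,
                       nb_dispersion = 0.1,
                       ambient_mixture = list(pi = c(0.55, 0.27, 0.18),
                                              xi = c(1.25, 3.2, 4.6),
                                              omega = c(0.30, 0.45, 0.40),
                                              alpha = c(2, 0, -1)),
                       p_ambient = 0.02,
                       doublet_rate = 0,
                       editing_window = c(4L, 8L),
                       seed = 1L) {
  check_count(n_barcodes, "n_barcodes")
  check_prob(frac_nt, "frac_nt")
  check_pos(cells_per_barcode_dna, "cells_per_barcode_dna")
  check_pos(cells_per_barcode_rna, "cells_per_barcode_rna")
  check_count(ploidy, "ploidy", min = 1)
  check_prob(dropout_rate, "dropout_rate")
  check_prob(het_noise_rate, "het_noise_rate")
  check_count(n_noise_sites, "n_noise_sites", min = 0)
  check_count(recurrent_artifact_sites, "recurrent_artifact_sites", min = 0)
  check_prob(artifact_barcode_frac, "artifact_barcode_frac")
  check_prob(p_ambient, "p_ambient")
  check_prob(doublet_rate, "doublet_rate")
  check_prob(sof_responder_prob, "sof_responder_prob")
  check_count(n_genes, "n_genes")
  check_count(n_signature_genes, "n_signature_genes", min = 0)
  assert_that(n_signature_genes <= n_genes,
              "`n_signature_genes` must not exceed `n_genes`")
  check_pos(nb_dispersion, "nb_dispersion")
  for (nm in list(c("genotype_class_probs", "WT"),
                  c("consequence_probs", "stop_gained"),
                  c("missense_phenotype_probs", "notLoF"))) {
    p <- get(nm[1])
    check_prob(p, nm[1])
    assert_that(abs(sum(p) - 1) < 1e-8,
                paste0("`", nm[1], "` must sum to 1"))
  }
  am <- ambient_mixture
  assert_that(is.list(am) && all(c("pi", "xi", "omega", "alpha") %in% names(am)),
              "`ambient_mixture` needs pi, xi, omega, alpha")
  assert_that(length(am$pi) == 3 && length(am$xi) == 3 &&
                length(am$omega) == 3 && length(am$alpha) == 3,
              "`ambient_mixture` must have exactly 3 components")
  check_prob(am$pi, "ambient_mixture$pi")
  assert_that(abs(sum(am$pi) - 1) < 1e-8, "`ambient_mixture$pi` must sum to 1")
  check_pos(am$omega, "ambient_mixture$omega")
  assert_that(length(editing_window) == 2 && editing_window[1] >= 1 &&
                editing_window[2] >= editing_window[1] &&
                editing_window[2] <= 20,
              "`editing_window` must be positions within the 20-nt protospacer")
  if (is.null(lof_logfc)) {
    lof_logfc <- rep(c(log(4), -log(4)), length.out = n_signature_genes)
  }
  assert_that(length(lof_logfc) == n_signature_genes,
              "`lof_logfc` must have length n_signature_genes")
  check_count(seed, "seed", min = 0)

  structure(list(
    n_barcodes = as.integer(n_barcodes), frac_nt = frac_nt,
    cells_per_barcode_dna = cells_per_barcode_dna,
    cells_per_barcode_rna = cells_per_barcode_rna,
    ploidy = as.integer(ploidy), dropout_rate = dropout_rate,
    het_noise_rate = het_noise_rate, n_noise_sites = as.integer(n_noise_sites),
    recurrent_artifact_sites = as.integer(recurrent_artifact_sites),
    artifact_barcode_frac = artifact_barcode_frac,
    genotype_class_probs = genotype_class_probs,
    consequence_probs = consequence_probs,
    missense_phenotype_probs = missense_phenotype_probs,
    sof_responder_prob = sof_responder_prob,
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    lof_logfc = lof_logfc, nb_dispersion = nb_dispersion,
    ambient_mixture = am, p_ambient = p_ambient, doublet_rate = doublet_rate,
    editing_window = as.integer(editing_window), seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic screen config:", x$n_barcodes, "barcodes (",
      round(100 * x$frac_nt), "% NT ), ploidy", x$ploidy,
      ", dropout", x$dropout_rate, ", het noise", x$het_noise_rate, "\n")
  cat("  cells/barcode: DNA ~", x$cells_per_barcode_dna, ", RNA ~",
      x$cells_per_barcode_rna, "; genes:", x$n_genes, "(",
      x$n_signature_genes, "signature ); seed", x$seed, "\n")
  invisible(x)
}
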
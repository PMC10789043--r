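# Synthetic coupled scDNA + scRNA screen with known ground truth.

random_seq <- function(n, len, window = NULL, window_c_prob = 0.4) {
  vapply(seq_len(n), function(i) {
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (!is.null(window)) {
      wpos <- seq(window[1], window[2])
      b[wpos] <- ifelse(runif(length(wpos)) < window_c_prob, "C",
                        sample(c("A", "G", "T"), length(wpos), replace = TRUE))
    }
    paste(b, collapse = "")
  }, character(1))
}

# zero-truncated Poisson draws (cells per barcode can never be zero)
rtpois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) {
    z <- x == 0
    x[z] <- rpois(sum(z), lambda)
  }
  x
}

# genomic layout of the simulated target gene (JAK1-like coordinates, chr1)
sim_region <- function() {
  list(chrom = "chr1", body_start = 64834000L, site_spacing = 60L,
       promoter = c(64964978L, 64967543L),
       decoy_start = 64990000L, artifact_start = 64995000L)
}

#' Simulate the ground truth of a barcoded base-editor screen
#'
#' Draws the per-barcode truth: gRNA identity (a small fraction of targeting
#' gRNAs recur under independent barcodes, as happens when several transduced
#' cells receive the same guide), iBAR and puroR barcodes, target site with
#' strand and protospacer, the realized edit class (WT / het1 / het2 /
#' homozygous at every editable window cytosine), the functional consequence
#' of the site, and the phenotype class (notLoF / LoF / SoF). Also lays out
#' the shared decoy sites for spurious heterozygous noise and the recurrent
#' artifact sites.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth` with elements `barcodes` (tibble with a
#'   `variants` list-column), `annotation` (variant -> consequence table),
#'   `noise_sites`, `artifact_carriers`, `signature_genes`,
#'   `promoter_interval`, `editing_window`, `ploidy`.
#' @export
simulate_truth <- function(config) {
  assert_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  reg <- sim_region()
  withr::with_seed(config$seed, {
    n <- config$n_barcodes
    n_nt <- round(config$frac_nt * n)
    n_t <- n - n_nt
    targeting <- c(rep(TRUE, n_t), rep(FALSE, n_nt))

    # gRNA identities: ~8% of targeting barcodes reuse an existing guide
    n_unique <- max(1L, ceiling(0.92 * n_t))
    g_idx <- c(seq_len(n_unique),
               if (n_t > n_unique) sample.int(n_unique, n_t - n_unique,
                                              replace = TRUE))
    grna_id <- c(sprintf("gRNA-%04d", g_idx),
                 sprintf("NT-gRNA-%02d", seq_len(n_nt)))

    # per unique guide: site class, strand, protospacer, genomic position of
    # protospacer position 1 (promoter-class guides sit inside the promoter
    # interval, all others tile the gene body)
    cls <- sample(names(config$consequence_probs), n_unique, replace = TRUE,
                  prob = config$consequence_probs)
    strand <- sample(c("+", "-"), n_unique, replace = TRUE)
    proto <- random_seq(n_unique, 20, window = config$editing_window)
    pos1 <- integer(n_unique)
    is_prom <- cls == "promoter"
    pos1[!is_prom] <- reg$body_start +
      (seq_len(sum(!is_prom)) - 1L) * reg$site_spacing
    pos1[is_prom] <- reg$promoter[1] + 30L +
      (seq_len(sum(is_prom)) - 1L) * reg$site_spacing
    # keep minus-strand windows clear of neighbouring sites
    pos1[strand == "-"] <- pos1[strand == "-"] + 25L

    guide <- tibble(g_idx = seq_len(n_unique), site_class = cls,
                    strand = strand, protospacer = proto, site_pos = pos1)

    window_edits <- function(gi) {
      g <- guide[gi, ]
      wpos <- seq(config$editing_window[1], config$editing_window[2])
      bases <- strsplit(g$protospacer, "")[[1]][wpos]
      wpos <- wpos[bases == "C"]
      if (!length(wpos)) {
        return(tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
      }
      if (g$strand == "+") {
        tibble(chrom = reg$chrom, pos = g$site_pos + (wpos - 1L),
               ref = "C", alt = "T")
      } else {
        tibble(chrom = reg$chrom, pos = rev(g$site_pos - (wpos - 1L)),
               ref = "G", alt = "A")
      }
    }
    guide_edits <- map(seq_len(n_unique), window_edits)

    geno_class <- ifelse(targeting,
                         sample(names(config$genotype_class_probs), n,
                                replace = TRUE,
                                prob = config$genotype_class_probs),
                         "WT")
    dosage_of <- c(WT = 0L, het1 = 1L, het2 = 2L, hom = config$ploidy)

    barcodes <- tibble(
      barcode_id = sprintf("BC-%04d", seq_len(n)),
      grna_id = grna_id,
      ibar = paste0("iBAR-", random_seq(n, 6)),
      puror = paste0("puroR-", random_seq(n, 12)),
      targeting = targeting,
      g_idx = c(g_idx, rep(NA_integer_, n_nt)),
      genotype_class = geno_class)
    barcodes <- barcodes |>
      left_join(guide, by = "g_idx") |>
      mutate(variants = map2(.data$g_idx, .data$genotype_class, function(gi, gc) {
        if (is.na(gi) || gc == "WT") {
          return(tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        dosage = integer()))
        }
        mutate(guide_edits[[gi]], dosage = dosage_of[[gc]])
      }))

    # realized consequence: site class for homozygous edits, none for
    # heterozygous-only, WT otherwise
    barcodes <- barcodes |>
      mutate(
        edited = map_int(.data$variants, nrow) > 0,
        consequence_class = case_when(
          !.data$edited ~ "WT",
          .data$genotype_class %in% c("het1", "het2") ~ "none (heterozygous)",
          TRUE ~ .data$site_class),
        phenotype_class = case_when(
          .data$consequence_class %in% c("stop_gained", "splice") ~ "LoF",
          .data$consequence_class == "missense" ~ NA_character_,
          TRUE ~ "notLoF"))
    n_mis <- sum(is.na(barcodes$phenotype_class))
    barcodes$phenotype_class[is.na(barcodes$phenotype_class)] <-
      sample(names(config$missense_phenotype_probs), n_mis, replace = TRUE,
             prob = config$missense_phenotype_probs)

    # annotation covers every possible window edit except promoter-class
    # sites, whose consequence is derived from the promoter interval instead
    annotation <- guide |>
      filter(.data$site_class != "promoter") |>
      mutate(edits = guide_edits[.data$g_idx]) |>
      select("site_class", "edits") |>
      tidyr::unnest("edits") |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
               consequence = .data$site_class)

    # decoy sites for spurious het noise (a few carry disallowed
    # substitutions, exercising the edit-type filter) and recurrent artifacts
    noise_sites <- tibble(
      chrom = reg$chrom,
      pos = reg$decoy_start + seq_len(config$n_noise_sites) * 10L,
      ref = "C",
      alt = ifelse(seq_len(config$n_noise_sites) %% 4 == 0, "A", "T"),
      type = "decoy")
    if (config$recurrent_artifact_sites > 0) {
      art <- tibble(
        chrom = reg$chrom,
        pos = reg$artifact_start + seq_len(config$recurrent_artifact_sites) * 10L,
        ref = "C", alt = "T", type = "artifact")
      carriers <- tidyr::crossing(barcode_id = barcodes$barcode_id,
                                  pos = art$pos) |>
        filter(runif(n()) < config$artifact_barcode_frac) |>
        mutate(chrom = reg$chrom, ref = "C", alt = "T")
      noise_sites <- bind_rows(noise_sites, art)
    } else {
      carriers <- tibble(barcode_id = character(), pos = integer(),
                         chrom = character(), ref = character(),
                         alt = character())
    }

    sig <- tibble(gene = sprintf("gene%04d", seq_len(config$n_signature_genes)),
                  lof_logfc = config$lof_logfc)

    structure(list(barcodes = select(barcodes, -"g_idx", -"edited"),
                   annotation = annotation,
                   noise_sites = noise_sites,
                   artifact_carriers = carriers,
                   signature_genes = sig,
                   promoter_interval = list(chrom = reg$chrom,
                                            start = reg$promoter[1],
                                            end = reg$promoter[2]),
                   editing_window = config$editing_window,
                   ploidy = config$ploidy),
              class = "sim_truth")
  })
}

draw_cells <- function(truth, mean_cells, prefix, doublet_rate = 0,
                       responder_prob = NULL) {
  n_per <- rtpois(nrow(truth$barcodes), mean_cells)
  cells <- tibble(barcode_id = rep(truth$barcodes$barcode_id, n_per))
  cells$cell_id <- sprintf("%s_%05d", prefix, seq_len(nrow(cells)))
  cells$barcode_id2 <- NA_character_
  if (doublet_rate > 0) {
    dbl <- runif(nrow(cells)) < doublet_rate
    cells$barcode_id2[dbl] <- sample(truth$barcodes$barcode_id, sum(dbl),
                                     replace = TRUE)
  }
  if (!is.null(responder_prob)) {
    sof <- truth$barcodes$barcode_id[truth$barcodes$phenotype_class == "SoF"]
    cells$responder <- ifelse(cells$barcode_id %in% sof,
                              runif(nrow(cells)) < responder_prob, NA)
  }
  select(cells, "cell_id", everything())
}

#' Simulate per-cell genotype calls with allele dropout and spurious noise
#'
#' Each true variant allele is observed independently with probability
#' `1 - dropout_rate` (so an observed dosage is Binomial(true dosage,
#' 1 - dropout)); cells whose observed dosage falls to zero lose the row
#' entirely. Spurious heterozygous (dosage 1) calls are injected per cell and
#' per shared decoy site with probability `het_noise_rate`, and planted
#' recurrent artifact sites appear as heterozygous calls in their carrier
#' barcodes' cells.
#'
#' @param truth a `sim_truth`.
#' @param cells tibble with `cell_id`, `barcode_id` (one row per DNA cell).
#' @param dropout_rate,het_noise_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return tibble `cell_id, chrom, pos, ref, alt, dosage` (the per-cell
#'   variant table; 1-based genomic coordinates).
#' @export
simulate_cell_genotypes <- function(truth, cells, dropout_rate = 0.10,
                                    het_noise_rate = 0.02, seed = 1L) {
  check_prob(dropout_rate, "dropout_rate")
  check_prob(het_noise_rate, "het_noise_rate")
  assert_that(inherits(truth, "sim_truth") && nrow(truth$barcodes) > 0,
              "`truth` must be a non-empty sim_truth")
  withr::with_seed(seed, {
    real <- cells |>
      select("cell_id", "barcode_id") |>
      inner_join(select(truth$barcodes, "barcode_id", "variants"),
                 by = "barcode_id") |>
      tidyr::unnest("variants")
    if (nrow(real)) {
      real$dosage <- rbinom(nrow(real), real$dosage, 1 - dropout_rate)
      real <- filter(real, .data$dosage > 0)
    }
    art <- cells |>
      select("cell_id", "barcode_id") |>
      inner_join(truth$artifact_carriers, by = "barcode_id",
                 relationship = "many-to-many") |>
      filter(runif(n()) < 0.8) |>
      mutate(dosage = 1L)
    decoys <- filter(truth$noise_sites, .data$type == "decoy")
    spur <- tidyr::crossing(cell_id = cells$cell_id,
                            pos = decoys$pos) |>
      filter(runif(n()) < het_noise_rate) |>
      inner_join(select(decoys, "chrom", "pos", "ref", "alt"), by = "pos") |>
      mutate(dosage = 1L)
    bind_rows(select(real, "cell_id", "chrom", "pos", "ref", "alt", "dosage"),
              select(art, "cell_id", "chrom", "pos", "ref", "alt", "dosage"),
              select(spur, "cell_id", "chrom", "pos", "ref", "alt", "dosage")) |>
      arrange(.data$cell_id, .data$pos) |>
      as_tibble()
  })
}

draw_signal_counts <- function(n, mix) {
  w <- mix$pi[2:3]
  comp <- 1L + sample(2:3 - 1L, n, replace = TRUE, prob = w / sum(w))
  x <- rskewnorm(n, mix$xi[comp], mix$omega[comp], mix$alpha[comp])
  pmax(1, round(exp(x)))
}

#' Simulate barcode UMI count matrices (gRNA, iBAR, puroR classes)
#'
#' Each cell receives one high "signal" count for each of its own three
#' barcode features, drawn from the two signal components of the log-scale
#' skew-normal mixture, plus ambient counts (component 1) for a
#' Binomial(`n_barcodes`, `p_ambient`) subset of foreign features per class.
#' With ambient weight zero, no ambient counts are drawn at all.
#'
#' @param truth a `sim_truth`.
#' @param cells tibble of cells for one modality (`cell_id`, `barcode_id`,
#'   optionally `barcode_id2` for doublets).
#' @param ambient_mixture 3-component mixture parameter list (see
#'   [sim_config()]).
#' @param p_ambient per foreign barcode ambient inclusion probability.
#' @param seed integer seed.
#' @return list of class `barcode_counts`: sparse `counts` (cells x
#'   features) and `features` tibble (`feature_id`, `class`).
#' @export
simulate_barcode_counts <- function(truth, cells, ambient_mixture,
                                    p_ambient = 0.02, seed = 1L) {
  mix <- ambient_mixture
  assert_that(length(mix$pi) == 3, "ambient mixture must have 3 components")
  bc <- truth$barcodes
  features <- bind_rows(
    tibble(feature_id = unique(bc$grna_id), class = "gRNA"),
    tibble(feature_id = bc$ibar, class = "iBAR"),
    tibble(feature_id = bc$puror, class = "puroR"))
  fidx <- setNames(seq_len(nrow(features)), features$feature_id)
  bc_feats <- bc |> select("barcode_id", "grna_id", "ibar", "puror")

  withr::with_seed(seed, {
    own <- cells |>
      select("cell_id", "barcode_id") |>
      inner_join(bc_feats, by = "barcode_id") |>
      tidyr::pivot_longer(c("grna_id", "ibar", "puror"),
                          values_to = "feature_id") |>
      select("cell_id", "feature_id")
    if (any(!is.na(cells$barcode_id2))) {
      dbl <- cells |>
        filter(!is.na(.data$barcode_id2)) |>
        select("cell_id", barcode_id = "barcode_id2") |>
        inner_join(bc_feats, by = "barcode_id") |>
        tidyr::pivot_longer(c("grna_id", "ibar", "puror"),
                            values_to = "feature_id") |>
        select("cell_id", "feature_id")
      own <- bind_rows(own, dbl)
    }
    own$count <- draw_signal_counts(nrow(own), mix)

    amb <- NULL
    if (mix$pi[1] > 0 && p_ambient > 0) {
      n_cells <- nrow(cells)
      per_class <- lapply(c("gRNA", "iBAR", "puroR"), function(cl) {
        feats <- features$feature_id[features$class == cl]
        k <- rbinom(n_cells, nrow(bc), p_ambient)
        k <- pmin(k, length(feats))
        idx <- unlist(lapply(k, function(m) sample.int(length(feats), m)))
        tibble(cell_id = rep(cells$cell_id, k), feature_id = feats[idx])
      })
      amb <- bind_rows(per_class)
      amb$count <- pmax(1, round(exp(rskewnorm(nrow(amb), mix$xi[1],
                                               mix$omega[1], mix$alpha[1]))))
    }
    trip <- bind_rows(own, amb)
    m <- sparseMatrix(i = match(trip$cell_id, cells$cell_id),
                      j = fidx[trip$feature_id],
                      x = trip$count,
                      dims = c(nrow(cells), nrow(features)),
                      dimnames = list(cells$cell_id, features$feature_id))
    structure(list(counts = m, features = features), class = "barcode_counts")
  })
}

#' Simulate the gene expression matrix
#'
#' Genes follow a negative-binomial model with log-normal baseline means.
#' Cells in the LoF expression state (barcodes with a LoF phenotype, and the
#' non-responding cells of SoF barcodes) have the signature genes shifted by
#' the configured log fold changes; NT and WT/benign cells share the baseline
#' state.
#'
#' @param truth a `sim_truth`.
#' @param cells RNA cell tibble (`cell_id`, `barcode_id`, `responder`).
#' @param config the [sim_config()] (gene counts, effect sizes, dispersion).
#' @param seed integer seed.
#' @return sparse cells x genes count matrix (`dgCMatrix`).
#' @export
simulate_expression <- function(truth, cells, config, seed = 1L) {
  assert_that(length(config$lof_logfc) == config$n_signature_genes,
              "effect vector length must equal n_signature_genes")
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  pheno <- setNames(truth$barcodes$phenotype_class, truth$barcodes$barcode_id)
  state_lof <- pheno[cells$barcode_id] == "LoF" |
    (pheno[cells$barcode_id] == "SoF" & !cells$responder %in% TRUE)
  n_cells <- nrow(cells)
  size <- 1 / config$nb_dispersion

  withr::with_seed(seed, {
    mu0 <- numeric(config$n_genes)
    nsig <- config$n_signature_genes
    mu0[seq_len(nsig)] <- exp(rnorm(nsig, log(5), 0.3))
    if (config$n_genes > nsig) {
      mu0[(nsig + 1):config$n_genes] <-
        exp(rnorm(config$n_genes - nsig, log(0.3), 1))
    }
    lfc <- c(config$lof_logfc, rep(0, config$n_genes - nsig))
    ii <- vector("list", config$n_genes)
    jj <- vector("list", config$n_genes)
    xx <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      mu <- ifelse(state_lof, mu0[g] * exp(lfc[g]), mu0[g])
      cnt <- rnbinom(n_cells, mu = mu, size = size)
      nz <- which(cnt > 0)
      ii[[g]] <- nz; jj[[g]] <- rep.int(g, length(nz)); xx[[g]] <- cnt[nz]
    }
    sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                 dims = c(n_cells, config$n_genes),
                 dimnames = list(cells$cell_id, genes))
  })
}

#' Generate a complete coupled scDNA + scRNA synthetic screen
#'
#' Runs the whole generator: barcode-level truth, DNA and RNA cell rosters,
#' per-cell genotype calls with dropout and noise, barcode UMI count matrices
#' for both modalities, and the gene expression matrix. All randomness
#' derives from `config$seed`; the same config yields bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_screen` with elements `config`, `truth`
#'   (including the cell rosters), `variants` (per-cell variant table),
#'   `dna_barcode_counts`, `rna_barcode_counts` (each a `barcode_counts`)
#'   and `rna_gene_counts` (sparse cells x genes).
#' @export
generate_screen <- function(config = sim_config()) {
  assert_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  truth <- simulate_truth(config)
  truth$cells_dna <- withr::with_seed(config$seed + 1L,
    draw_cells(truth, config$cells_per_barcode_dna, "dna",
               doublet_rate = config$doublet_rate))
  truth$cells_rna <- withr::with_seed(config$seed + 2L,
    draw_cells(truth, config$cells_per_barcode_rna, "rna",
               doublet_rate = config$doublet_rate,
               responder_prob = config$sof_responder_prob))
  variants <- simulate_cell_genotypes(truth, truth$cells_dna,
                                      config$dropout_rate,
                                      config$het_noise_rate,
                                      seed = config$seed + 3L)
  dna_bc <- simulate_barcode_counts(truth, truth$cells_dna,
                                    config$ambient_mixture, config$p_ambient,
                                    seed = config$seed + 4L)
  rna_bc <- simulate_barcode_counts(truth, truth$cells_rna,
                                    config$ambient_mixture, config$p_ambient,
                                    seed = config$seed + 5L)
  expr <- simulate_expression(truth, truth$cells_rna, config,
                              seed = config$seed + 6L)
  structure(list(config = config, truth = truth, variants = variants,
                 dna_barcode_counts = dna_bc, rna_barcode_counts = rna_bc,
                 rna_gene_counts = expr),
            class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("Synthetic screen:", nrow(x$truth$barcodes), "barcodes,",
      nrow(x$truth$cells_dna), "DNA cells,", nrow(x$truth$cells_rna),
      "RNA cells,", ncol(x$rna_gene_counts), "genes\n")
  invisible(x)
}
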
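# Readers and writers: MatrixMarket count matrices with feature-class
# sidecars, per-cell variant tables (TSV), and a per-group consensus VCF.
# Coordinates are 1-based inclusive genomic positions throughout (VCF
# convention); TSV is tab-separated with a header row and no quoting.

#' Write a count matrix as a MatrixMarket triplet directory
#'
#' Writes `matrix.mtx` (cells x features, integer coordinate format),
#' `features.tsv` (`feature_id`, `class`) and `barcodes.tsv` (cell ids).
#'
#' @param counts sparse cells x features matrix, or a `barcode_counts`
#'   object.
#' @param dir output directory (created if missing).
#' @param features optional features tibble (`feature_id, class`); derived
#'   from colnames with class `"gene"` when absent.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir, features = NULL) {
  if (inherits(counts, "barcode_counts")) {
    features <- counts$features
    counts <- counts$counts
  }
  if (is.null(features)) {
    features <- tibble(feature_id = colnames(counts), class = "gene")
  }
  assert_that(nrow(features) == ncol(counts),
              "features table must match the matrix columns")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(features, file.path(dir, "features.tsv"))
  readr::write_tsv(tibble(cell_id = rownames(counts)),
                   file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix from a MatrixMarket triplet directory
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` as written by [write_count_matrix()].
#' @return list of class `barcode_counts`: sparse `counts` (cells x
#'   features, with dimnames) and the `features` tibble.
#' @export
read_count_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0,
              paste0("missing file(s): ", paste(missing, collapse = ", ")))
  m <- tryCatch(Matrix::readMM(paths[1]), error = function(e) {
    abort(paste0("malformed MatrixMarket file ", paths[1], ": ",
                 conditionMessage(e)))
  })
  m <- methods::as(m, "CsparseMatrix")
  features <- readr::read_tsv(paths[2], show_col_types = FALSE)
  barcodes <- readr::read_tsv(paths[3], show_col_types = FALSE)
  assert_that("feature_id" %in% names(features),
              "features.tsv needs a feature_id column")
  if (nrow(features) != ncol(m) || nrow(barcodes) != nrow(m)) {
    abort(paste0("dimension mismatch between matrix.mtx (", nrow(m), " x ",
                 ncol(m), ") and barcodes.tsv (", nrow(barcodes),
                 ") / features.tsv (", nrow(features), ")"))
  }
  dimnames(m) <- list(barcodes[[1]], features$feature_id)
  if (!"class" %in% names(features)) features$class <- "gene"
  structure(list(counts = m, features = features), class = "barcode_counts")
}

#' Read a per-cell variant table
#'
#' Expects a TSV with columns `cell_id, chrom, pos, ref, alt, dosage`.
#' Rows failing validation (position < 1, non-ACGT or equal ref/alt, dosage
#' outside `0..ploidy`) are rejected with their row numbers; more than
#' `max_reject_frac` rejected rows is a hard error.
#'
#' @param path TSV file path.
#' @param ploidy dosage upper bound (default 3).
#' @param max_reject_frac tolerated fraction of invalid rows (default 0.01).
#' @return validated tibble (1-based coordinates preserved).
#' @export
read_variant_table <- function(path, ploidy = 3, max_reject_frac = 0.01) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         cell_id = "c", chrom = "c", pos = "i",
                         ref = "c", alt = "c", dosage = "i"))
  need <- c("cell_id", "chrom", "pos", "ref", "alt", "dosage")
  assert_that(all(need %in% names(d)),
              paste0("variant table needs columns: ",
                     paste(need, collapse = ", ")))
  ok_base <- function(b) b %in% c("A", "C", "G", "T")
  bad <- is.na(d$pos) | d$pos < 1 | !ok_base(d$ref) | !ok_base(d$alt) |
    d$ref == d$alt | is.na(d$dosage) | d$dosage < 0 | d$dosage > ploidy
  if (any(bad)) {
    warn(paste0("rejected ", sum(bad), " invalid row(s): ",
                paste(head(which(bad), 10), collapse = ", ")))
    if (mean(bad) > max_reject_frac) {
      abort(paste0(round(100 * mean(bad), 1), "% of rows invalid (> ",
                   100 * max_reject_frac, "%); refusing to continue"))
    }
  }
  d[!bad, ]
}

#' Write a per-cell variant table
#'
#' @param variants tibble `cell_id, chrom, pos, ref, alt, dosage`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants[order(variants$cell_id, variants$pos), ], path)
  invisible(path)
}

#' Write consensus genotypes as a VCF with one sample per barcode group
#'
#' Emits VCF 4.2 with a genotype (`GT`) and an allele-dosage (`DS`) FORMAT
#' field; the header documents the ploidy. Positions are sorted on write.
#'
#' @param consensus output of [call_consensus()] (uncallable groups are
#'   skipped).
#' @param path output file path.
#' @param ploidy copies of the genome (documented in the header and used
#'   for the GT field).
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path, ploidy = 3) {
  callable <- filter(consensus, .data$status != "uncallable")
  assert_that(nrow(callable) > 0, "no callable consensus genotypes to write")
  samples <- callable$group_id
  sites <- callable |>
    select("group_id", "variants") |>
    tidyr::unnest("variants")
  sites_u <- sites |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$chrom, .data$pos, .data$alt)
  gt_of <- function(ds) {
    paste(c(rep("1", ds), rep("0", ploidy - ds)), collapse = "/")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=snvscreen ",
           as.character(utils::packageVersion("snvscreen"))),
    paste0("##ploidy=", ploidy),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Integer,Description=",
           "\"Number of edited alleles (0-", ploidy, ")\">"),
    paste0("##contig=<ID=", unique(sites_u$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites_u)), function(i) {
    s <- sites_u[i, ]
    ds <- setNames(rep(0L, length(samples)), samples)
    hit <- sites |>
      filter(.data$chrom == s$chrom, .data$pos == s$pos, .data$alt == s$alt)
    ds[hit$group_id] <- hit$dosage
    cols <- paste0(vapply(ds, gt_of, character(1)), ":", ds)
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT:DS",
            cols), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a whole synthetic screen to disk
#'
#' Writes the three count-matrix directories, the per-cell variant table,
#' the barcode-level truth tables and a config echo, mirroring the on-disk
#' layout the readers expect.
#'
#' @param screen a `sim_screen` from [generate_screen()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(screen$rna_gene_counts,
                     file.path(dir, "rna_genes"))
  write_count_matrix(screen$rna_barcode_counts, file.path(dir, "rna_barcodes"))
  write_count_matrix(screen$dna_barcode_counts, file.path(dir, "dna_barcodes"))
  write_variant_table(screen$variants, file.path(dir, "cell_variants.tsv"))
  truth_flat <- screen$truth$barcodes |>
    mutate(variants = map_chr(.data$variants, function(v) {
      paste(sprintf("%s:%d%s>%s(%d)", v$chrom, v$pos, v$ref, v$alt, v$dosage),
            collapse = ";")
    }))
  readr::write_tsv(truth_flat, file.path(dir, "truth_barcodes.tsv"))
  readr::write_tsv(screen$truth$cells_dna, file.path(dir, "truth_cells_dna.tsv"))
  readr::write_tsv(screen$truth$cells_rna, file.path(dir, "truth_cells_rna.tsv"))
  cfg <- screen$config
  cfg_lines <- vapply(names(cfg), function(nm) {
    paste0(nm, "\t", paste(format(unlist(cfg[[nm]]), digits = 10),
                           collapse = ","))
  }, character(1))
  writeLines(c(paste0("# snvscreen ",
                      as.character(utils::packageVersion("snvscreen")),
                      " config echo, seed ", cfg$seed),
               cfg_lines), file.path(dir, "config_echo.tsv"))
  invisible(dir)
}
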
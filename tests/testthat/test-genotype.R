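mk_co <- function(...) {
  d <- tibble::tribble(...)
  d$unique_grna_ibar <- !is.na(d$grna) & !is.na(d$ibar)
  d$unique_puror <- !is.na(d$puror)
  d$both <- d$unique_grna_ibar & d$unique_puror
  d
}

test_that("puroR mapping requires a unique pairing seen in at least 2 cells", {
  co <- mk_co(
    ~cell_id, ~grna, ~ibar, ~puror,
    "c1", "g1", "i1", "P1",
    "c2", "g1", "i1", "P1",
    "c3", "g1", "i1", "P1",
    "c4", "g1", "i1", "P1",
    "c5", "g1", "i1", "P1",
    "c6", "g1", "i1", "P2",
    "c7", "g1", "i1", "P3",
    "c8", "g2", "i2", "P3")
  m <- map_puror_to_grna_ibar(co)
  expect_true(m$mapped[m$puror == "P1"])
  expect_false(m$mapped[m$puror == "P2"])          # single supporting cell
  expect_true(all(!m$mapped[m$puror == "P3"]))     # two different pairs
})

test_that("barcode groups pool cells over shared keys via the mapping", {
  co <- mk_co(
    ~cell_id, ~grna, ~ibar, ~puror,
    "c1", "g1", "i1", "P1",
    "c2", "g1", "i1", "P1",
    "c3", "g1", "i1", "P1",
    "c4", "g1", "i1", "P1",
    "c5", "g1", "i1", NA,
    "c6", "g1", "i1", NA,
    "c7", NA,   NA,   "P1",
    "c8", "g2", "i2", "P9")   # P9 maps elsewhere: conflicting keys
  # mapping as derived on a genotyping dataset: P1 -> (g1, i1), P9 -> (g3, i3)
  mapping <- tibble::tibble(puror = c("P1", "P9"),
                            grna = c("g1", "g3"), ibar = c("i1", "i3"),
                            n_cells = c(4L, 5L), mapped = TRUE)
  grp <- form_barcode_groups(co, mapping)
  g1 <- grp$membership$cell_id[grp$membership$group_id == "g1|i1"]
  expect_setequal(g1, paste0("c", 1:7))
  expect_identical(grp$excluded$cell_id, "c8")
  empty <- form_barcode_groups(co[0, ], mapping)
  expect_identical(nrow(empty$groups), 0L)
})

test_that("edit-type filtering keeps only allowed substitutions", {
  v <- tibble::tibble(cell_id = "c1", chrom = "chr1", pos = 1:5,
                      ref = c("C", "C", "G", "T", "C"),
                      alt = c("T", "A", "A", "T", "G"))
  expect_warning(out <- filter_edit_types(v), "malformed")
  expect_identical(out$pos, c(1L, 3L))
  # randomized table equals a set-membership oracle
  withr::with_seed(8, {
    vr <- tibble::tibble(cell_id = "c", chrom = "chr1", pos = 1:200,
                         ref = sample(c("A", "C", "G", "T"), 200, TRUE),
                         alt = sample(c("A", "C", "G", "T"), 200, TRUE))
  })
  vr <- vr[vr$ref != vr$alt, ]
  keep <- paste0(vr$ref, ">", vr$alt) %in% c("C>T", "G>A")
  expect_identical(filter_edit_types(vr)$pos, vr$pos[keep])
})

test_that("recurrence filtering is strict at the 10% boundary", {
  n_groups <- 233
  membership <- tibble::tibble(cell_id = sprintf("c%03d", 1:n_groups),
                               group_id = sprintf("G%03d", 1:n_groups))
  mk_var <- function(pos, n) {
    tibble::tibble(cell_id = sprintf("c%03d", 1:n), chrom = "chr1", pos = pos,
                   ref = "C", alt = "T", dosage = 1L)
  }
  v <- rbind(mk_var(100L, 30),                 # 30/233 = 12.9% -> removed
             mk_var(200L, 5),                  # kept
             mk_var(300L, floor(0.10 * 233)))  # exactly 10% (23) -> kept
  out <- remove_recurrent_artifacts(v, membership, 0.10)
  expect_setequal(unique(out$pos), c(200L, 300L))
  expect_identical(attr(out, "removed")$pos, 100L)
  expect_error(remove_recurrent_artifacts(v, membership[0, ], 0.10),
               "no barcode groups")
})

mk_groups <- function(cells, gid = "g1|i1") {
  list(membership = tibble::tibble(cell_id = cells, group_id = gid),
       groups = tibble::tibble(group_id = gid, grna = "g1", ibar = "i1",
                               puror = NA_character_, size = length(cells)))
}

vrows <- function(cells, pos = 500L, dosage = 3L) {
  tibble::tibble(cell_id = cells, chrom = "chr1", pos = pos, ref = "C",
                 alt = "T", dosage = dosage)
}

test_that("consensus calling follows the majority and wild-type rules", {
  p <- consensus_params()
  # 3 of 5 cells carry dosage 3 -> edited, homozygous
  g <- mk_groups(sprintf("c%d", 1:5))
  out <- call_consensus(g, vrows(c("c1", "c2", "c3")), p)
  expect_identical(out$status, "edited")
  expect_identical(out$variants[[1]]$dosage, 3L)
  expect_identical(out$zygosity, "homozygous")
  # 2 of 5 cells (40% < 50%) -> below group fraction, and 2 > 1 mutated
  # cells means not WT either -> uncallable
  out <- call_consensus(g, vrows(c("c1", "c2")), p)
  expect_identical(out$status, "uncallable")
  # 12-cell group tolerates a single mutated cell -> WT
  g12 <- mk_groups(sprintf("c%02d", 1:12))
  out <- call_consensus(g12, vrows("c01"), p)
  expect_identical(out$status, "WT")
  # small group tolerates none
  g4 <- mk_groups(sprintf("c%d", 1:4))
  out <- call_consensus(g4, vrows("c1"), p)
  expect_identical(out$status, "uncallable")
  # no mutations at all -> WT
  out <- call_consensus(g4, vrows(character(0)), p)
  expect_identical(out$status, "WT")
  # dosage tie among carriers -> uncallable
  out <- call_consensus(g4, vrows(c("c1", "c2", "c3", "c4"),
                                  dosage = c(1L, 1L, 3L, 3L)), p)
  expect_identical(out$status, "uncallable")
  # below minimum group size -> never genotyped
  g2 <- mk_groups(c("c1", "c2"))
  out <- call_consensus(g2, vrows(c("c1", "c2")), p)
  expect_identical(out$status, "uncallable")
  expect_identical(out$reason, "too_few_cells")
})

test_that("consensus equals the brute-force rule implementation on random groups", {
  p <- consensus_params()
  withr::with_seed(19, {
    for (rep in seq_len(300)) {
      n <- sample(3:8, 1)
      cells <- sprintf("c%02d", seq_len(n))
      v <- random_group_variants(n)
      got <- call_consensus(mk_groups(cells), v, p)
      want <- brute_consensus(cells, v, n, p)
      expect_identical(got$status, want$status)
      if (got$status == "edited") {
        expect_equal(as.data.frame(got$variants[[1]]),
                     as.data.frame(want$variants))
      }
    }
  })
})

test_that("consensus is invariant to cell and variant order", {
  p <- consensus_params()
  withr::with_seed(23, {
    n <- 6
    cells <- sprintf("c%02d", 1:n)
    v <- random_group_variants(n)
    base <- call_consensus(mk_groups(cells), v, p)
    perm <- call_consensus(mk_groups(rev(cells)), v[sample(nrow(v)), ], p)
  })
  expect_identical(base$status, perm$status)
  expect_identical(base$variants[[1]], perm$variants[[1]])
})

ann_fixture <- tibble::tibble(
  chrom = "chr1", pos = c(500L, 600L, 700L),
  ref = "C", alt = "T",
  consequence = c("synonymous", "stop_gained", "missense"))
prom <- list(chrom = "chr1", start = 64964978L, end = 64967543L)

test_that("consequence assignment ranks severity over homozygous edits only", {
  cons <- tibble::tibble(
    group_id = c("a", "b", "c"), status = c("edited", "edited", "edited"),
    variants = list(
      tibble::tibble(chrom = "chr1", pos = c(500L, 600L), ref = "C",
                     alt = "T", dosage = c(3L, 3L)),
      tibble::tibble(chrom = "chr1", pos = 64965500L, ref = "C", alt = "T",
                     dosage = 3L),
      tibble::tibble(chrom = "chr1", pos = 700L, ref = "C", alt = "T",
                     dosage = 1L)))
  out <- assign_consequence(cons, ann_fixture, prom)
  expect_identical(out$consequence,
                   c("stop_gained", "promoter", "none (heterozygous)"))
  bad <- cons[1, ]
  bad$variants <- list(tibble::tibble(chrom = "chr1", pos = 999L, ref = "C",
                                      alt = "T", dosage = 3L))
  expect_error(assign_consequence(bad, ann_fixture, prom), "chr1 999")
})

test_that("predicted genotypes edit every window cytosine homozygously", {
  guides <- tibble::tibble(
    grna_id = c("g+", "g-", "gNoC", "gNT"),
    protospacer = c("AAACACAAAAAAAAAAAAAA",  # C at positions 4 and 6
                    "AAACACAAAAAAAAAAAAAA",
                    "AAATATAAAAAAAAAAAAAA",
                    NA),
    strand = c("+", "-", "+", NA),
    chrom = "chr1", site_pos = c(1000L, 1000L, 1000L, NA),
    targeting = c(TRUE, TRUE, TRUE, FALSE))
  out <- predict_genotype_from_grna(guides)
  plus <- out$predicted[[1]]
  expect_identical(plus$pos, c(1003L, 1005L))
  expect_identical(plus$ref, c("C", "C"))
  expect_identical(plus$alt, c("T", "T"))
  expect_true(all(plus$dosage == 3L))
  minus <- out$predicted[[2]]
  expect_identical(minus$pos, c(995L, 997L))
  expect_true(all(minus$ref == "G" & minus$alt == "A"))
  expect_identical(nrow(out$predicted[[3]]), 0L)
  expect_true(out$non_targeting[4])
  expect_identical(nrow(out$predicted[[4]]), 0L)
  expect_error(predict_genotype_from_grna(guides, window = c(4, 25)),
               "window")
})

test_that("prediction comparison reports concordance and discordance reasons", {
  pred <- tibble::tibble(
    grna_id = c("g1", "g2", "g3"),
    non_targeting = FALSE,
    predicted = list(
      tibble::tibble(chrom = "chr1", pos = 600L, ref = "C", alt = "T",
                     dosage = 3L),
      tibble::tibble(chrom = "chr1", pos = 600L, ref = "C", alt = "T",
                     dosage = 3L),
      tibble::tibble(chrom = "chr1", pos = 700L, ref = "C", alt = "T",
                     dosage = 3L)))
  called <- tibble::tibble(
    grna_id = c("g1", "g2", "g3"),
    status = c("edited", "edited", "WT"),
    variants = list(
      tibble::tibble(chrom = "chr1", pos = 600L, ref = "C", alt = "T",
                     dosage = 3L),
      tibble::tibble(chrom = "chr1", pos = 600L, ref = "C", alt = "T",
                     dosage = 1L),
      tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), dosage = integer())))
  out <- compare_to_prediction(called, pred, ann_fixture, prom)
  expect_identical(out$nucleotide_match, c(TRUE, FALSE, FALSE))
  expect_identical(out$protein_match, c(TRUE, FALSE, FALSE))
  expect_identical(out$reason, c(NA, "heterozygous", "unedited"))
})

test_that("statuses partition all groups of sufficient size", {
  scr <- small_screen()
  co <- tibble::tibble(
    cell_id = scr$truth$cells_dna$cell_id,
    grna = scr$truth$barcodes$grna_id[
      match(scr$truth$cells_dna$barcode_id, scr$truth$barcodes$barcode_id)],
    ibar = scr$truth$barcodes$ibar[
      match(scr$truth$cells_dna$barcode_id, scr$truth$barcodes$barcode_id)],
    puror = NA_character_) |>
    dplyr::mutate(unique_grna_ibar = TRUE, unique_puror = FALSE, both = FALSE)
  grp <- form_barcode_groups(co, map_puror_to_grna_ibar(co))
  v <- filter_edit_types(scr$variants)
  v <- remove_recurrent_artifacts(v, grp$membership)
  out <- call_consensus(grp, v)
  expect_true(all(out$status %in% c("WT", "edited", "uncallable")))
  expect_identical(sum(out$status == "WT") + sum(out$status == "edited") +
                     sum(out$status == "uncallable"), nrow(out))
})
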
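# Barcode groups and consensus genotype calling.
#
# Daughter cells of one transduced parent share a clone barcode; genotyping
# single cells is noisy (allele dropout, spurious heterozygous calls), so
# genotypes are called per barcode group under majority rules.

#' Consensus genotyping parameters
#'
#' @param min_cells_variant a variant must be carried by at least this many
#'   cells of a group to be callable (default 2).
#' @param min_fraction ... and by at least this fraction of the group's cells
#'   (default 0.5).
#' @param wt_max_mutated_cells a group is wild-type when no position is
#'   mutated in more than this many cells (default 1)...
#' @param small_group_cutoff ...unless the group has fewer cells than this,
#'   in which case zero mutated cells are tolerated (default 10).
#' @param min_group_size groups below this size are never genotyped
#'   (default 3).
#' @param recurrence_fraction variants present in strictly more than this
#'   fraction of barcode groups are treated as artifacts (default 0.10).
#' @param allowed_substitutions base-editor substitution classes kept by the
#'   edit-type filter, on the genomic forward strand (default `C>T` and
#'   `G>A`, i.e. a cytosine edit on either strand).
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(min_cells_variant = 2, min_fraction = 0.5,
                             wt_max_mutated_cells = 1, small_group_cutoff = 10,
                             min_group_size = 3, recurrence_fraction = 0.10,
                             allowed_substitutions = c("C>T", "G>A")) {
  check_count(min_cells_variant, "min_cells_variant", min = 1)
  check_prob(min_fraction, "min_fraction")
  check_count(wt_max_mutated_cells, "wt_max_mutated_cells", min = 0)
  check_count(small_group_cutoff, "small_group_cutoff", min = 1)
  check_count(min_group_size, "min_group_size", min = 1)
  check_prob(recurrence_fraction, "recurrence_fraction")
  structure(list(min_cells_variant = min_cells_variant,
                 min_fraction = min_fraction,
                 wt_max_mutated_cells = wt_max_mutated_cells,
                 small_group_cutoff = small_group_cutoff,
                 min_group_size = min_group_size,
                 recurrence_fraction = recurrence_fraction,
                 allowed_substitutions = allowed_substitutions),
            class = "consensus_params")
}

#' Map puroR barcodes to gRNA + iBAR combinations
#'
#' A puroR barcode is mapped to a gRNA + iBAR pair iff, across cells carrying
#' both, it only ever co-occurs with that single pair and the pairing is
#' observed in at least `min_cells` cells.
#'
#' @param co_assignments output of [co_assign()] on the DNA modality.
#' @param min_cells minimum supporting cells (default 2).
#' @return tibble `puror, grna, ibar, n_cells, mapped`; unmappable puroRs are
#'   retained with `mapped = FALSE`.
#' @export
map_puror_to_grna_ibar <- function(co_assignments, min_cells = 2) {
  pairs <- co_assignments |>
    filter(.data$both) |>
    count(.data$puror, .data$grna, .data$ibar, name = "n_cells")
  pairs |>
    group_by(.data$puror) |>
    mutate(mapped = n() == 1 & .data$n_cells >= min_cells) |>
    ungroup() |>
    arrange(.data$puror)
}

#' Form barcode groups of daughter cells
#'
#' Cells with both a gRNA + iBAR combination and a puroR are grouped by the
#' combination; cells with only one of the two keys join the group implied by
#' that key (using the puroR mapping when only the puroR was called). Cells
#' whose two keys disagree with the mapping are excluded and reported.
#'
#' @param co_assignments output of [co_assign()].
#' @param mapping output of [map_puror_to_grna_ibar()].
#' @return list with `membership` (tibble `cell_id, group_id`), `groups`
#'   (tibble `group_id, grna, ibar, puror, size`), and `excluded`
#'   (conflicting cells).
#' @export
form_barcode_groups <- function(co_assignments, mapping) {
  if (nrow(co_assignments) == 0) {
    return(list(membership = tibble(cell_id = character(),
                                    group_id = character()),
                groups = tibble(group_id = character(), grna = character(),
                                ibar = character(), puror = character(),
                                size = integer()),
                excluded = tibble(cell_id = character(), grna = character(),
                                  ibar = character(), puror = character())))
  }
  pmap_tbl <- mapping |> filter(.data$mapped) |>
    select("puror", map_grna = "grna", map_ibar = "ibar")
  d <- co_assignments |>
    left_join(pmap_tbl, by = "puror") |>
    mutate(
      gi_key = ifelse(.data$unique_grna_ibar,
                      paste(.data$grna, .data$ibar, sep = "|"),
                      NA_character_),
      mapped_key = ifelse(!is.na(.data$map_grna),
                          paste(.data$map_grna, .data$map_ibar, sep = "|"),
                          NA_character_),
      conflict = !is.na(.data$gi_key) & !is.na(.data$mapped_key) &
        .data$gi_key != .data$mapped_key,
      group_id = case_when(
        .data$conflict ~ NA_character_,
        !is.na(.data$gi_key) ~ .data$gi_key,
        !is.na(.data$mapped_key) ~ .data$mapped_key,
        !is.na(.data$puror) ~ paste0("puroR-only|", .data$puror),
        TRUE ~ NA_character_))
  membership <- d |>
    filter(!is.na(.data$group_id)) |>
    select("cell_id", "group_id")
  groups <- d |>
    filter(!is.na(.data$group_id)) |>
    group_by(.data$group_id) |>
    summarise(
      grna = first(sort(unique(stats::na.omit(.data$grna)))) %|na|% NA_character_,
      ibar = first(sort(unique(stats::na.omit(.data$ibar)))) %|na|% NA_character_,
      puror = first(sort(unique(stats::na.omit(.data$puror)))) %|na|% NA_character_,
      size = n(), .groups = "drop") |>
    arrange(.data$group_id)
  list(membership = membership, groups = groups,
       excluded = filter(d, .data$conflict) |> select("cell_id", "grna",
                                                      "ibar", "puror"))
}

`%|na|%` <- function(x, y) if (length(x) == 0 || all(is.na(x))) y else x

#' Filter per-cell variants to base-editor substitution classes
#'
#' Keeps only rows whose `ref>alt` substitution is in the allowed set
#' (genomic forward strand). Malformed rows (non-ACGT bases or `ref == alt`)
#' are dropped with a warning.
#'
#' @param variants per-cell variant tibble
#'   (`cell_id, chrom, pos, ref, alt, dosage`).
#' @param allowed character vector of `"R>A"` substitution codes.
#' @return filtered tibble.
#' @export
filter_edit_types <- function(variants, allowed = c("C>T", "G>A")) {
  ok_base <- function(b) b %in% c("A", "C", "G", "T")
  bad <- !ok_base(variants$ref) | !ok_base(variants$alt) |
    variants$ref == variants$alt
  if (any(bad)) {
    warn(paste0(sum(bad), " malformed variant row(s) (non-ACGT or ref == alt)",
                " rejected"))
  }
  variants |>
    filter(!bad, paste0(.data$ref, ">", .data$alt) %in% allowed)
}

#' Remove recurrent artifact variants
#'
#' A variant observed (in any cell) in strictly more than
#' `recurrence_fraction` of all barcode groups is assumed not to be caused by
#' the gRNAs and removed.
#'
#' @param variants per-cell variant tibble.
#' @param membership tibble `cell_id, group_id` from [form_barcode_groups()].
#' @param recurrence_fraction strict incidence threshold (default 0.10).
#' @return filtered variant tibble; removed variants are attached as the
#'   `"removed"` attribute.
#' @export
remove_recurrent_artifacts <- function(variants, membership,
                                       recurrence_fraction = 0.10) {
  n_groups <- n_distinct(membership$group_id)
  if (n_groups == 0) abort("no barcode groups: cannot compute recurrence")
  incidence <- variants |>
    inner_join(membership, by = "cell_id") |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$group_id) |>
    count(.data$chrom, .data$pos, .data$ref, .data$alt, name = "n_groups_with")
  removed <- incidence |>
    filter(.data$n_groups_with > recurrence_fraction * n_groups)
  out <- variants |>
    anti_join(removed, by = c("chrom", "pos", "ref", "alt"))
  attr(out, "removed") <- removed
  out
}

# consensus for the cells of one group; returns list(status, variants, reason)
consensus_one_group <- function(vars, n, params) {
  wt_tol <- if (n < params$small_group_cutoff) 0 else params$wt_max_mutated_cells
  if (nrow(vars) == 0) {
    return(list(status = "WT", variants = empty_variants(), reason = NA_character_))
  }
  per_site <- vars |>
    filter(.data$dosage > 0) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(m = n_distinct(.data$cell_id),
              dosages = list(.data$dosage), .groups = "drop")
  if (nrow(per_site) == 0) {
    return(list(status = "WT", variants = empty_variants(), reason = NA_character_))
  }
  called <- per_site |>
    filter(.data$m >= params$min_cells_variant,
           .data$m >= params$min_fraction * n)
  ambiguous_support <- per_site |>
    filter(.data$m >= params$min_cells_variant,
           .data$m < params$min_fraction * n)
  if (nrow(ambiguous_support) > 0) {
    return(list(status = "uncallable", variants = empty_variants(),
                reason = "variant_below_group_fraction"))
  }
  if (nrow(called) > 0) {
    maj <- map_int(called$dosages, function(d) {
      tab <- table(d)
      top <- which(tab == max(tab))
      if (length(top) > 1 || max(tab) * 2 <= length(d)) NA_integer_
      else as.integer(names(tab)[top])
    })
    if (any(is.na(maj))) {
      return(list(status = "uncallable", variants = empty_variants(),
                  reason = "no_dosage_majority"))
    }
    out <- called |>
      mutate(dosage = maj) |>
      select("chrom", "pos", "ref", "alt", "dosage") |>
      arrange(.data$pos)
    return(list(status = "edited", variants = out, reason = NA_character_))
  }
  # only singleton (m == 1) positions remain
  if (max(per_site$m) <= wt_tol) {
    list(status = "WT", variants = empty_variants(), reason = NA_character_)
  } else {
    list(status = "uncallable", variants = empty_variants(),
         reason = "scattered_mutations")
  }
}

empty_variants <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), dosage = integer())
}

zygosity_of <- function(vars, ploidy) {
  if (nrow(vars) == 0) return(NA_character_)
  d <- unique(vars$dosage)
  if (length(d) > 1) return("mixed")
  if (d == ploidy) "homozygous" else if (d == 1) "het1"
  else if (d == 2) "het2" else "mixed"
}

#' Call consensus genotypes for barcode groups
#'
#' For each group with at least `min_group_size` cells, a variant is called
#' when it is present on at least one allele in at least `min_cells_variant`
#' cells comprising at least `min_fraction` of the group, at the dosage
#' shared by a strict majority of its carrier cells. A group is wild-type
#' when no position is mutated in more than `wt_max_mutated_cells` cells
#' (zero for groups below `small_group_cutoff`). Groups with a variant
#' supported by >= 2 cells but < 50% of the group, or without a strict dosage
#' majority, are uncallable.
#'
#' @param groups output of [form_barcode_groups()] (list with `membership`
#'   and `groups`).
#' @param variants per-cell variant tibble, already passed through
#'   [filter_edit_types()] and [remove_recurrent_artifacts()].
#' @param params a [consensus_params()].
#' @param ploidy copies of the genome (bounds dosages; default 3).
#' @return tibble, one row per group: `group_id, grna, ibar, puror, n_cells,
#'   status` (`WT | edited | uncallable`), `variants` (list-column of called
#'   variants), `zygosity`, `reason`.
#' @export
call_consensus <- function(groups, variants, params = consensus_params(),
                           ploidy = 3) {
  assert_that(inherits(params, "consensus_params"),
              "`params` must come from consensus_params()")
  bad_dosage <- variants$dosage > ploidy | variants$dosage < 0
  assert_that(!any(bad_dosage), "variant dosages must lie in [0, ploidy]")
  by_cell <- split(seq_len(nrow(variants)), variants$cell_id)
  res <- groups$groups |>
    mutate(n_cells = .data$size) |>
    select(-"size")
  members <- split(groups$membership$cell_id, groups$membership$group_id)
  calls <- map(res$group_id, function(gid) {
    cells <- members[[gid]]
    n <- length(cells)
    if (n < params$min_group_size) {
      return(list(status = "uncallable", variants = empty_variants(),
                  reason = "too_few_cells"))
    }
    idx <- unlist(by_cell[intersect(cells, names(by_cell))], use.names = FALSE)
    consensus_one_group(variants[idx, , drop = FALSE], n, params)
  })
  res$status <- map_chr(calls, "status")
  res$variants <- map(calls, "variants")
  res$reason <- map_chr(calls, "reason")
  res$zygosity <- map_chr(res$variants, zygosity_of, ploidy = ploidy)
  as_tibble(res)
}

#' Assign the functional consequence to consensus genotypes
#'
#' Only homozygous variants (dosage = ploidy) carry a consequence;
#' heterozygous-only genotypes get `"none (heterozygous)"`. The consequence
#' of a genotype with several homozygous edits is the most severe one, with
#' severity `stop_gained/start_lost > splice > missense > promoter/intron >
#' synonymous`. Variants missing from the annotation but inside the promoter
#' interval are labelled `promoter`; unannotated variants outside it raise an
#' error.
#'
#' @param consensus output of [call_consensus()].
#' @param annotation tibble `chrom, pos, ref, alt, consequence`.
#' @param promoter_interval list with `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @param ploidy copies of the genome.
#' @return `consensus` with a `consequence` column (`NA` for uncallable
#'   groups, `"WT"` for wild-type groups).
#' @export
assign_consequence <- function(consensus, annotation, promoter_interval,
                               ploidy = 3) {
  sev <- consequence_severity_levels()
  lookup <- annotation |>
    mutate(key = paste(.data$chrom, .data$pos, .data$ref, .data$alt))
  ann <- setNames(lookup$consequence, lookup$key)
  in_promoter <- function(chrom, pos) {
    chrom == promoter_interval$chrom & pos >= promoter_interval$start &
      pos <= promoter_interval$end
  }
  consequence_for <- function(vars, status) {
    if (status == "uncallable") return(NA_character_)
    if (status == "WT" || nrow(vars) == 0) return("WT")
    hom <- filter(vars, .data$dosage == ploidy)
    if (nrow(hom) == 0) return("none (heterozygous)")
    key <- paste(hom$chrom, hom$pos, hom$ref, hom$alt)
    cons <- unname(ann[key])
    miss <- is.na(cons)
    cons[miss & in_promoter(hom$chrom[miss], hom$pos[miss])] <- "promoter"
    if (any(is.na(cons))) {
      abort(paste0("unannotated variant(s) outside the promoter interval: ",
                   paste(key[is.na(cons)], collapse = ", ")))
    }
    sev[min(match(cons, sev))]
  }
  consensus |>
    mutate(consequence = map2_chr(.data$variants, .data$status,
                                  consequence_for))
}

#' Predict the genotype expected from complete editing in the window
#'
#' Every protospacer-strand cytosine within the editing window is predicted
#' to be edited to T on all alleles (homozygous), mapped to genomic
#' forward-strand coordinates (a `G>A` substitution for minus-strand
#' guides). Non-targeting guides predict wild type.
#'
#' @param guides tibble with `grna_id, protospacer, strand, chrom, site_pos,
#'   targeting` (`site_pos` = genomic coordinate of protospacer position 1);
#'   one row per guide.
#' @param window editing window in protospacer coordinates (default 4-8).
#' @param ploidy copies of the genome (predicted dosage).
#' @return tibble `grna_id, non_targeting, predicted` (list-column of
#'   predicted variants).
#' @export
predict_genotype_from_grna <- function(guides, window = c(4L, 8L), ploidy = 3) {
  assert_that(window[1] >= 1 && window[2] >= window[1],
              "`window` must be an increasing pair of positions")
  assert_that(all(window[2] <= nchar(guides$protospacer[guides$targeting]),
                  na.rm = TRUE),
              "editing window extends beyond the protospacer")
  one <- function(proto, strand, chrom, pos1, targeting) {
    if (!isTRUE(targeting)) return(empty_variants())
    wpos <- seq(window[1], window[2])
    bases <- strsplit(proto, "")[[1]][wpos]
    wpos <- wpos[bases == "C"]
    if (!length(wpos)) return(empty_variants())
    if (strand == "+") {
      tibble(chrom = chrom, pos = as.integer(pos1 + (wpos - 1L)), ref = "C",
             alt = "T", dosage = as.integer(ploidy))
    } else {
      tibble(chrom = chrom, pos = as.integer(pos1 - (wpos - 1L)), ref = "G",
             alt = "A", dosage = as.integer(ploidy)) |>
        arrange(.data$pos)
    }
  }
  guides |>
    mutate(non_targeting = !.data$targeting,
           predicted = pmap(list(.data$protospacer, .data$strand, .data$chrom,
                                 .data$site_pos, .data$targeting), one)) |>
    select("grna_id", "non_targeting", "predicted")
}

severity_or_wt <- function(variants, annotation, promoter_interval, ploidy) {
  fake <- tibble(group_id = "x", status = if (nrow(variants)) "edited" else "WT",
                 variants = list(variants))
  assign_consequence(fake, annotation, promoter_interval, ploidy)$consequence
}

#' Compare a called consensus genotype with the gRNA-based prediction
#'
#' Produces two concordance booleans per record: nucleotide-exact agreement
#' of the homozygous edit set, and protein-level agreement of the functional
#' consequence. Protein-discordant records carry a reason: `heterozygous`
#' (called edits are heterozygous only), `unedited` (called WT where edits
#' were predicted) or `different_consequence`.
#'
#' @param called one row of [call_consensus()] output (with `status` and
#'   `variants`), or a tibble of such rows plus a `grna_id` column.
#' @param predicted matching rows of [predict_genotype_from_grna()].
#' @param annotation,promoter_interval,ploidy as in [assign_consequence()].
#' @return tibble `grna_id, nucleotide_match, protein_match, reason`.
#' @export
compare_to_prediction <- function(called, predicted, annotation,
                                  promoter_interval, ploidy = 3) {
  d <- inner_join(called, predicted, by = "grna_id",
                  suffix = c("_called", "_pred"))
  one <- function(status, vars, pred) {
    hom <- filter(vars, .data$dosage == ploidy)
    key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
    nuc <- setequal(key(hom), key(pred))
    cons_called <- severity_or_wt(vars, annotation, promoter_interval, ploidy)
    cons_pred <- severity_or_wt(pred, annotation, promoter_interval, ploidy)
    prot <- identical(cons_called, cons_pred)
    reason <- if (prot) NA_character_
      else if (status == "WT" || nrow(vars) == 0) "unedited"
      else if (nrow(hom) == 0) "heterozygous"
      else "different_consequence"
    tibble(nucleotide_match = nuc, protein_match = prot, reason = reason)
  }
  res <- pmap(list(d$status, d$variants, d$predicted), one) |> bind_rows()
  bind_cols(select(d, "grna_id"), res)
}
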
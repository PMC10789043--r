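# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

# consensus genotype rules, re-implemented naively over one group
brute_consensus <- function(group_cells, variants, n, params, ploidy = 3) {
  wt_tol <- if (n < params$small_group_cutoff) 0 else params$wt_max_mutated_cells
  v <- variants[variants$cell_id %in% group_cells & variants$dosage > 0, ,
                drop = FALSE]
  if (n < params$min_group_size) return(list(status = "uncallable"))
  if (nrow(v) == 0) return(list(status = "WT"))
  sites <- unique(v[, c("chrom", "pos", "ref", "alt")])
  called <- list()
  max_m <- 0
  for (i in seq_len(nrow(sites))) {
    rows <- v[v$chrom == sites$chrom[i] & v$pos == sites$pos[i] &
                v$ref == sites$ref[i] & v$alt == sites$alt[i], ]
    m <- length(unique(rows$cell_id))
    max_m <- max(max_m, m)
    if (m >= params$min_cells_variant && m >= params$min_fraction * n) {
      # strict dosage majority among carriers
      doses <- rows$dosage
      best <- NA
      for (d in unique(doses)) {
        if (sum(doses == d) * 2 > length(doses)) best <- d
      }
      if (is.na(best)) return(list(status = "uncallable"))
      called[[length(called) + 1]] <-
        cbind(sites[i, ], data.frame(dosage = best))
    } else if (m >= params$min_cells_variant) {
      return(list(status = "uncallable"))
    }
  }
  if (length(called) > 0) {
    out <- do.call(rbind, called)
    out <- out[order(out$pos), ]
    rownames(out) <- NULL
    return(list(status = "edited", variants = out))
  }
  if (max_m <= wt_tol) list(status = "WT") else list(status = "uncallable")
}

# AUC by exhaustive pairwise comparison, ties counted one half
brute_auc <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(a) * length(b))
}

# k-NN majority-vote label transfer by exhaustive distances in a given
# embedding, with the package's tie conventions (distance then id;
# label ties to the smaller distance-rank sum)
brute_knn_labels <- function(emb_ref, emb_query, labels, ids_ref, k) {
  out <- character(nrow(emb_query))
  for (i in seq_len(nrow(emb_query))) {
    d <- numeric(nrow(emb_ref))
    for (j in seq_len(nrow(emb_ref))) {
      d[j] <- sqrt(sum((emb_ref[j, ] - emb_query[i, ])^2))
    }
    o <- order(d, ids_ref)
    nn <- o[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      rs <- sapply(top, function(lb) sum(which(labels[nn] == lb)))
      top <- top[which.min(rs)]
    }
    out[i] <- top[1]
  }
  out
}

# exact binomial acceptance region at confidence level 1 - alpha
binom_region <- function(n, p, alpha = 0.01) {
  c(qbinom(alpha / 2, n, p), qbinom(1 - alpha / 2, n, p))
}

# random small variant tables for property tests
random_group_variants <- function(n_cells, max_sites = 4, ploidy = 3) {
  cells <- sprintf("c%02d", seq_len(n_cells))
  sites <- data.frame(chrom = "chr1", pos = sample(100:120, max_sites),
                      ref = "C", alt = "T")
  rows <- list()
  for (ci in cells) {
    for (si in seq_len(nrow(sites))) {
      if (runif(1) < 0.4) {
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = ci, chrom = sites$chrom[si], pos = sites$pos[si],
          ref = sites$ref[si], alt = sites$alt[si],
          dosage = sample.int(ploidy, 1))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(cell_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), dosage = integer()))
  }
  tibble::as_tibble(do.call(rbind, rows))
}
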
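# Diffusion-map loss-of-function scoring and per-barcode classification.

# top eigenpairs of a sparse symmetric matrix by deterministic subspace
# iteration (start basis from the embedding itself, so runs are reproducible)
top_eigen_sym <- function(s, q, start, max_iter = 300, tol = 1e-10) {
  qmat <- qr.Q(qr(start))
  ev_old <- rep(Inf, q)
  for (it in seq_len(max_iter)) {
    z <- as.matrix(s %*% qmat)
    qrz <- qr(z)
    qmat <- qr.Q(qrz)
    ev <- abs(diag(qr.R(qrz)))
    if (max(abs(ev - ev_old)) < tol * max(ev)) break
    ev_old <- ev
  }
  b <- Matrix::t(qmat) %*% (s %*% qmat)
  eb <- eigen(as.matrix(b), symmetric = TRUE)
  list(values = eb$values, vectors = qmat %*% eb$vectors)
}

#' Per-cell diffusion score
#'
#' Builds a Gaussian kernel on the `n_neighbors`-nearest-neighbour graph of
#' the embedding with per-cell adaptive bandwidth (distance to the k-th
#' neighbour), symmetrizes it, and takes the first non-trivial eigenvector
#' of the normalized diffusion operator. The sign is oriented so the
#' reference (non-targeting / wild-type) cells score low, and scores are
#' min-max scaled to `[0, 1]`: a continuous measure of progression towards
#' full loss of function.
#'
#' @param embedding cells x dims matrix with cell ids as rownames.
#' @param reference_cells cell ids anchoring the low end of the score.
#' @param n_neighbors neighbours for the kernel graph (default 10).
#' @param bridge_components with strongly separated cell states the kNN
#'   graph can be genuinely disconnected at any practical `n_neighbors`;
#'   `TRUE` restores the behaviour of a dense kernel by adding one
#'   minimum-distance edge between components (default `FALSE`: error).
#' @return tibble `cell_id, score` of class `diffusion_result`.
#' @export
diffusion_score <- function(embedding, reference_cells, n_neighbors = 10,
                            bridge_components = FALSE) {
  n <- nrow(embedding)
  assert_that(!is.null(rownames(embedding)), "embedding needs cell rownames")
  ref_idx <- match(intersect(reference_cells, rownames(embedding)),
                   rownames(embedding))
  assert_that(length(ref_idx) > 0, "no reference cells found in the embedding")
  # neighbours tied with the k-th distance are all included, so duplicated
  # cells build exactly symmetric kernels
  ke <- kernel_edges(embedding, n_neighbors)
  sigma <- ke$sigma
  sigma[sigma <= 0] <- min(sigma[sigma > 0])
  ii <- ke$i
  jj <- ke$j
  ww <- exp(-ke$d^2 / (sigma[ii] * sigma[jj]))
  w <- sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  w <- pmax_sparse(w, Matrix::t(w))
  g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1 && !bridge_components) {
    abort("kernel graph is disconnected; increase n_neighbors or the kernel width")
  }
  while (comp$no > 1) {
    # bridge the first component to its nearest other component through the
    # closest pair of cells, with the kernel weight at that distance
    a <- which(comp$membership == comp$membership[1])
    b <- which(comp$membership != comp$membership[1])
    best <- c(Inf, NA_integer_, NA_integer_)
    step <- max(1L, floor(5e6 / length(b)))
    for (start in seq(1, length(a), by = step)) {
      rows <- a[seq(start, min(start + step - 1L, length(a)))]
      d2 <- outer(rowSums(embedding[rows, , drop = FALSE]^2),
                  rowSums(embedding[b, , drop = FALSE]^2), "+") -
        2 * embedding[rows, , drop = FALSE] %*%
          t(embedding[b, , drop = FALSE])
      hit <- arrayInd(which.min(d2), dim(d2))
      if (d2[hit] < best[1]) best <- c(d2[hit], rows[hit[1]], b[hit[2]])
    }
    wt <- max(exp(-best[1] / (sigma[best[2]] * sigma[best[3]])), 1e-10)
    w[best[2], best[3]] <- wt
    w[best[3], best[2]] <- wt
    g <- igraph::add_edges(g, best[2:3])
    comp <- igraph::components(g)
  }
  d <- Matrix::rowSums(w)
  dis <- Diagonal(x = 1 / sqrt(d))
  s <- dis %*% w %*% dis
  if (n <= 2048) {
    # exact dense solve at small n; the spectrum of weakly structured
    # graphs is near-degenerate and iterative solvers converge poorly there
    es <- eigen(as.matrix((s + Matrix::t(s)) / 2), symmetric = TRUE)
    eig <- list(values = es$values[1:2], vectors = es$vectors[, 1:2])
    ord <- 1:2
  } else {
    start <- cbind(sqrt(d), embedding[, seq_len(min(4, ncol(embedding))),
                                      drop = FALSE])
    eig <- top_eigen_sym(s, q = ncol(start), start = start)
    ord <- order(eig$values, decreasing = TRUE)
  }
  psi <- as.vector(dis %*% eig$vectors[, ord[2]])
  if (mean(psi[ref_idx]) > mean(psi)) psi <- -psi
  score <- (psi - min(psi)) / (max(psi) - min(psi))
  out <- tibble(cell_id = rownames(embedding), score = score)
  class(out) <- c("diffusion_result", class(out))
  out
}

# elementwise max of two sparse matrices with the same pattern union
pmax_sparse <- function(a, b) {
  (a + b + abs(a - b)) / 2
}

# k-nearest-neighbour edges including all ties at the k-th distance, plus
# the per-cell adaptive bandwidth (distance to the k-th neighbour)
kernel_edges <- function(embedding, k) {
  n <- nrow(embedding)
  assert_that(k < n, "k must be smaller than the number of cells")
  sq <- rowSums(embedding^2)
  sigma <- numeric(n)
  ei <- vector("list", n)
  ed <- vector("list", n)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1, n, by = block)) {
    rows <- seq(start, min(start + block - 1L, n))
    d2 <- outer(sq[rows], sq, "+") -
      2 * embedding[rows, , drop = FALSE] %*% t(embedding)
    for (i in seq_along(rows)) {
      v <- d2[i, ]
      v[rows[i]] <- Inf
      dk <- sort.int(v, partial = k)[k]
      sel <- which(v <= dk + 1e-12)
      sigma[rows[i]] <- sqrt(max(dk, 0))
      ei[[rows[i]]] <- sel
      ed[[rows[i]]] <- sqrt(pmax(v[sel], 0))
    }
  }
  list(i = rep(seq_len(n), lengths(ei)), j = unlist(ei), d = unlist(ed),
       sigma = sigma)
}

#' Sarle's bimodality coefficient
#'
#' `(g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with sample skewness `g1`
#' and sample excess kurtosis `g2`; values above ~0.555 (the uniform
#' distribution's value) suggest bimodality.
#'
#' @param x numeric vector (needs n >= 4 and positive variance).
#' @return the coefficient, or `NA` if undefined.
#' @export
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x); s <- sd(x)
  if (s == 0) return(NA_real_)
  g1 <- (sum((x - m)^3) / n) / s^3 * sqrt(n * (n - 1)) / (n - 2)
  m4 <- sum((x - m)^4) / n
  m2 <- sum((x - m)^2) / n
  g2 <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Classify barcode groups by diffusion score
#'
#' Thresholds are anchored on the genotype references: the low threshold is
#' the 95th percentile (order statistic) of the wild-type barcodes' mean
#' scores and the high threshold the 5th percentile of the stop-codon
#' barcodes' mean scores. A barcode is `notLoF` when its mean score is at or
#' below the low threshold, `LoF` at or above the high threshold and
#' `intermediate` (the separation-of-function range) in between. Sarle's
#' bimodality coefficient of the per-cell scores is reported per barcode.
#'
#' @param barcode_scores tibble `group_id, cell_id, score` (per-cell
#'   diffusion scores of genotyped barcodes).
#' @param wt_groups,stop_groups group ids of the wild-type and homozygous
#'   stop-codon reference barcodes (each non-empty).
#' @return tibble `group_id, n_cells, mean_score, bimodality, class` plus
#'   attributes `low_threshold` / `high_threshold`.
#' @export
classify_barcodes <- function(barcode_scores, wt_groups, stop_groups) {
  assert_that(length(wt_groups) > 0 && length(stop_groups) > 0,
              "need at least one WT and one stop-codon reference barcode")
  per <- barcode_scores |>
    group_by(.data$group_id) |>
    summarise(n_cells = n(), mean_score = mean(.data$score),
              bimodality = bimodality_coefficient(.data$score),
              .groups = "drop")
  wt_means <- per$mean_score[per$group_id %in% wt_groups]
  stop_means <- per$mean_score[per$group_id %in% stop_groups]
  assert_that(length(wt_means) > 0 && length(stop_means) > 0,
              "reference group ids not found in `barcode_scores`")
  lo <- quantile(wt_means, 0.95, type = 1, names = FALSE)
  hi <- quantile(stop_means, 0.05, type = 1, names = FALSE)
  if (lo > hi) {
    abort(paste0("reference barcodes are not separable: WT 95th percentile (",
                 signif(lo, 3), ") exceeds stop-codon 5th percentile (",
                 signif(hi, 3), ")"))
  }
  out <- per |>
    mutate(class = case_when(.data$mean_score <= lo ~ "notLoF",
                             .data$mean_score >= hi ~ "LoF",
                             TRUE ~ "intermediate"))
  attr(out, "low_threshold") <- lo
  attr(out, "high_threshold") <- hi
  out
}
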
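# Skew-normal mixture modelling of pooled log UMI counts.
#
# Barcode (gRNA / iBAR / puroR) UMI counts pooled over cells and features of
# one class are modelled on the natural-log scale as a three-component
# skew-normal mixture: one component for ambient background molecules and two
# for genuine ("signal") counts, allowing a bimodal signal distribution. The
# ambient component is identified as the one with the smallest location.

#' Skew-normal density
#'
#' Density of the skew-normal distribution with location `xi`, scale `omega`
#' and slant `alpha`: `f(x) = 2/omega * phi(z) * Phi(alpha * z)` with
#' `z = (x - xi)/omega`.
#'
#' @param x numeric vector.
#' @param xi location.
#' @param omega scale (> 0).
#' @param alpha slant; `alpha = 0` recovers the normal density.
#' @param log return log-density?
#' @return numeric vector of (log-)densities.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  check_pos(omega, "omega")
  z <- (x - xi) / omega
  ld <- log(2) - log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Skew-normal random deviates
#'
#' Uses the stochastic representation
#' `X = xi + omega * (delta * |Z0| + sqrt(1 - delta^2) * Z1)` with
#' `delta = alpha / sqrt(1 + alpha^2)` and independent standard normals.
#'
#' @param n number of draws.
#' @inheritParams dskewnorm
#' @return numeric vector of length `n`.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  check_pos(omega, "omega")
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(rnorm(n))
  z1 <- rnorm(n)
  xi + omega * (delta * z0 + sqrt(1 - delta^2) * z1)
}

# weighted mixture log-likelihood; `w` are multiplicities of the (unique)
# values in `x`, so fitting integer counts costs O(#distinct values)
mixture_loglik <- function(x, pi_k, xi, omega, alpha, w = 1) {
  k <- length(pi_k)
  comp <- vapply(seq_len(k), function(j) {
    log(pi_k[j]) + dskewnorm(x, xi[j], omega[j], alpha[j], log = TRUE)
  }, numeric(length(x)))
  m <- apply(comp, 1, max)
  sum(w * (m + log(rowSums(exp(comp - m)))))
}

# responsibilities: n x k matrix of posterior component memberships
mixture_responsibilities <- function(x, pi_k, xi, omega, alpha) {
  k <- length(pi_k)
  comp <- vapply(seq_len(k), function(j) {
    log(pi_k[j]) + dskewnorm(x, xi[j], omega[j], alpha[j], log = TRUE)
  }, numeric(length(x)))
  comp <- matrix(comp, ncol = k)
  m <- apply(comp, 1, max)
  w <- exp(comp - m)
  w / rowSums(w)
}

# weighted skew-normal fit for one component; generalized M-step by bounded
# Nelder-Mead from the current parameters, so the EM objective cannot decrease
# bounds: the scale floor keeps a component from collapsing onto a single
# integer count atom; the slant bound keeps the shape identifiable
fit_component <- function(x, w, xi0, omega0, alpha0, omega_floor = 0.08,
                          alpha_max = 10) {
  nll <- function(p) {
    om <- max(exp(p[2]), omega_floor)
    al <- max(min(p[3], alpha_max), -alpha_max)
    -sum(w * dskewnorm(x, p[1], om, al, log = TRUE))
  }
  fit <- optim(c(xi0, log(max(omega0, omega_floor)), alpha0), nll,
               method = "Nelder-Mead", control = list(maxit = 60))
  list(xi = fit$par[1],
       omega = max(exp(fit$par[2]), omega_floor),
       alpha = max(min(fit$par[3], alpha_max), -alpha_max))
}

#' Fit a three-component skew-normal mixture to pooled UMI counts
#'
#' Counts strictly above `min_count`, pooled over all cells and all features
#' of one barcode class, are log-transformed and fitted with a
#' three-component skew-normal mixture by (generalized) EM: exact component
#' posteriors in the E-step, per-component weighted maximum-likelihood
#' updates in the M-step. Initialization places the components at the
#' 33%/66% count quantiles with slant zero; `n_restarts` jittered restarts
#' are run and the best log-likelihood kept. The ambient component is the
#' one with the smallest fitted location.
#'
#' @param counts non-negative integer vector of pooled UMI counts.
#' @param min_count only counts strictly greater than this enter the fit
#'   (default 2).
#' @param n_components number of mixture components (fixed to 3 for the
#'   screen model; other values are for diagnostics only).
#' @param n_restarts random restarts of EM (best likelihood kept).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param min_n minimum number of usable counts required.
#' @param seed integer seed controlling restart jitter.
#' @return an object of class `mixture_fit`: list with `pi`, `xi`, `omega`,
#'   `alpha` (component parameters in fitted order), `ambient_component`
#'   (index of smallest location), `loglik`, trace of log-likelihoods,
#'   `n_obs`, `converged`, `min_count`.
#' @export
fit_count_mixture <- function(counts, min_count = 2, n_components = 3,
                              n_restarts = 5, max_iter = 200, tol = 1e-6,
                              min_n = 100, seed = 1L) {
  assert_that(is.numeric(counts) && all(counts >= 0, na.rm = TRUE),
              "`counts` must be non-negative")
  x_all <- log(counts[!is.na(counts) & counts > min_count])
  n_use <- length(x_all)
  if (n_use < min_n) {
    abort(paste0("insufficient data: ", n_use, " counts above min_count=",
                 min_count, " (need >= ", min_n, ")"))
  }
  # counts are integers: collapse to unique values with multiplicities so EM
  # cost scales with the number of distinct counts, not cells. Each integer
  # atom is spread over its rounding interval (continuity correction) so no
  # component can collapse onto a single count value.
  cnt_tab <- table(counts[!is.na(counts) & counts > min_count])
  vals <- as.numeric(names(cnt_tab))
  mult <- as.numeric(cnt_tab)
  xs <- vector("list", length(vals))
  ws <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    if (vals[i] <= 50) {
      xs[[i]] <- log(vals[i] + c(-0.4, -0.2, 0, 0.2, 0.4))
      ws[[i]] <- rep(mult[i] / 5, 5)
    } else {
      xs[[i]] <- log(vals[i])
      ws[[i]] <- mult[i]
    }
  }
  x <- unlist(xs)
  w <- unlist(ws)
  k <- n_components
  q <- quantile(x_all, probs = seq(1, k) / (k + 1), names = FALSE)
  s <- sd(x_all) / k

  run_em <- function(xi, omega, alpha, pi_k) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      r <- mixture_responsibilities(x, pi_k, xi, omega, alpha)
      pi_k <- pmax(colSums(w * r) / sum(w), 1e-8)
      pi_k <- pi_k / sum(pi_k)
      for (j in seq_len(k)) {
        upd <- fit_component(x, w * r[, j], xi[j], omega[j], alpha[j])
        xi[j] <- upd$xi; omega[j] <- upd$omega; alpha[j] <- upd$alpha
      }
      ll <- mixture_loglik(x, pi_k, xi, omega, alpha, w)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(pi = pi_k, xi = xi, omega = omega, alpha = alpha,
         loglik = trace[length(trace)], trace = trace, converged = converged)
  }

  km_init <- function(data) {
    km <- tryCatch(stats::kmeans(data, centers = k, iter.max = 50,
                                 nstart = 3),
                   error = function(e) NULL)
    if (is.null(km)) return(NULL)
    o <- order(km$centers)
    om0 <- vapply(o, function(j) {
      v <- data[km$cluster == j]
      if (length(v) > 1) max(sd(v), 0.1) else 0.1
    }, numeric(1))
    om0[!is.finite(om0)] <- 0.1
    list(xi = as.vector(km$centers)[o], omega = om0,
         pi_k = pmax(km$size[o] / sum(km$size), 0.01))
  }

  best <- NULL
  withr::with_seed(seed, {
    # three deterministic starts — k-means on all log counts (mass-weighted
    # modes), k-means on the distinct log counts (spread across the range,
    # which finds minority signal modes under a dominant ambient cluster),
    # and an intent-shaped start with one component on the low-count bulk
    # and two splitting the high tail — plus jittered quantile restarts
    tail_init <- local({
      hi <- x_all[x_all > quantile(x_all, 0.8)]
      km2 <- tryCatch(stats::kmeans(hi, centers = 2, iter.max = 50,
                                    nstart = 3), error = function(e) NULL)
      if (is.null(km2) || k != 3) NULL else {
        o <- order(km2$centers)
        list(xi = c(median(x_all), as.vector(km2$centers)[o]),
             omega = pmax(c(sd(x_all[x_all <= quantile(x_all, 0.8)]),
                            vapply(o, function(j) sd(hi[km2$cluster == j]),
                                   numeric(1))), 0.1),
             pi_k = c(0.8, 0.1, 0.1))
      }
    })
    inits <- list(km_init(x_all), km_init(unique(x_all)), tail_init)
    cands <- list()
    for (r in seq_len(max(n_restarts, length(inits)))) {
      if (r <= length(inits)) {
        if (is.null(inits[[r]])) next
        init <- inits[[r]]
        cand <- run_em(xi = init$xi, omega = init$omega,
                       alpha = rep(0, k), pi_k = init$pi_k / sum(init$pi_k))
      } else {
        jit <- rnorm(k, 0, s)
        cand <- run_em(xi = sort(q + jit), omega = rep(max(s, 0.1), k),
                       alpha = rep(0, k), pi_k = rep(1 / k, k))
      }
      cands[[length(cands) + 1]] <- cand
    }
    # a fit only plays the ambient role the model asserts if its smallest-
    # location component carries most of the mass below the median count;
    # prefer the best valid fit, falling back to raw likelihood otherwise
    med <- median(x_all)
    low <- x <= med
    valid <- vapply(cands, function(cd) {
      r0 <- mixture_responsibilities(x[low], cd$pi, cd$xi, cd$omega, cd$alpha)
      sum(w[low] * r0[, which.min(cd$xi)]) / sum(w[low]) > 0.5
    }, logical(1))
    lls <- vapply(cands, function(cd) cd$loglik, numeric(1))
    best <- if (any(valid)) {
      cands[valid][[which.max(lls[valid])]]
    } else {
      cands[[which.max(lls)]]
    }
  })
  if (!best$converged) {
    warn("EM did not converge within max_iter; fit flagged as non-converged")
  }
  structure(
    list(pi = best$pi, xi = best$xi, omega = best$omega, alpha = best$alpha,
         ambient_component = which.min(best$xi), loglik = best$loglik,
         loglik_trace = best$trace, n_obs = n_use,
         max_count_observed = max(counts, na.rm = TRUE),
         converged = best$converged, min_count = min_count),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Skew-normal mixture fit (", length(x$pi), " components, n = ",
      x$n_obs, ")\n", sep = "")
  tab <- data.frame(pi = round(x$pi, 3), xi = round(x$xi, 3),
                    omega = round(x$omega, 3), alpha = round(x$alpha, 2))
  tab$role <- ifelse(seq_along(x$pi) == x$ambient_component, "ambient", "signal")
  print(tab)
  cat("logLik:", format(x$loglik), if (!x$converged) " (not converged)", "\n")
  invisible(x)
}

#' Posterior probability of the ambient component at given counts
#'
#' @param fit a `mixture_fit`.
#' @param counts positive counts (evaluated at `log(counts)`).
#' @return numeric vector of ambient posteriors.
#' @export
ambient_posterior <- function(fit, counts) {
  r <- mixture_responsibilities(log(counts), fit$pi, fit$xi, fit$omega,
                                fit$alpha)
  r[, fit$ambient_component]
}

#' Derive the dual UMI-count assignment thresholds from a mixture fit
#'
#' The ambient posterior is evaluated on the integer count grid from
#' `min_count` to the largest observed count. The lower threshold `t_lo` is
#' the largest count whose ambient posterior is still at least `p_lo` (counts
#' at or below it are consistent with ambient background at >= 90%
#' probability); the upper threshold `t_hi` is the smallest count beyond the
#' last crossing at which the posterior stays at or below `p_hi`. When the
#' posterior crosses a level more than once the most conservative pair is
#' used (largest `t_hi`, then the largest `t_lo` not exceeding it). A fitted
#' ambient weight that is essentially zero yields the degenerate pair
#' `t_lo = t_hi = min_count`: every count above the floor is signal.
#'
#' @param fit a `mixture_fit`.
#' @param p_lo,p_hi posterior levels defining the lower/upper thresholds
#'   (defaults 0.9 and 0.1).
#' @param max_count upper end of the scanned grid; defaults to the count at
#'   which the fitted signal components hold essentially all mass.
#' @return an object of class `threshold_pair`: list with `t_lo`, `t_hi`,
#'   `p_lo`, `p_hi`.
#' @export
assignment_thresholds <- function(fit, p_lo = 0.9, p_hi = 0.1,
                                  max_count = NULL) {
  check_prob(p_lo, "p_lo"); check_prob(p_hi, "p_hi")
  mc <- fit$min_count
  if (fit$pi[fit$ambient_component] < 1e-3) {
    return(structure(list(t_lo = mc, t_hi = mc, p_lo = p_lo, p_hi = p_hi),
                     class = "threshold_pair"))
  }
  if (is.null(max_count)) {
    # thresholds are only meaningful inside the observed count range
    max_count <- fit$max_count_observed %||%
      ceiling(exp(max(fit$xi + 8 * fit$omega)))
    max_count <- max(max_count, mc + 10)
  }
  grid <- seq(mc, max_count)
  post <- ambient_posterior(fit, grid)
  # far in the signal tail every component density underflows; the ambient
  # posterior is zero there for any sensible fit
  post[!is.finite(post)] <- 0
  if (min(post) > p_hi) {
    abort(paste0("ambient posterior never reaches p_hi = ", p_hi,
                 "; the fit looks ambient-dominated - inspect it before",
                 " assigning barcodes"))
  }
  # t_hi: preferably after the *last* up-crossing, i.e. smallest count c
  # with posterior <= p_hi for every count >= c (conservative for
  # non-monotone posteriors); when a heavy ambient tail regains dominance
  # at extreme counts, the first down-crossing is used instead
  suffix_max <- rev(cummax(rev(post)))
  t_hi <- grid[which(suffix_max <= p_hi)[1]]
  if (is.na(t_hi)) {
    t_hi <- grid[which(post <= p_hi)[1]]
    warn(paste0("ambient posterior re-exceeds p_hi at high counts; using ",
                "the first crossing (t_hi = ", t_hi, ")"))
  }
  below <- grid[post >= p_lo & grid <= t_hi]
  t_lo <- if (length(below)) max(below) else mc
  structure(list(t_lo = t_lo, t_hi = t_hi, p_lo = p_lo, p_hi = p_hi),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat("UMI thresholds: t_lo =", x$t_lo, "(ambient posterior >=", x$p_lo,
      "), t_hi =", x$t_hi, "(ambient posterior <=", x$p_hi, ")\n")
  invisible(x)
}

#' Assign one feature of a class to each cell from UMI counts
#'
#' A feature is called in a cell iff its count exceeds the upper threshold
#' and no *other* feature of the same class exceeds the lower threshold.
#' Cells failing the rule are unassigned, with reason `ambiguous` when a
#' second feature exceeds `t_lo` (this removes most doublets, which carry two
#' gRNAs) and `no_signal` when no feature clears `t_hi`.
#'
#' @param counts sparse or dense cells x features count matrix with cell ids
#'   as rownames and feature ids as colnames.
#' @param thresholds a `threshold_pair` derived from the same feature class.
#' @return a tibble (one row per cell): `cell_id`, `feature_id` (`NA` when
#'   unassigned), `reason` in `assigned | ambiguous | no_signal`.
#' @export
assign_features <- function(counts, thresholds) {
  assert_that(inherits(thresholds, "threshold_pair"),
              "`thresholds` must come from assignment_thresholds()")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` needs cell rownames and feature colnames")
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  # top and second-largest count per cell
  dtm <- Matrix::t(m)
  n_cells <- ncol(dtm)
  top <- numeric(n_cells); second <- numeric(n_cells); arg <- integer(n_cells)
  p <- dtm@p; ii <- dtm@i; xx <- dtm@x
  for (cell in seq_len(n_cells)) {
    idx <- if (p[cell + 1] > p[cell]) seq(p[cell] + 1, p[cell + 1]) else integer(0)
    if (!length(idx)) { top[cell] <- 0; second[cell] <- 0; arg[cell] <- NA_integer_; next }
    v <- xx[idx]
    o <- order(v, decreasing = TRUE)
    top[cell] <- v[o[1]]
    arg[cell] <- ii[idx][o[1]] + 1L
    second[cell] <- if (length(v) > 1) v[o[2]] else 0
  }
  assigned <- top > thresholds$t_hi & second <= thresholds$t_lo
  reason <- ifelse(assigned, "assigned",
                   ifelse(top > thresholds$t_hi, "ambiguous", "no_signal"))
  tibble(cell_id = rownames(counts),
         feature_id = ifelse(assigned, colnames(counts)[arg], NA_character_),
         reason = reason)
}

#' Combine gRNA, iBAR and puroR calls per cell
#'
#' @param grna,ibar,puror assignment tibbles from [assign_features()] over
#'   the same cell set.
#' @return tibble with one row per cell: assigned ids per class (`NA` when
#'   unassigned) and logical flags `unique_grna_ibar`, `unique_puror`,
#'   `both`.
#' @export
co_assign <- function(grna, ibar, puror) {
  for (tb in list(grna, ibar, puror)) {
    assert_that(all(c("cell_id", "feature_id", "reason") %in% names(tb)),
                "assignment tables need cell_id/feature_id/reason columns")
  }
  same <- setequal(grna$cell_id, ibar$cell_id) &&
    setequal(grna$cell_id, puror$cell_id)
  if (!same) abort("assignment tables cover different cell sets")
  out <- grna |>
    select(cell_id = "cell_id", grna = "feature_id") |>
    inner_join(select(ibar, cell_id = "cell_id", ibar = "feature_id"),
               by = "cell_id") |>
    inner_join(select(puror, cell_id = "cell_id", puror = "feature_id"),
               by = "cell_id") |>
    mutate(unique_grna_ibar = !is.na(.data$grna) & !is.na(.data$ibar),
           unique_puror = !is.na(.data$puror),
           both = .data$unique_grna_ibar & .data$unique_puror) |>
    arrange(.data$cell_id)
  as_tibble(out)
}
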
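#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,j) = 1 - 2 * sum(pmin(x_i, x_j)) / sum(x_i + x_j)` on non-negative
#' feature rows (abundances, relative abundances, or range-standardised
#' metric values). Entries lie in `[0, 1]`, the matrix is symmetric with a
#' zero diagonal.
#'
#' @param mat site x feature numeric matrix, non-negative, no all-zero row.
#' @return square symmetric matrix with site labels; the site totals of the
#'   first feature column are attached as attribute `orient_ref` for later
#'   axis orientation.
#' @examples
#' bray_curtis(rbind(a = c(2, 1), b = c(1, 3)))   # off-diagonal 3/7
#' @export
bray_curtis <- function(mat) {
  assert_that(is.matrix(mat) && is.numeric(mat), "need a numeric matrix")
  assert_that(all(mat >= 0), "Bray-Curtis requires non-negative entries")
  zero_rows <- rowSums(mat) == 0
  if (any(zero_rows)) {
    stop_sh("all-zero row(s): ",
            paste(rownames(mat)[zero_rows], collapse = ", "),
            class = "streamhealth_validation_error")
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  rs <- rowSums(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(pmin(mat[i, ], mat[j, ]))
      d[i, j] <- d[j, i] <- 1 - 2 * shared / (rs[i] + rs[j])
    }
  }
  attr(d, "orient_ref") <- mat[, 1]
  d
}

#' Pool-adjacent-violators isotonic regression
#'
#' Least-squares non-decreasing fit to `y` (optionally weighted): adjacent
#' blocks violating monotonicity are pooled to their (weighted) mean until
#' the fitted sequence is non-decreasing. The weighted sum of the fit
#' equals the weighted sum of the input.
#'
#' @param y numeric vector, already arranged in the target order (for NMDS:
#'   configuration distances ordered by ascending dissimilarity).
#' @param w optional positive weights.
#' @return numeric vector of fitted values, non-decreasing.
#' @export
pav_isotonic <- function(y, w = NULL) {
  n <- length(y)
  assert_that(n >= 1, "need at least one value")
  if (is.null(w)) w <- rep(1, n)
  # stack of blocks: running (mean, weight, size)
  means <- numeric(n); wts <- numeric(n); sizes <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    means[top] <- y[i]; wts[top] <- w[i]; sizes[top] <- 1L
    while (top > 1L && means[top - 1L] > means[top]) {
      wsum <- wts[top - 1L] + wts[top]
      means[top - 1L] <- (wts[top - 1L] * means[top - 1L] +
                          wts[top] * means[top]) / wsum
      wts[top - 1L] <- wsum
      sizes[top - 1L] <- sizes[top - 1L] + sizes[top]
      top <- top - 1L
    }
  }
  rep(means[seq_len(top)], sizes[seq_len(top)])
}

#' Kruskal stress-1
#'
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`: the badness-of-fit of a
#' configuration's inter-point distances `d` to the monotone disparities
#' `dhat`. Zero iff the monotone fit is perfect.
#'
#' @param d configuration distances (positive support overall).
#' @param dhat fitted disparities, same length.
#' @return stress value in `[0, 1]` for PAV-fitted disparities.
#' @export
stress1 <- function(d, dhat) {
  assert_that(length(d) == length(dhat), "d and dhat must have equal length")
  ss <- sum(d^2)
  assert_that(ss > 0, "stress undefined for all-zero configuration distances")
  sqrt(sum((d - dhat)^2) / ss)
}

# pairwise distances of configuration rows, as the lower-triangle vector
# ordered to match `pairs` (2-column index matrix)
config_dist <- function(x, pairs) {
  dx <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(dx * dx))
}

# stress of configuration x given dissimilarity order; returns list(stress, d, dhat)
eval_stress <- function(x, pairs, ord_primary, diss_sorted) {
  d <- config_dist(x, pairs)
  dsort <- d[ord_primary]
  # primary (weak) tie treatment: within blocks of tied dissimilarities the
  # configuration distances are taken in ascending order, so ties are free
  # to differ without stress penalty
  o2 <- order(diss_sorted, dsort, method = "radix")
  dhat_sorted <- pav_isotonic(dsort[o2])
  dhat <- numeric(length(d))
  dhat[ord_primary[o2]] <- dhat_sorted
  list(stress = stress1(d, dhat), d = d, dhat = dhat)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds sites in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities as closely
#' as possible, minimising Kruskal stress-1. The optimiser alternates a
#' pool-adjacent-violators isotonic fit (primary/weak tie treatment) with a
#' steepest-descent configuration update under step halving; the best of
#' `n_starts` starts is kept (start 1 is a classical-scaling configuration,
#' the rest are seeded uniform random configurations scaled to the distance
#' range). Axes are centred, rotated to principal axes, and sign-fixed (see
#' [orient_axes()]), so results are reproducible given `seed`.
#'
#' @param dm square symmetric dissimilarity matrix (e.g. [bray_curtis()]).
#' @param k number of dimensions (default 2).
#' @param n_starts number of starting configurations (default 20).
#' @param max_iter maximum iterations per start (default 300).
#' @param tol relative stress-change convergence tolerance (default 1e-7).
#' @param seed integer seed controlling the random starts.
#' @param orient_ref optional covariate for axis-sign fixing; defaults to
#'   the `orient_ref` attribute of `dm` when present.
#' @return object of class `sh_nmds`: `points` (site x k), `stress`,
#'   `n_starts`, `best_start`, `iterations`, `converged`, `stress_trace`
#'   (best start), `degenerate` flag.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, max_iter = 300, tol = 1e-7,
                 seed = 1, orient_ref = NULL) {
  assert_that(is.matrix(dm) && nrow(dm) == ncol(dm), "need a square matrix")
  assert_that(isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)),
              "dissimilarity matrix must be symmetric")
  n <- nrow(dm)
  assert_that(n >= k + 1, "need at least k + 1 sites")
  if (is.null(orient_ref)) orient_ref <- attr(dm, "orient_ref")
  pairs <- which(upper.tri(dm), arr.ind = TRUE)[, c(2, 1), drop = FALSE]
  colnames(pairs) <- NULL
  diss <- dm[cbind(pairs[, 1], pairs[, 2])]
  # fixed primary order: ascending dissimilarity, ties by pair index
  ord_primary <- order(diss, pairs[, 1], pairs[, 2], method = "radix")
  diss_sorted <- diss[ord_primary]
  dmax <- max(diss)
  assert_that(dmax > 0, "all dissimilarities are zero")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- vector("list", n_starts)
  cm <- try(stats::cmdscale(stats::as.dist(dm), k = k), silent = TRUE)
  starts[[1]] <- if (!inherits(cm, "try-error") && is.matrix(cm) && ncol(cm) == k) {
    cm + matrix(stats::rnorm(n * k, sd = 1e-4 * dmax), n, k)
  } else {
    matrix(stats::runif(n * k, -dmax, dmax), n, k)
  }
  if (n_starts > 1) {
    for (s in 2:n_starts) {
      starts[[s]] <- matrix(stats::runif(n * k, -dmax, dmax), n, k)
    }
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    run <- nmds_one_start(starts[[s]], pairs, ord_primary, diss_sorted,
                          max_iter, tol)
    run$start <- s
    if (is.null(best) || run$stress < best$stress) best <- run
  }

  pts <- orient_axes(best$x, reference = orient_ref)
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  degenerate <- best$stress < 1e-6 &&
    any(stats::dist(pts) < 1e-8 * max(stats::dist(pts), 1e-12)) && n > k + 1
  if (!best$converged) {
    warning("NMDS did not converge in any start within max_iter = ", max_iter)
  }
  structure(list(points = pts, stress = best$stress, n_starts = n_starts,
                 best_start = best$start, iterations = best$iterations,
                 converged = best$converged, stress_trace = best$trace,
                 degenerate = degenerate, k = k, seed = seed),
            class = "sh_nmds")
}

# single-start stress minimisation: steepest descent with step halving;
# every accepted step strictly decreases the full (re-fitted) stress, so the
# per-iteration stress trace is non-increasing by construction
nmds_one_start <- function(x, pairs, ord_primary, diss_sorted, max_iter, tol) {
  n <- nrow(x)
  ev <- eval_stress(x, pairs, ord_primary, diss_sorted)
  trace <- ev$stress
  step <- 0.1 * max(diss_sorted)
  converged <- FALSE
  iter <- 0L
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- pmax(ev$d, 1e-12)
    sstar <- sum((ev$d - ev$dhat)^2)
    tstar <- sum(ev$d^2)
    s <- max(ev$stress, 1e-12)
    # dS/dx with disparities held fixed:
    # S^2 = S*/T*; dS*/d d_ij = 2(d - dhat); dT*/d d_ij = 2 d
    coefS <- 2 * (ev$d - ev$dhat) / d
    coefT <- 2
    grad <- matrix(0, n, ncol(x))
    for (a in seq_len(ncol(x))) {
      dx <- x[i1, a] - x[i2, a]
      gS <- coefS * dx
      gT <- coefT * dx
      # d(S*)/dx_ia accumulates +g over pairs with i first, -g with i second
      gs_i <- rowsum_vec(gS, i1, n) - rowsum_vec(gS, i2, n)
      gt_i <- rowsum_vec(gT, i1, n) - rowsum_vec(gT, i2, n)
      grad[, a] <- (gs_i * tstar - sstar * gt_i) / (2 * s * tstar^2)
    }
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < 1e-14) { converged <- TRUE; break }
    dir <- grad / gnorm
    improved <- FALSE
    st <- step
    for (h in 1:20) {
      xn <- x - st * dir
      evn <- eval_stress(xn, pairs, ord_primary, diss_sorted)
      if (evn$stress < ev$stress) { improved <- TRUE; break }
      st <- st / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel <- (ev$stress - evn$stress) / max(ev$stress, 1e-12)
    x <- xn; ev <- evn
    trace <- c(trace, ev$stress)
    step <- st * 1.5
    if (rel < tol) { converged <- TRUE; break }
    if (ev$stress < 1e-9) { converged <- TRUE; break }
  }
  list(x = x, stress = ev$stress, iterations = iter, converged = converged,
       trace = trace)
}

# sum v over groups idx (1..n); dense and fast for our sizes
rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  tab <- rowsum(v, idx)
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

#' Orient ordination axes deterministically
#'
#' NMDS solutions are defined only up to rotation, reflection and
#' translation. This centres the configuration, rotates it to its principal
#' axes (axis 1 = maximum variance), and fixes the sign of each axis so
#' that its correlation with `reference` is non-negative (falling back, for
#' a missing or uncorrelated reference, to making the largest-magnitude
#' coordinate positive).
#'
#' @param x site x k coordinate matrix.
#' @param reference optional numeric site covariate used for sign fixing.
#' @return oriented coordinate matrix of the same shape.
#' @export
orient_axes <- function(x, reference = NULL) {
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  if (any(sv$d < 1e-12 * max(sv$d, 1e-300))) {
    warning("zero-variance axis; returning centred coordinates unrotated")
    rot <- x
  } else {
    rot <- x %*% sv$v
  }
  for (a in seq_len(ncol(rot))) {
    s <- 0
    if (!is.null(reference) && stats::sd(reference) > 0 && stats::sd(rot[, a]) > 0) {
      s <- sign(stats::cor(reference, rot[, a]))
    }
    if (s == 0) s <- sign(rot[which.max(abs(rot[, a])), a])
    if (s == 0) s <- 1
    rot[, a] <- s * rot[, a]
  }
  dimnames(rot) <- dimnames(x)
  rot
}

#' @export
print.sh_nmds <- function(x, ...) {
  cat("NMDS (Kruskal stress-1):", nrow(x$points), "sites, k =", x$k, "\n")
  cat("stress:", format(x$stress, digits = 6),
      "| converged:", x$converged,
      "| best start:", x$best_start, "/", x$n_starts, "\n")
  if (x$degenerate) cat("note: near-zero stress with coincident points (degenerate)\n")
  invisible(x)
}
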
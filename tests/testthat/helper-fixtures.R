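# fixtures and independent oracles used across the suite

random_guild_table <- function(n_species, seed = 1) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("rsp%03d", seq_len(n_species)),
    trophic = sample(c("Omn", "Ins", "Car"), n_species, replace = TRUE),
    habitat = sample(c("BT", "RB", "RB-WC", "WC"), n_species, replace = TRUE),
    tolerance = sample(c("SS", "IS", "TS"), n_species, replace = TRUE),
    native = sample(c(TRUE, FALSE), n_species, replace = TRUE, prob = c(.9, .1)),
    stringsAsFactors = FALSE
  )
}

random_abundance <- function(n_sites, species_ids, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_sites * length(species_ids), lambda), n_sites,
              dimnames = list(sprintf("rs%02d", seq_len(n_sites)), species_ids))
  m
}

# brute-force isotonic fit: enumerate all monotone block partitions of y and
# return the least-squares non-decreasing step fit (block means)
brute_force_isotonic <- function(y) {
  n <- length(y)
  if (n == 1) return(y)
  best <- NULL; best_sse <- Inf
  # each of the 2^(n-1) cut patterns defines contiguous blocks; the block-mean
  # fit is optimal within a partition, and feasible iff means non-decreasing
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- mean(y[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# variance-based Ward oracle: greedy merge of the pair with the smallest
# increase in total within-cluster sum of squares, recomputed from raw
# coordinates; Ward.D2 height = sqrt(2 * delta ESS)
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  ess <- function(idx) {
    sub <- x[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_d - 1e-12) { best_d <- delta; best <- c(i, j) }
      }
    }
    heights <- c(heights, sqrt(2 * best_d))
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# 1-D grid search over 4-point NMDS configurations (x1 fixed at 0, the rest
# on a coarse grid then locally refined); stress is scale-invariant so the
# unit cube suffices
grid_search_stress_4pt_k1 <- function(dm) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  diss <- dm[pairs]
  ordp <- order(diss, pairs[, 1], pairs[, 2])
  eval1 <- function(x) {
    d <- abs(x[pairs[, 1]] - x[pairs[, 2]])
    if (sum(d^2) == 0) return(Inf)  # fully collapsed configuration
    ds <- d[ordp]
    o2 <- order(diss[ordp], ds)
    dhat <- numeric(6)
    dhat[ordp[o2]] <- streamhealth::pav_isotonic(ds[o2])
    streamhealth::stress1(d, dhat)
  }
  grid <- seq(-1, 1, by = 0.1)
  best <- Inf; bx <- NULL
  for (a in grid) for (b in grid) for (cc in grid) {
    s <- eval1(c(0, a, b, cc))
    if (s < best) { best <- s; bx <- c(0, a, b, cc) }
  }
  for (rounds in 1:3) {
    stepw <- 0.1 / 4^rounds
    repeat {
      improved <- FALSE
      for (i in 2:4) for (dd in c(-stepw, stepw)) {
        cand <- bx; cand[i] <- cand[i] + dd
        s <- eval1(cand)
        if (s < best - 1e-12) { best <- s; bx <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  best
}

tiny_chem <- function(n = 8, seed = 3) {
  set.seed(seed)
  data.frame(site_id = sprintf("c%02d", 1:n),
             WT = runif(n, 20, 29), DO = runif(n, 7, 12),
             EC = runif(n, 100, 600), TSS = runif(n, 1, 18),
             TOC = runif(n, 1, 11), BOD = runif(n, 0.4, 4.5),
             TN = runif(n, 1, 6), NH4_N = runif(n, 0.01, 1),
             NO3_N = runif(n, 0.6, 4.6), TP = runif(n, 7, 208),
             PO4_P = runif(n, 0.1, 70), TN_TP = runif(n, 13, 222),
             Chl_a = runif(n, 0.5, 140))
}
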
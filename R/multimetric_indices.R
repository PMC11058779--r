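#' Metric scoring criteria
#'
#' Both indices score each metric 5 / 3 / 1 against two cut points.
#' `cut1` separates the best bin (score 5) from the middle bin (score 3);
#' `cut2` separates the middle bin from the worst (score 1). For a
#' `lower_is_better` metric `cut1 < cut2`; for `higher_is_better`
#' `cut1 > cut2`. Values equal to a cut take the better score.
#'
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @param cut1,cut2 the two thresholds (finite, distinct, ordered per
#'   direction).
#' @return a `metric_criterion` list.
#' @export
metric_criterion <- function(direction = c("lower_is_better", "higher_is_better"),
                             cut1, cut2) {
  direction <- match.arg(direction)
  assert_that(is.finite(cut1) && is.finite(cut2), "criterion cuts must be finite")
  if (direction == "lower_is_better") {
    assert_that(cut1 < cut2, "lower_is_better needs cut1 < cut2")
  } else {
    assert_that(cut1 > cut2, "higher_is_better needs cut1 > cut2")
  }
  structure(list(direction = direction, cut1 = cut1, cut2 = cut2),
            class = "metric_criterion")
}

#' Score one metric value against its criterion
#'
#' @param value finite numeric metric value.
#' @param criterion a [metric_criterion()].
#' @return integer score: 5, 3 or 1.
#' @export
score_metric <- function(value, criterion) {
  assert_that(inherits(criterion, "metric_criterion"), "need a metric_criterion")
  assert_that(all(is.finite(value)), "metric value must be finite")
  if (criterion$direction == "lower_is_better") {
    ifelse(value <= criterion$cut1, 5L, ifelse(value <= criterion$cut2, 3L, 1L))
  } else {
    ifelse(value >= criterion$cut1, 5L, ifelse(value >= criterion$cut2, 3L, 1L))
  }
}

#' Default mWPI criteria
#'
#' Seven chemical metrics spanning the nutrient regime (TN, TP, TN:TP),
#' organic matter (BOD), suspended/ionic content (TSS, EC), and primary
#' productivity (Chl-a). The shipped cut points are round numbers placed
#' inside the observed ranges of wadable-stream monitoring data for these
#' variables; regional programmes should supply their own criteria file
#' (see [read_criteria()]). A high TN:TP ratio indicates phosphorus-poor,
#' cleaner water, so TN:TP scores higher-is-better; all other metrics are
#' pollutant-like.
#'
#' @return named list of `metric_criterion`, names =
#'   `TN, TP, TN_TP, BOD, TSS, EC, Chl_a`.
#' @export
default_mwpi_criteria <- function() {
  list(
    TN    = metric_criterion("lower_is_better", 1.5, 3),     # mg/L
    TP    = metric_criterion("lower_is_better", 30, 100),    # ug/L
    TN_TP = metric_criterion("higher_is_better", 100, 30),
    BOD   = metric_criterion("lower_is_better", 1, 3),       # mg/L
    TSS   = metric_criterion("lower_is_better", 4, 10),      # mg/L
    EC    = metric_criterion("lower_is_better", 200, 400),   # uS/cm
    Chl_a = metric_criterion("lower_is_better", 5, 25)       # ug/L
  )
}

#' Default mIBI-F criteria
#'
#' Eight fish-community metrics. %TS, %Omn and %Ano degrade as their values
#' rise, so they score lower-is-better; the richness, native-insectivore and
#' native-abundance metrics score higher-is-better. Cut points follow the
#' trisection convention of regional fish IBIs for wadable streams and are
#' configurable.
#'
#' @return named list of `metric_criterion`, names `M1_NS ... M8_pAno`.
#' @export
default_mibif_criteria <- function() {
  list(
    M1_NS   = metric_criterion("higher_is_better", 8, 4),    # native species
    M2_RB   = metric_criterion("higher_is_better", 4, 2),    # riffle-benthic species
    M3_SS   = metric_criterion("higher_is_better", 4, 2),    # sensitive species
    M4_pTS  = metric_criterion("lower_is_better", 20, 45),   # % tolerant individuals
    M5_pOmn = metric_criterion("lower_is_better", 25, 50),   # % omnivore individuals
    M6_pNIns = metric_criterion("higher_is_better", 45, 20), # % native insectivores
    M7_NSI  = metric_criterion("higher_is_better", 200, 75), # native individuals
    M8_pAno = metric_criterion("lower_is_better", 1, 3)      # % anomalies
  )
}

#' Health-class bands
#'
#' Ordered, contiguous integer bands mapping an index total to one of
#' `very poor < poor < fair < good < excellent`.
#'
#' @param bands data.frame with columns `lo`, `hi`, `label`.
#' @return validated `health_bands` object.
#' @export
health_bands <- function(bands) {
  assert_that(is.data.frame(bands) && all(c("lo", "hi", "label") %in% names(bands)),
              "bands need columns lo, hi, label")
  bands <- bands[order(bands$lo), ]
  assert_that(all(bands$lo <= bands$hi), "each band needs lo <= hi")
  if (nrow(bands) > 1) {
    gaps <- bands$lo[-1] != bands$hi[-nrow(bands)] + 1
    assert_that(!any(gaps), "bands must tile the score range without gaps/overlaps",
                class = "streamhealth_validation_error")
  }
  bands$label <- factor(bands$label, levels = bands$label, ordered = TRUE)
  structure(bands, class = c("health_bands", "data.frame"))
}

#' @rdname health_bands
#' @details `default_mwpi_bands()` spans the 7-35 mWPI total; the class
#'   narrative for chemical health places scores above 30 in `excellent`
#'   and 13 or less in `very poor`.
#' @export
default_mwpi_bands <- function() {
  health_bands(data.frame(
    lo = c(7, 14, 20, 26, 31),
    hi = c(13, 19, 25, 30, 35),
    label = c("very poor", "poor", "fair", "good", "excellent")
  ))
}

#' @rdname health_bands
#' @details `default_mibif_bands()` trisects the 8-40 mIBI-F total the same
#'   way; treat as a configurable placeholder pending programme-specific
#'   calibration.
#' @export
default_mibif_bands <- function() {
  health_bands(data.frame(
    lo = c(8, 15, 22, 29, 35),
    hi = c(14, 21, 28, 34, 40),
    label = c("very poor", "poor", "fair", "good", "excellent")
  ))
}

#' Map an index total to its health class
#'
#' @param total integer index total (vectorised).
#' @param bands a [health_bands()] object.
#' @return ordered factor of class labels.
#' @export
classify_health <- function(total, bands) {
  assert_that(inherits(bands, "health_bands"), "need health_bands")
  out <- bands$label[findInterval(total, c(bands$lo, max(bands$hi) + 1))]
  bad <- total < min(bands$lo) | total > max(bands$hi)
  if (any(bad)) {
    stop_sh("index total outside band coverage: ",
            paste(total[bad], collapse = ", "),
            class = "streamhealth_validation_error")
  }
  out
}

#' Compute the eight mIBI-F community metrics for one site
#'
#' M1 native species richness (NS); M2 riffle-benthic species richness (RB
#' habitat exactly, the combined riffle-benthic/water-column guild is not
#' counted); M3 sensitive-species richness (SS); M4 % individuals of
#' tolerant species; M5 % individuals of omnivores; M6 % individuals of
#' native insectivores; M7 native individuals (NSI); M8 % individuals with
#' anomalies.
#'
#' @param abund site x species count matrix.
#' @param guilds guild table covering all species in `abund`.
#' @param site site id (row of `abund`).
#' @param anomalies optional site x species anomaly-count matrix.
#' @return named numeric vector `M1_NS ... M8_pAno`.
#' @export
compute_biological_metrics <- function(abund, guilds, site, anomalies = NULL) {
  guilds <- validate_guild_table(guilds)
  validate_abundance(abund, anomalies)
  assert_that(site %in% rownames(abund), "unknown site: ", site)
  missing_sp <- setdiff(colnames(abund), guilds$species_id)
  assert_that(length(missing_sp) == 0,
              "species missing from guild table: ",
              paste(missing_sp, collapse = ", "))
  x <- stats::setNames(as.vector(abund[site, ]), colnames(abund))
  g <- guilds[match(names(x), guilds$species_id), ]
  n_tot <- sum(x)
  if (n_tot == 0) {
    stop_sh("site ", site, " has zero individuals; percentage metrics undefined",
            class = "streamhealth_zero_site")
  }
  present <- x > 0
  ano <- if (is.null(anomalies)) 0 else sum(anomalies[site, ])
  c(
    M1_NS   = sum(present & g$native),
    M2_RB   = sum(present & g$habitat == "RB"),
    M3_SS   = sum(present & g$tolerance == "SS"),
    M4_pTS  = 100 * sum(x[g$tolerance == "TS"]) / n_tot,
    M5_pOmn = 100 * sum(x[g$trophic == "Omn"]) / n_tot,
    M6_pNIns = 100 * sum(x[g$native & g$trophic == "Ins"]) / n_tot,
    M7_NSI  = sum(x[g$native]),
    M8_pAno = 100 * ano / n_tot
  )
}

score_index <- function(values, criteria, bands, prefix) {
  missing_m <- setdiff(names(criteria), names(values))
  assert_that(length(missing_m) == 0,
              prefix, " metric value(s) missing: ", paste(missing_m, collapse = ", "))
  scores <- vapply(names(criteria),
                   function(m) score_metric(values[[m]], criteria[[m]]),
                   integer(1))
  total <- sum(scores)
  list(values = unlist(values)[names(criteria)], scores = scores,
       total = total, health_class = classify_health(total, bands))
}

#' Score the multi-metric water pollution index (mWPI)
#'
#' Scores seven chemical metrics 5/3/1 against `criteria` and sums them.
#' The total lies in 7-35; higher totals indicate better chemical health.
#'
#' @param record named list/vector holding at least
#'   `TN, TP, TN_TP, BOD, TSS, EC, Chl_a`.
#' @param criteria named list of [metric_criterion()] (default
#'   [default_mwpi_criteria()]).
#' @param bands [health_bands()] over 7-35.
#' @return list with `values`, `scores`, `total`, `health_class`.
#' @export
mwpi_score <- function(record, criteria = default_mwpi_criteria(),
                       bands = default_mwpi_bands()) {
  res <- score_index(as.list(record), criteria, bands, "mWPI")
  structure(res, class = "index_result", index = "mWPI")
}

#' Score the fish multi-metric index of biotic integrity (mIBI-F)
#'
#' Scores the eight community metrics 5/3/1 and sums them; total in 8-40,
#' higher = better biological health.
#'
#' @param metrics named vector from [compute_biological_metrics()].
#' @param criteria named list of [metric_criterion()].
#' @param bands [health_bands()] over 8-40.
#' @return list with `values`, `scores`, `total`, `health_class`.
#' @export
mibif_score <- function(metrics, criteria = default_mibif_criteria(),
                        bands = default_mibif_bands()) {
  res <- score_index(as.list(metrics), criteria, bands, "mIBI-F")
  structure(res, class = "index_result", index = "mIBI-F")
}

#' @export
print.index_result <- function(x, ...) {
  cat(attr(x, "index"), "total:", x$total,
      "| class:", as.character(x$health_class), "\n")
  print(data.frame(value = x$values, score = x$scores))
  invisible(x)
}

#' Score an index across many sites
#'
#' Applies [mwpi_score()] to each row of a chemistry table, or computes
#' biological metrics and applies [mibif_score()] to each site of an
#' abundance matrix. Sites with zero individuals are excluded from the
#' biological table with a warning and listed in the `excluded` attribute
#' (never given a fabricated score).
#'
#' @param chem data.frame with `site_id` plus the chemistry columns.
#' @param criteria,bands as for the per-site scorers.
#' @return data.frame: site_id, each metric value, each score, `total`,
#'   `health_class`.
#' @export
mwpi_table <- function(chem, criteria = default_mwpi_criteria(),
                       bands = default_mwpi_bands()) {
  rows <- lapply(seq_len(nrow(chem)), function(i) {
    r <- mwpi_score(chem[i, names(criteria)], criteria, bands)
    data.frame(site_id = chem$site_id[i], t(r$values),
               t(stats::setNames(r$scores, paste0(names(r$scores), "_score"))),
               total = r$total, health_class = as.character(r$health_class))
  })
  do.call(rbind, rows)
}

#' @rdname mwpi_table
#' @param abund,guilds,anomalies as in [compute_biological_metrics()].
#' @export
mibif_table <- function(abund, guilds, anomalies = NULL,
                        criteria = default_mibif_criteria(),
                        bands = default_mibif_bands()) {
  zero_sites <- rownames(abund)[rowSums(abund) == 0]
  if (length(zero_sites) > 0) {
    warning("excluding zero-individual site(s) from mIBI-F: ",
            paste(zero_sites, collapse = ", "))
  }
  keep <- setdiff(rownames(abund), zero_sites)
  rows <- lapply(keep, function(s) {
    m <- compute_biological_metrics(abund, guilds, s, anomalies)
    r <- mibif_score(m, criteria, bands)
    data.frame(site_id = s, t(r$values),
               t(stats::setNames(r$scores, paste0(names(r$scores), "_score"))),
               total = r$total, health_class = as.character(r$health_class))
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- zero_sites
  out
}
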
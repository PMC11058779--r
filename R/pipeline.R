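#' Read and write the standard CSV interfaces
#'
#' Guild tables: `species_id,trophic,habitat,tolerance,native`. Abundance:
#' wide CSV, first column `site_id`, remaining columns species counts
#' (anomalies use the same shape). Chemistry and covariates: `site_id`
#' plus numeric columns.
#'
#' @param path CSV path.
#' @return the corresponding in-memory object.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
read_guild_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_guild_table(g)
}

#' @rdname csv_io
#' @export
read_abundance_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(names(tab)[1] == "site_id", "first column must be site_id")
  m <- as.matrix(tab[-1])
  rownames(m) <- as.character(tab$site_id)
  storage.mode(m) <- "numeric"
  validate_abundance(m)
  m
}

#' @rdname csv_io
#' @export
read_chemistry_csv <- function(path) {
  chem <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that("site_id" %in% names(chem), "chemistry needs a site_id column")
  chem
}

#' @rdname csv_io
#' @param catalog an `fe_catalog`.
#' @export
write_catalog_csv <- function(catalog, path) {
  out <- catalog
  out$members <- vapply(catalog$members, paste, "", collapse = ";")
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a scoring-criteria configuration
#'
#' JSON with one entry per metric (`direction`, `cut1`, `cut2`) plus
#' `bands` as ordered `[lo, hi, label]` triples; validated on load.
#'
#' @param path JSON path.
#' @return list with `criteria` (named [metric_criterion()] list) and
#'   `bands` ([health_bands()]).
#' @export
read_criteria <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(!is.null(raw$metrics) && !is.null(raw$bands),
              "criteria file needs 'metrics' and 'bands'")
  criteria <- lapply(raw$metrics, function(m) {
    metric_criterion(m$direction, m$cut1, m$cut2)
  })
  bands <- health_bands(data.frame(lo = as.numeric(raw$bands$lo),
                                   hi = as.numeric(raw$bands$hi),
                                   label = as.character(raw$bands$label)))
  list(criteria = criteria, bands = bands)
}

#' @rdname read_criteria
#' @param criteria named list of [metric_criterion()].
#' @param bands a [health_bands()].
#' @export
write_criteria <- function(criteria, bands, path) {
  obj <- list(
    metrics = lapply(criteria, function(cr) {
      list(direction = cr$direction, cut1 = cr$cut1, cut2 = cr$cut2)
    }),
    bands = data.frame(lo = bands$lo, hi = bands$hi,
                       label = as.character(bands$label))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Cross-validate a set of input tables
#'
#' Checks label consistency across the abundance matrix, guild table,
#' chemistry and covariates before any analysis: species covered by the
#' guild table, matching site sets, no duplicate ids, no negative counts.
#' All problems are collected and reported together (fail-fast with a
#' complete list).
#'
#' @param abund site x species matrix.
#' @param guilds guild table.
#' @param chem chemistry data.frame (`site_id` + variables).
#' @param covariates optional covariate data.frame (`site_id` + variables).
#' @return list `ok` (logical) and `errors` (character vector).
#' @export
validate_inputs <- function(abund, guilds, chem, covariates = NULL) {
  errors <- character(0)
  note <- function(...) errors <<- c(errors, paste0(...))
  gt <- try(validate_guild_table(guilds), silent = TRUE)
  if (inherits(gt, "try-error")) {
    note("guild table: ", attr(gt, "condition")$message)
  } else {
    orphans <- setdiff(colnames(abund), gt$species_id)
    if (length(orphans) > 0)
      note("abundance species absent from guild table: ",
           paste(orphans, collapse = ", "))
  }
  if (anyDuplicated(rownames(abund)))
    note("duplicated site rows in abundance: ",
         paste(unique(rownames(abund)[duplicated(rownames(abund))]),
               collapse = ", "))
  if (any(abund < 0)) note("negative abundance counts")
  if (any(abund != floor(abund))) note("non-integer abundance counts")
  chem_sites <- as.character(chem$site_id)
  if (anyDuplicated(chem_sites))
    note("duplicated site rows in chemistry: ",
         paste(unique(chem_sites[duplicated(chem_sites)]), collapse = ", "))
  miss <- setdiff(rownames(abund), chem_sites)
  if (length(miss) > 0)
    note("abundance sites missing from chemistry: ",
         paste(miss, collapse = ", "))
  if (!is.null(covariates)) {
    miss2 <- setdiff(rownames(abund), as.character(covariates$site_id))
    if (length(miss2) > 0)
      note("abundance sites missing from covariates: ",
           paste(miss2, collapse = ", "))
  }
  list(ok = length(errors) == 0, errors = errors)
}

# range-standardise columns to [0,1]; constant columns map to 0.5
range_standardise <- function(m) {
  out <- apply(m, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) rep(0.5, length(col)) else (col - rng[1]) / diff(rng)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Run the full stream-health assessment pipeline
#'
#' Executes, in order: input validation; mWPI scoring; Ward.D2 chemistry
#' clustering (cluster ids ordered by descending mean mWPI, so cluster 1 is
#' the cleanest); entity construction and abundance aggregation; mIBI-F
#' scoring; two NMDS ordinations (entity relative abundances, and mIBI-F
#' metric values range-standardised to `[0, 1]` — Bray-Curtis needs
#' non-negative commensurate features); regressions of ordination axes on
#' chemical health indicators; and the environmental correlation screen.
#' Zero-fish sites are excluded from biological stages only. Deterministic
#' given `seed`.
#'
#' @param abund,guilds,chem,covariates input tables (see [validate_inputs()]);
#'   `covariates` may be `NULL` to skip the screen.
#' @param anomalies optional anomaly matrix.
#' @param k number of spatial chemistry clusters (default 5).
#' @param nmds_k,nmds_starts,nmds_tol,seed ordination settings.
#' @param indicators chemistry columns regressed against the axes.
#' @param mwpi,mibif lists with `criteria` and `bands` (defaults shipped).
#' @param out_dir optional directory: result tables are written as CSV and
#'   the report as `report.json`.
#' @return list of class `sh_report` with all stage outputs and the
#'   decisions log.
#' @export
run_pipeline <- function(abund, guilds, chem, covariates = NULL,
                         anomalies = NULL, k = 5,
                         nmds_k = 2, nmds_starts = 20, nmds_tol = 1e-7,
                         seed = 1,
                         indicators = c("EC", "TSS", "BOD", "TP", "TN_TP",
                                        "Chl_a"),
                         mwpi = list(criteria = default_mwpi_criteria(),
                                     bands = default_mwpi_bands()),
                         mibif = list(criteria = default_mibif_criteria(),
                                      bands = default_mibif_bands()),
                         out_dir = NULL) {
  val <- validate_inputs(abund, guilds, chem, covariates)
  if (!val$ok) {
    stop_sh("input validation failed:\n  ",
            paste(val$errors, collapse = "\n  "),
            class = "streamhealth_validation_error")
  }
  decisions <- character(0)
  chem <- chem[match(rownames(abund), as.character(chem$site_id)), ]

  # chemical health + spatial clusters
  mwpi_tab <- mwpi_table(chem, mwpi$criteria, mwpi$bands)
  lchem <- log_transform_chem(chem, vars = intersect(CHEM_VARS, names(chem)))
  offs <- attr(lchem, "offsets")
  if (any(offs > 0)) {
    decisions <- c(decisions, paste0("log offsets (half min positive): ",
                                     paste(names(offs)[offs > 0], collapse = ", ")))
  }
  dend <- ward_cluster(stats::dist(lchem))
  clusters <- cut_tree(dend, k = k,
                       order_by = stats::setNames(mwpi_tab$total,
                                                  mwpi_tab$site_id))
  decisions <- c(decisions,
                 "clusters renumbered by descending mean mWPI (1 = cleanest)")

  # entities + biological index
  catalog <- build_entities(guilds)
  em <- entity_abundance(abund, catalog)
  mibif_tab <- mibif_table(abund, guilds, anomalies,
                           mibif$criteria, mibif$bands)
  bio_sites <- mibif_tab$site_id
  if (length(attr(mibif_tab, "excluded")) > 0) {
    decisions <- c(decisions,
                   paste0("zero-fish site(s) excluded from biological stages: ",
                          paste(attr(mibif_tab, "excluded"), collapse = ", ")))
  }

  # ordinations
  ra <- relative_abundance(em[bio_sites, , drop = FALSE],
                           scope = "per_site", digits = NULL)
  ord_fe <- nmds(bray_curtis(ra), k = nmds_k, n_starts = nmds_starts,
                 tol = nmds_tol, seed = seed)
  metric_cols <- grep("^M[0-9]", names(mibif_tab), value = TRUE)
  metric_cols <- setdiff(metric_cols, grep("_score$", metric_cols, value = TRUE))
  mm <- as.matrix(mibif_tab[metric_cols])
  rownames(mm) <- mibif_tab$site_id
  decisions <- c(decisions,
                 "mIBI-F metrics range-standardised to [0,1] before Bray-Curtis")
  ord_mibif <- nmds(bray_curtis(range_standardise(mm)), k = nmds_k,
                    n_starts = nmds_starts, tol = nmds_tol, seed = seed)

  # gradient statistics
  reg_fe <- regress_axes_on_indicators(ord_fe$points, chem, indicators)
  reg_mibif <- regress_axes_on_indicators(ord_mibif$points, chem, indicators)
  decisions <- c(decisions,
                 "chemical indicators log10-transformed before regression")
  screen <- NULL
  if (!is.null(covariates)) {
    cov <- covariates[match(bio_sites, as.character(covariates$site_id)), ]
    screen_tab <- data.frame(
      NMDS1_FE = ord_fe$points[bio_sites, 1],
      NMDS2_FE = ord_fe$points[bio_sites, 2],
      NMDS1_mIBIF = ord_mibif$points[bio_sites, 1],
      NMDS2_mIBIF = ord_mibif$points[bio_sites, 2],
      mIBIF = mibif_tab$total,
      mWPI = mwpi_tab$total[match(bio_sites, mwpi_tab$site_id)],
      cov[setdiff(names(cov), "site_id")]
    )
    screen <- environment_screen(screen_tab)
  }

  report <- structure(list(
    n_sites = nrow(abund), n_species = ncol(abund),
    clusters = clusters, dendrogram = dend, mwpi = mwpi_tab,
    mibif = mibif_tab, catalog = catalog, entity_abundance = em,
    ord_fe = ord_fe, ord_mibif = ord_mibif,
    regressions_fe = reg_fe, regressions_mibif = reg_mibif,
    screen = screen, seed = seed, k = k, decisions = decisions,
    version = as.character(utils::packageVersion("streamhealth"))
  ), class = "sh_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @rdname run_pipeline
#' @param report an `sh_report`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE)
  w(data.frame(site_id = names(report$clusters),
               cluster = as.integer(report$clusters)), "clusters.csv")
  w(report$mwpi, "mwpi.csv")
  w(report$mibif, "mibif.csv")
  write_catalog_csv(report$catalog, file.path(out_dir, "entity_catalog.csv"))
  w(dendrogram_merges(report$dendrogram), "dendrogram_merges.csv")
  write_dendrogram_newick(report$dendrogram,
                          file.path(out_dir, "dendrogram.nwk"))
  for (nm in c("ord_fe", "ord_mibif")) {
    ord <- report[[nm]]
    w(data.frame(site_id = rownames(ord$points), ord$points),
      paste0(nm, "_scores.csv"))
  }
  w(report$regressions_fe, "regressions_fe.csv")
  w(report$regressions_mibif, "regressions_mibif.csv")
  if (!is.null(report$screen)) w(as.data.frame(report$screen), "screen.csv")
  meta <- list(
    n_sites = report$n_sites, n_species = report$n_species,
    k = report$k, seed = report$seed, version = report$version,
    decisions = report$decisions,
    ordination = lapply(report[c("ord_fe", "ord_mibif")], function(o) {
      list(stress = o$stress, converged = o$converged,
           best_start = o$best_start, n_starts = o$n_starts,
           iterations = o$iterations)
    })
  )
  jsonlite::write_json(meta, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sh_report <- function(x, ...) {
  cat("streamhealth pipeline report\n")
  cat("  sites:", x$n_sites, "| species:", x$n_species,
      "| entities:", nrow(x$catalog), "| clusters: k =", x$k, "\n")
  cat("  NMDS stress: FE =", format(x$ord_fe$stress, digits = 4),
      "| mIBI-F =", format(x$ord_mibif$stress, digits = 4), "\n")
  cat("  decisions:\n")
  for (d in x$decisions) cat("   -", d, "\n")
  invisible(x)
}
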
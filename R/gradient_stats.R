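#' Pearson correlation with t-test p-value
#'
#' Pairwise-complete Pearson correlation; the p-value comes from the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n` (complete pairs used).
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "Pearson correlation needs at least 3 complete pairs")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for zero-variance input",
              class = "streamhealth_validation_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on a single predictor `x`, reporting the
#' slope, intercept, coefficient of determination and the two-sided slope
#' p-value. For simple OLS, `R^2` equals the squared Pearson correlation.
#'
#' @param x predictor; @param y response.
#' @param predictor,response names recorded in the result.
#' @return data.frame of class `sh_regression` with columns `predictor`,
#'   `response`, `slope`, `intercept`, `r_squared`, `p_value`, `n`; the
#'   fitted `lm` is kept in attribute `fit` (confidence bands via
#'   `predict(..., interval = "confidence")`).
#' @export
ols_simple <- function(x, y, predictor = "x", response = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "regression needs at least 3 complete pairs")
  assert_that(stats::sd(x) > 0, "zero predictor variance",
              class = "streamhealth_validation_error")
  fit <- stats::lm(y ~ x)
  if (stats::var(y) == 0) {
    # constant response: exact zero slope, nothing explained, no test
    out <- data.frame(predictor = predictor, response = response,
                      slope = 0, intercept = y[1], r_squared = 0,
                      p_value = NA_real_, n = length(x))
    attr(out, "fit") <- fit
    class(out) <- c("sh_regression", "data.frame")
    return(out)
  }
  sm <- summary(fit)
  out <- data.frame(predictor = predictor, response = response,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r_squared = sm$r.squared,
                    p_value = sm$coefficients[2, 4],
                    n = length(x))
  attr(out, "fit") <- fit
  class(out) <- c("sh_regression", "data.frame")
  out
}

#' Regress ordination site scores on chemical health indicators
#'
#' One simple linear regression per (axis, indicator) pair. Indicators are
#' log10-transformed first (offset rule of [log_transform_chem()]), the
#' standard normalising step for concentration data; set
#' `log_transform = FALSE` to regress on raw values.
#'
#' @param scores site x axis matrix (e.g. `$points` of [nmds()]).
#' @param chem chemistry data.frame with `site_id`.
#' @param indicators chemistry column names to use as predictors.
#' @param log_transform logical.
#' @return data.frame: axis, indicator, slope, intercept, r_squared,
#'   p_value, n, significance tier (`"p<0.001"`, `"p<0.05"`, `"ns"`), and
#'   a `transform` attribute recording whether logs were used.
#' @export
regress_axes_on_indicators <- function(scores, chem, indicators,
                                       log_transform = TRUE) {
  sites <- intersect(rownames(scores), as.character(chem$site_id))
  assert_that(length(sites) >= 3, "site sets barely overlap",
              class = "streamhealth_validation_error")
  chem <- chem[match(sites, as.character(chem$site_id)), ]
  pred <- if (log_transform) {
    log_transform_chem(chem, vars = indicators)
  } else {
    as.matrix(chem[indicators])
  }
  rows <- list()
  for (ax in colnames(scores)) {
    for (ind in indicators) {
      r <- ols_simple(pred[, ind], scores[sites, ax],
                      predictor = ind, response = ax)
      rows[[length(rows) + 1]] <-
        data.frame(axis = ax, indicator = ind, slope = r$slope,
                   intercept = r$intercept, r_squared = r$r_squared,
                   p_value = r$p_value, n = r$n)
    }
  }
  out <- do.call(rbind, rows)
  out$tier <- ifelse(out$p_value < 0.001, "p<0.001",
                     ifelse(out$p_value < 0.05, "p<0.05", "ns"))
  attr(out, "transform") <- if (log_transform) "log10" else "none"
  out
}

#' Correlation screen of ordination scores against environment
#'
#' Full pairwise-complete Pearson correlation matrix over the supplied
#' variables (ordination axes, index totals, elevation, stream order,
#' land-use proportions, mWPI score ...), with a significance mask at
#' `alpha`. Constant columns are excluded with a warning. No multiplicity
#' correction by default (the screen reports raw p-values); Holm correction
#' is available.
#'
#' @param tab data.frame of numeric site-level variables.
#' @param alpha significance level for the mask (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return list of class `sh_corscreen`: matrices `r`, `p`, `n`, logical
#'   `significant`, and `dropped` (constant columns).
#' @export
environment_screen <- function(tab, alpha = 0.05,
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  num <- tab[vapply(tab, is.numeric, TRUE)]
  sds <- vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0)
  dropped <- names(num)[!is.na(sds) & sds == 0]
  if (length(dropped) > 0) {
    warning("excluding constant column(s): ", paste(dropped, collapse = ", "))
    num <- num[setdiff(names(num), dropped)]
  }
  vars <- names(num)
  p <- r <- nmat <- matrix(NA_real_, length(vars), length(vars),
                           dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    r[i, i] <- 1; p[i, i] <- 0
    nmat[i, i] <- sum(is.finite(num[[i]]))
    for (j in seq_along(vars)) {
      if (j <= i) next
      pc <- pearson(num[[i]], num[[j]])
      r[i, j] <- r[j, i] <- pc$r
      p[i, j] <- p[j, i] <- pc$p
      nmat[i, j] <- nmat[j, i] <- pc$n
    }
  }
  if (adjust == "holm") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = nmat,
                 significant = p < alpha & !diag(TRUE, length(vars)),
                 alpha = alpha, adjust = adjust, dropped = dropped),
            class = "sh_corscreen")
}

#' @export
print.sh_corscreen <- function(x, ...) {
  cat("Correlation screen:", ncol(x$r), "variables, alpha =", x$alpha,
      if (x$adjust != "none") paste0("(", x$adjust, "-adjusted)"), "\n")
  shown <- round(x$r, 2)
  shown[!x$significant] <- NA
  diag(shown) <- 1
  print(shown, na.print = ".")
  invisible(x)
}

#' Long-format view of a correlation screen
#'
#' @param x an `sh_corscreen`.
#' @param ... unused.
#' @return data.frame `var1, var2, r, p, n, significant` (upper triangle).
#' @export
as.data.frame.sh_corscreen <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(var1 = rownames(x$r)[idx[, 1]],
             var2 = colnames(x$r)[idx[, 2]],
             r = x$r[idx], p = x$p[idx], n = x$n[idx],
             significant = x$significant[idx])
}
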
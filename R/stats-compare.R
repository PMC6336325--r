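#' Regional means and the long-format regional table
#'
#' `regional_means` averages a map over each atlas region. The regional table
#' is the long format feeding every agreement statistic: one row per
#' (subject, region, measure) with the subject's group label.
#'
#' @param img a `static_image`.
#' @param atlas a `pet_atlas`.
#' @return `regional_means` returns a named numeric vector (atlas table
#'   order).
#' @export
regional_means <- function(img, atlas) {
  stopifnot(inherits(img, "static_image"), inherits(atlas, "pet_atlas"))
  if (!identical(as.integer(dim(atlas$labels)), as.integer(dim(img$voxels))))
    stop("atlas grid must match the map")
  v <- vapply(atlas$table$label,
              function(l) mean(img$voxels[atlas$labels == l], na.rm = TRUE),
              numeric(1))
  names(v) <- atlas$table$name
  v
}

#' @rdname regional_means
#' @param maps a list of entries, each a list with elements `subject`,
#'   `group`, `measure` and `map` (a `static_image`).
#' @return `build_regional_table` returns a data.frame with columns
#'   `subject`, `group`, `region`, `measure`, `value`.
#' @export
build_regional_table <- function(maps, atlas) {
  if (length(maps) < 1L) stop("no maps supplied")
  rows <- lapply(maps, function(e) {
    if (is.null(e$map)) stop("missing map for a (subject, measure) entry")
    v <- regional_means(e$map, atlas)
    data.frame(subject = e$subject, group = e$group,
               region = names(v), measure = e$measure, value = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab[, c("subject", "region", "measure")]))
    stop("duplicate (subject, region, measure) rows")
  if (any(!is.finite(tab$value))) stop("non-finite regional values")
  rownames(tab) <- NULL
  tab
}

#' Ordinary least-squares regression between two regional measures
#'
#' Simple linear regression `y = slope * x + intercept` with the two-sided
#' slope p-value, Pearson correlation and R-squared. Used to relate R1 or
#' ePIB (dependent) to FDG SUVR (independent), pooling subject-region pairs.
#'
#' @param x independent values (must not be constant), `n >= 3`.
#' @param y dependent values, matched length.
#' @return A `regression_result`: `slope`, `intercept`, `r_squared`,
#'   `pearson_r`, `p_value`, `n`.
#' @export
fit_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("constant x: slope is not identifiable")
  if (stats::sd(y) == 0) {
    res <- list(slope = 0, intercept = mean(y), r_squared = 0,
                pearson_r = 0, p_value = 1, n = n)
    return(structure(res, class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(fit)
  p <- sm$coefficients[2L, 4L]
  if (!is.finite(p)) p <- 0  # exact fit: zero residual variance
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = sm$r.squared,
                 pearson_r = stats::cor(x, y),
                 p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression> slope=%.3f intercept=%.3f R2=%.3f r=%.3f p=%.3g n=%d\n",
    x$slope, x$intercept, x$r_squared, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `test - reference` summarised by their mean (bias), sample
#' standard deviation and the 95% limits of agreement at
#' `bias +/- 1.96 * sd`, plus a trend regression of the differences on the
#' reference values (proportional-bias check).
#'
#' @param reference reference-method values (typically FDG SUVR).
#' @param test test-method values, matched length `n >= 3`.
#' @return A `bland_altman_result`: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `trend` (a `regression_result` or `NULL` if the reference is constant),
#'   `n`.
#' @export
bland_altman <- function(reference, test) {
  reference <- as.numeric(reference); test <- as.numeric(test)
  if (length(reference) != length(test)) stop("length mismatch")
  if (length(reference) < 3L) stop("need at least 3 paired observations")
  d <- test - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  trend <- tryCatch(fit_regression(reference, d), error = function(e) NULL)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 trend = trend, n = length(d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> bias=%.4f sd=%.4f LoA=[%.4f, %.4f] n=%d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Per-region two-sample t-tests with FDR correction
#'
#' For one measure, tests each region for a group difference with a
#' two-sample t-test (pooled variance by default, Welch optional) and applies
#' Benjamini-Hochberg false-discovery-rate correction across regions. The
#' t statistic is positive when the first group's mean is larger.
#'
#' @param table a regional table from [build_regional_table()].
#' @param measure measure name to test.
#' @param groups optional length-2 character vector fixing group order;
#'   defaults to the sorted unique group labels.
#' @param var_equal pooled-variance (Student) t-test if `TRUE` (default).
#' @return data.frame with columns `region`, `t`, `p`, `p_fdr`,
#'   `mean_diff`, `n1`, `n2`.
#' @export
group_ttests_fdr <- function(table, measure, groups = NULL, var_equal = TRUE) {
  tab <- table[table$measure == measure, , drop = FALSE]
  if (nrow(tab) == 0L) stop(sprintf("no rows for measure '%s'", measure))
  if (is.null(groups)) groups <- sort(unique(tab$group))
  if (length(groups) != 2L)
    stop("exactly two groups are required")
  regions <- unique(tab$region)
  res <- lapply(regions, function(rg) {
    x <- tab$value[tab$region == rg & tab$group == groups[1L]]
    y <- tab$value[tab$region == rg & tab$group == groups[2L]]
    if (length(x) < 2L || length(y) < 2L)
      stop("both groups need at least 2 subjects per region")
    tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # (near-)constant data in both groups, e.g. the reference region of
      # reference-normalized maps
      scale <- max(abs(c(x, y)), 1e-12)
      d <- mean(x) - mean(y)
      t <- if (abs(d) <= 1e-8 * scale) 0 else sign(d) * Inf
      p <- if (t == 0) 1 else 0
    } else {
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(region = rg, t = t, p = p,
               mean_diff = mean(x) - mean(y),
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("region", "t", "p", "p_fdr", "mean_diff", "n1", "n2")]
}
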
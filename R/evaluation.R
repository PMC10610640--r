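#' Ordinary least squares fit between two paired samples
#'
#' Pairs with a missing member are dropped (and counted) before fitting.
#' `r_squared = 1 - SSE/SST`. A response with zero variance yields
#' `r_squared = 0` with a warning; a predictor with zero variance is an
#' error. The p-value comes from the standard F statistic and is
#' informational.
#'
#' @param x,y Equal-length numeric vectors.
#' @return An object of class `regression_fit` with `slope`, `intercept`,
#'   `r_squared`, `n`, `pairs_dropped`, `p_value`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs, got ", n)
  if (stats::var(x) == 0) stop("zero variance in x: slope is undefined")
  if (stats::var(y) == 0) {
    warning("zero variance in y: r_squared defined as 0")
    fit <- list(slope = 0, intercept = y[1], r_squared = 0, n = n,
                pairs_dropped = dropped, p_value = NA_real_)
    return(structure(fit, class = "regression_fit"))
  }
  m <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(m)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  p <- if (n > 2) {
    f <- (sst - sse) / (sse / (n - 2))
    stats::pf(f, 1, n - 2, lower.tail = FALSE)
  } else NA_real_
  structure(list(slope = unname(stats::coef(m)[2]),
                 intercept = unname(stats::coef(m)[1]),
                 r_squared = r2, n = n, pairs_dropped = dropped,
                 p_value = p),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4g x + %.4g, R2 = %.3f (n = %d, %d pair(s) dropped, p = %.3g)\n",
              x$slope, x$intercept, x$r_squared, x$n, x$pairs_dropped,
              x$p_value))
  invisible(x)
}

#' Pairwise regression comparison of per-plant records
#'
#' Pairs datasets by `plant_id` (the same grid is applied to every data
#' model, so ids are comparable), drops plants missing in either member of a
#' pair (empty cells, missing plants), and fits [fit_linear()] for every
#' requested pair.
#'
#' @param records Named list of per-plant data frames
#'   ([per_plant_cwsi()] or [plant_volumes()] output).
#' @param metric Column to compare (`"mean_cwsi"` or `"hull_volume"`).
#' @param pairs Optional 2-column character matrix of dataset names; default
#'   is every unordered pair.
#' @return An object of class `comparison_report`: `fits` and scatter-pair
#'   tables keyed `"x vs y"`.
#' @export
compare_datasets <- function(records, metric = "mean_cwsi", pairs = NULL) {
  if (length(records) < 2 || is.null(names(records)))
    stop("records must be a named list of at least 2 datasets")
  for (nm in names(records)) {
    if (!all(c("plant_id", metric) %in% names(records[[nm]])))
      stop(sprintf("dataset '%s' lacks plant_id or '%s'", nm, metric))
  }
  if (is.null(pairs)) {
    nms <- names(records)
    pairs <- t(utils::combn(nms, 2))
  }
  fits <- list()
  tables <- list()
  for (r in seq_len(nrow(pairs))) {
    xa <- records[[pairs[r, 1]]]; yb <- records[[pairs[r, 2]]]
    ids <- intersect(xa$plant_id, yb$plant_id)
    key <- paste(pairs[r, 1], "vs", pairs[r, 2])
    if (!length(ids))
      stop("no overlapping plant ids between '", pairs[r, 1], "' and '",
           pairs[r, 2], "'")
    xv <- xa[[metric]][match(ids, xa$plant_id)]
    yv <- yb[[metric]][match(ids, yb$plant_id)]
    ok <- is.finite(xv) & is.finite(yv)
    tab <- data.frame(plant_id = ids[ok], x = xv[ok], y = yv[ok])
    fits[[key]] <- fit_linear(xv, yv)
    tables[[key]] <- tab
  }
  structure(list(fits = fits, pairs = tables, metric = metric),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> metric '%s', %d pair(s)\n", x$metric,
              length(x$fits)))
  for (key in names(x$fits)) {
    f <- x$fits[[key]]
    cat(sprintf("  %-40s slope %.3f  R2 %.3f  n %d\n", key, f$slope,
                f$r_squared, f$n))
  }
  invisible(x)
}

#' Write a comparison report as a delimited table
#'
#' Intercepts are fitted, not forced; p-values are informational
#' (F statistic).
#'
#' @param report A [compare_datasets()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  rows <- lapply(names(report$fits), function(key) {
    f <- report$fits[[key]]
    data.frame(pair = key, metric = report$metric, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared, n = f$n,
               pairs_dropped = f$pairs_dropped, p_value = f$p_value)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
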
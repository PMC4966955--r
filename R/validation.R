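#' Energy-balance closure correction of eddy-covariance LE
#'
#' Eddy-covariance towers typically under-close the surface energy
#' budget: \eqn{H + LE < R_n - G}. The Bowen-ratio-preserving correction
#' rescales both turbulent fluxes by the closure factor, giving
#' \deqn{LE = \frac{R_n - G}{LE_{ori} + H_{ori}} \times LE_{ori}.}
#' The corrected fluxes close the budget exactly
#' (\eqn{H_{corr} + LE_{corr} = R_n - G}) and preserve the Bowen ratio
#' \eqn{H_{ori}/LE_{ori}}.
#'
#' Records with \eqn{H_{ori} + LE_{ori} = 0} (or any non-finite term)
#' have an undefined correction: they are returned as \code{NA} with a
#' warning — excluded, never silently zeroed. If every record is
#' undefined an error is raised.
#'
#' @param Rn net radiation (W/m2), or a tower \code{data.frame} as
#'   returned by \code{\link{read_towers}} (columns \code{Rn}, \code{G},
#'   \code{H_ori}, \code{LE_ori}), in which case the remaining arguments
#'   are ignored and the frame is returned with an \code{LE_corr} column.
#' @param G ground heat flux (W/m2).
#' @param H_ori,LE_ori uncorrected sensible and latent heat flux (W/m2).
#' @return corrected LE (W/m2), vectorised; or the augmented
#'   \code{data.frame}.
#' @examples
#' closure_correct(Rn = 100, G = 10, H_ori = 40, LE_ori = 40)  # 45
#' @export
closure_correct <- function(Rn, G = NULL, H_ori = NULL, LE_ori = NULL) {
  if (is.data.frame(Rn)) {
    df <- Rn
    df$LE_corr <- closure_correct(df$Rn, df$G, df$H_ori, df$LE_ori)
    return(df)
  }
  s <- H_ori + LE_ori
  bad <- !is.finite(Rn) | !is.finite(G) | !is.finite(s) | s == 0
  if (all(bad))
    stop("undefined closure correction: H_ori + LE_ori is zero or missing for every record")
  le <- (Rn - G) / s * LE_ori
  if (any(bad)) {
    le[bad] <- NA_real_
    warning(sprintf("%d record(s) with undefined closure correction excluded (set to NA)",
                    sum(bad)))
  }
  le
}

#' Composite a daily series into 8-day block means
#'
#' Aggregates a regularly spaced daily series into consecutive
#' non-overlapping 8-day means, matching the compositing convention of
#' 8-day satellite LE products. Blocks are anchored at the series start
#' by default; with \code{modis_calendar = TRUE} (and \code{dates}
#' supplied) they anchor at day-of-year 1, 9, 17, ... so composites line
#' up with the MODIS product calendar. The final block may be shorter.
#' Block means skip missing days; a fully missing block is \code{NA}.
#'
#' @param x numeric daily series (may contain \code{NA}).
#' @param dates optional \code{Date} vector (required for
#'   \code{modis_calendar}).
#' @param block block length in days (default 8).
#' @param modis_calendar anchor blocks on the day-of-year 1, 9, ... grid.
#' @return numeric vector of block means, named by the first day index
#'   (or date) of each block.
#' @export
composite_8day <- function(x, dates = NULL, block = 8L,
                           modis_calendar = FALSE) {
  if (length(x) == 0L) stop("validation error: empty series")
  if (modis_calendar) {
    if (is.null(dates)) stop("modis_calendar requires `dates`")
    doy <- as.integer(format(dates, "%j"))
    year <- format(dates, "%Y")
    id <- paste(year, sprintf("%03d", ((doy - 1L) %/% block) * block + 1L), sep = "-")
  } else {
    id <- (seq_along(x) - 1L) %/% block
  }
  id <- factor(id, levels = unique(id))
  out <- tapply(x, id, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  means <- as.vector(out)
  names(means) <- if (modis_calendar) levels(id)
    else as.character(seq(1L, length(x), by = block))
  means
}

#' Agreement metrics between a predicted and an observed series
#'
#' Pairs with either side missing are excluded. \code{r_squared} is the
#' squared Pearson correlation (not a regression 1 - SSE/SST), so it
#' measures co-variation and is insensitive to additive bias;
#' \code{bias} is \code{mean(predicted - observed)} and \code{rmse} the
#' root mean squared difference, both in the data's units (W/m2 for LE).
#' \code{r_squared} is \code{NA} when either series is constant.
#'
#' @param predicted,observed equal-length numeric series with at least 2
#'   complete pairs.
#' @param group label for the report row (default \code{"all"}).
#' @return a one-row \code{data.frame} of class \code{"metric_report"}
#'   with columns \code{group}, \code{n}, \code{r_squared}, \code{bias},
#'   \code{rmse}.
#' @export
compute_metrics <- function(predicted, observed, group = "all") {
  if (length(predicted) != length(observed))
    stop("validation error: predicted and observed lengths differ")
  ok <- is.finite(predicted) & is.finite(observed)
  p <- predicted[ok]; o <- observed[ok]
  if (length(p) < 2L)
    stop("insufficient data: fewer than 2 complete pairs")
  r2 <- if (stats::sd(p) > 0 && stats::sd(o) > 0)
    stats::cor(p, o)^2 else NA_real_
  structure(data.frame(group = group, n = length(p), r_squared = r2,
                       bias = mean(p - o),
                       rmse = sqrt(mean((p - o)^2)),
                       stringsAsFactors = FALSE),
            class = c("metric_report", "data.frame"))
}

#' Metrics grouped by biome
#'
#' One \code{\link{compute_metrics}} report per biome present in the
#' data, plus a pooled \code{"all"} row. Biomes with fewer than 2
#' complete pairs are skipped with a warning.
#'
#' @param predicted,observed paired series.
#' @param biome character vector of biome tags, one per pair.
#' @return a \code{data.frame} of class \code{"metric_report"}, one row
#'   per group.
#' @export
group_metrics <- function(predicted, observed, biome) {
  if (length(biome) != length(predicted))
    stop("validation error: biome tags must cover every pair")
  rows <- list()
  for (b in unique(biome)) {
    sel <- biome == b
    rows[[b]] <- tryCatch(compute_metrics(predicted[sel], observed[sel], group = b),
                          error = function(e) {
                            warning(sprintf("biome %s skipped: %s", b, conditionMessage(e)))
                            NULL
                          })
  }
  rows[["all"]] <- compute_metrics(predicted, observed, group = "all")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("LE validation metrics (W/m2):\n")
  df <- as.data.frame(x)
  df$r_squared <- round(df$r_squared, digits)
  df$bias <- round(df$bias, digits)
  df$rmse <- round(df$rmse, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write a metric report as CSV
#'
#' @param report a \code{\link{compute_metrics}} /
#'   \code{\link{group_metrics}} result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
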
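#' Locally weighted scatterplot smoothing (tricube, local linear)
#'
#' At each evaluation point, the `span` fraction of nearest points (by
#' x-distance) receives tricube weights `(1 - (d/h)^3)^3`, with `h` the
#' distance to the farthest in-window point, and a weighted linear regression
#' is solved in closed form; the smoothed value is its prediction at the
#' evaluation point. With `span = 1` every window spans all points. On
#' exactly collinear data the smoother reproduces the line; on constant `y`
#' it is constant. Degenerate windows (a single distinct x with positive
#' weight) fall back to the weighted mean.
#'
#' @param x,y Numeric vectors, at least 3 points.
#' @param span Fraction of points per local window, in (0, 1].
#' @param eval_x Points at which to evaluate (default `x`).
#' @return data.frame with columns `x` and `fitted`, ordered by `x`.
#' @export
#' @examples
#' p <- lowess_tricube(1:10, (1:10) * 2 + 1)
#' all.equal(p$fitted, (1:10) * 2 + 1)
lowess_tricube <- function(x, y, span = 1.0, eval_x = x) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite points to smooth", call. = FALSE)
  q <- min(n, max(2L, as.integer(ceiling(span * n))))
  fitted <- vapply(eval_x, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) return(mean(y[d == 0]))
    w <- numeric(n)
    inw <- d < h
    w[inw] <- (1 - (d[inw] / h)^3)^3
    sw <- sum(w)
    xb <- sum(w * x) / sw
    yb <- sum(w * y) / sw
    sxx <- sum(w * (x - xb)^2)
    if (sxx <= .Machine$double.eps * sum(w * x^2)) return(yb)
    yb + sum(w * (x - xb) * (y - yb)) / sxx * (x0 - xb)
  }, numeric(1))
  out <- data.frame(x = eval_x, fitted = fitted)
  out[order(out$x), , drop = FALSE]
}

#' Relative-risk vs attributable-death scatter data
#'
#' The machine form of the RR-against-log-AD comparison: one point per cause
#' with its RR and log10 attributable deaths, plus a LOWESS smooth
#' (span 1.0 by default). Causes are kept only when significant (Wald 95\% CI
#' excluding 1) and with positive AD (the log scale requires it); exclusions
#' are reported in the `excluded` attribute.
#'
#' @param results Sensitivity/report table with columns `cause`, `rr`,
#'   `ci_low`, `ci_high`, `ad` (e.g. one stratum of [run_sensitivity()]).
#' @param span LOWESS span fraction.
#' @return data.frame `cause`, `rr`, `log10_ad`, `smooth`; attribute
#'   `excluded` lists dropped causes with reasons.
#' @export
rr_ad_scatter <- function(results, span = 1.0) {
  need <- c("cause", "rr", "ci_low", "ci_high", "ad")
  stopifnot(all(need %in% names(results)))
  sig <- !is.na(results$rr) & (results$ci_low > 1 | results$ci_high < 1)
  pos <- !is.na(results$ad) & results$ad > 0
  keep <- sig & pos
  excluded <- data.frame(
    cause = results$cause[!keep],
    reason = ifelse(!sig[!keep], "CI includes 1 (non-significant)",
                    "non-positive attributable deaths"))
  pts <- results[keep, , drop = FALSE]
  if (nrow(pts) < 3L) {
    stop("fewer than 3 significant causes with positive attributable deaths",
         call. = FALSE)
  }
  sm <- lowess_tricube(pts$rr, log10(pts$ad), span = span, eval_x = pts$rr)
  out <- data.frame(cause = pts$cause, rr = pts$rr, log10_ad = log10(pts$ad),
                    smooth = sm$fitted[match(pts$rr, sm$x)])
  attr(out, "excluded") <- excluded
  out
}

#' Write the standard report files for a multi-cause analysis
#'
#' Fits each cause at a single model specification, attributes deaths, and
#' writes: `attribution.csv` (per-cause RR, CI, AD and both proportion
#' columns, unrounded plus 2-dp display values), `forest.csv` (plotting-ready
#' RR and CI per cause), `rr_ad.csv` (the RR vs log10-AD scatter with its
#' LOWESS smooth, when at least 3 causes qualify), and `manifest.json`
#' (package version, model settings, and an MD5 digest per input file so any
#' byte change in the inputs changes the manifest). Every display number is
#' derived from the stored unrounded values — there is no report-only
#' arithmetic.
#'
#' @param exposure Exposure data.frame.
#' @param mortality Wide mortality data.frame.
#' @param out_dir Output directory (created if absent).
#' @param causes Causes to fit.
#' @param input_paths Optional character vector of input file paths to digest
#'   into the manifest.
#' @param span LOWESS span for the RR-AD smooth.
#' @inheritParams heat_model
#' @return Invisibly, a list with the attribution table, the forest table,
#'   the scatter table (or `NULL`) and the manifest.
#' @export
make_report <- function(exposure, mortality, out_dir,
                        causes = setdiff(names(mortality), "date"),
                        percentile = 90, lag = "lag0",
                        confounders = c("humidity", "pressure", "dow", "trend"),
                        trend_df_per_year = 1, season = 5:9,
                        quantile_type = 7, span = 1.0,
                        input_paths = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_sensitivity(exposure, mortality, causes = causes, lags = lag,
                         percentiles = percentile,
                         confounders = confounders,
                         trend_df_per_year = trend_df_per_year,
                         season = season, quantile_type = quantile_type)
  tab$ad_rounded <- round(tab$ad)
  tab$pct_of_cause_display <- round_half_up(tab$pct_of_cause, 2)
  tab$pct_of_total_display <- round_half_up(tab$pct_of_total, 2)
  utils::write.csv(tab, file.path(out_dir, "attribution.csv"),
                   row.names = FALSE)
  forest <- tab[, c("cause", "rr", "ci_low", "ci_high")]
  utils::write.csv(forest, file.path(out_dir, "forest.csv"), row.names = FALSE)
  scatter <- tryCatch(rr_ad_scatter(tab, span = span), error = function(e) NULL)
  if (!is.null(scatter)) {
    utils::write.csv(scatter, file.path(out_dir, "rr_ad.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "heatmort",
    version = as.character(utils::packageVersion("heatmort")),
    settings = list(percentile = percentile, lag = lag,
                    confounders = confounders,
                    trend_df_per_year = trend_df_per_year,
                    season = season, quantile_type = quantile_type,
                    span = span, causes = causes),
    inputs = if (length(input_paths)) {
      data.frame(path = input_paths,
                 md5 = unname(tools::md5sum(input_paths)))
    } else NULL)
  writeLines(manifest_json(manifest), file.path(out_dir, "manifest.json"))
  invisible(list(attribution = tab, forest = forest, scatter = scatter,
                 manifest = manifest))
}

# minimal JSON emitter for the manifest (strings, numbers, vectors, lists,
# data.frames); avoids a hard dependency for one write
manifest_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.null(x)) return("null")
  if (is.data.frame(x)) {
    rows <- vapply(seq_len(nrow(x)), function(i) {
      manifest_json(as.list(x[i, , drop = FALSE]), indent + 1)
    }, character(1))
    return(paste0("[", paste(rows, collapse = ", "), "]"))
  }
  if (is.list(x)) {
    items <- vapply(names(x), function(nm) {
      paste0(pad, '  "', esc(nm), '": ', manifest_json(x[[nm]], indent + 1))
    }, character(1))
    return(paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste(vapply(x, manifest_json, character(1)),
                             collapse = ", "), "]"))
  }
  if (is.character(x)) paste0('"', esc(x), '"') else format(x, digits = 15)
}
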
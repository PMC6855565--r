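# Meta-evaluation of metrics: the replicate x signal-level output matrix,
# rank correlation with the signal, false-positive signal estimation from
# the per-level median curve, plots and summary tables.

#' Score a dilution series with one metric
#'
#' `Output[i, j] = Metric(T, APS_ij)` for every replicate `i` and signal
#' level `j`.  A metric failure on a single cell is recorded as missing and
#' logged; more than 10% missing cells aborts the run.
#'
#' @param g an `ads_ontology`.
#' @param truth the truth table the series was generated from.
#' @param series an `ads_series`.
#' @param metric a registry row or metric name (see [score_metric()]).
#' @param ic_table an `ads_ic` table for IC-weighted metrics.
#' @param ... passed on to [score_metric()] (e.g. `n_bins`, `universe`).
#' @return an `ads_output` matrix (replicates x signal levels) with the
#'   signal levels as an attribute.
#' @export
output_matrix <- function(g, truth, series, metric, ic_table = NULL, ...) {
  SR <- series$signal_levels
  N <- length(series$sets)
  out <- matrix(NA_real_, N, length(SR),
                dimnames = list(paste0("rep", seq_len(N)), format(SR)))
  for (i in seq_len(N)) {
    for (j in seq_along(SR)) {
      val <- tryCatch(
        score_metric(g, truth, series$sets[[i]][[j]], metric,
                     ic_table = ic_table, ...),
        error = function(e) {
          warning("metric failed on cell (", i, ", ", j, "): ",
                  conditionMessage(e))
          NA_real_
        })
      out[i, j] <- val
    }
  }
  if (mean(is.na(out)) > 0.1) {
    stop("more than 10% of output cells missing; aborting")
  }
  attr(out, "signal_levels") <- SR
  class(out) <- c("ads_output", class(out))
  out
}

#' Rank correlation between metric output and signal level
#'
#' Spearman (default) correlation between all output cells, pooled, and
#' their signal levels.  Missing cells are excluded; zero variance in the
#' scores yields 0 with a warning.
#'
#' @param out an `ads_output` matrix.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return correlation in `[-1, 1]`.
#' @export
rank_correlation <- function(out, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  SR <- attr(out, "signal_levels")
  stopifnot(length(unique(SR)) >= 2L)
  x <- rep(SR, each = nrow(out))
  y <- as.vector(unclass(out))
  keep <- !is.na(y)
  if (stats::sd(y[keep]) == 0) {
    warning("zero variance in metric output; rank correlation set to 0")
    return(0)
  }
  stats::cor(x[keep], y[keep], method = method)
}

#' Signal level at which an FP-set score crosses the median curve
#'
#' Builds the piecewise-linear curve of per-signal-level medians and
#' returns the largest signal at which the horizontal line at `fp_score`
#' crosses it (linear interpolation between adjacent levels).  A score
#' below all medians maps to 0, above all medians to 1: the estimate is
#' confined to the observed signal range.
#'
#' @param fp_score the metric score of the FP set.
#' @param out an `ads_output` matrix for the same metric.
#' @return a signal estimate in `[0, 1]`.
#' @export
fp_signal <- function(fp_score, out) {
  SR <- attr(out, "signal_levels")
  med <- apply(unclass(out), 2L, stats::median, na.rm = TRUE)
  ord <- order(SR)
  x <- SR[ord]; m <- med[ord]
  if (fp_score < min(m)) return(0)
  if (fp_score > max(m)) return(1)
  best <- NA_real_
  for (s in rev(seq_len(length(x) - 1L))) {   # scan from the high-signal end
    lo <- m[[s]]; hi <- m[[s + 1L]]
    if ((fp_score - lo) * (fp_score - hi) <= 0) {
      if (hi == lo) {
        best <- x[[s + 1L]]
      } else {
        frac <- (fp_score - lo) / (hi - lo)
        best <- x[[s]] + frac * (x[[s + 1L]] - x[[s]])
      }
      break
    }
  }
  if (is.na(best)) best <- 0
  min(max(best, 0), 1)
}

#' False-positive signal: the worst case over all FP sets
#'
#' @param per_fp named numeric vector of per-FP-set signal estimates.
#' @return the maximum, i.e. the most optimistic signal any decoy reached.
#' @export
fps <- function(per_fp) {
  if (length(per_fp) == 0L) stop("no FP-set signals supplied")
  max(per_fp)
}

#' Evaluate a battery of metrics on a series plus FP sets
#'
#' For each metric: computes the output matrix, its rank correlation with
#' the signal levels, scores each FP set and converts those scores to
#' signal estimates via the median curve.
#'
#' @param g an `ads_ontology`.
#' @param truth the truth table.
#' @param series an `ads_series`.
#' @param metrics registry rows to run (default: the full battery).
#' @param fp_sets named list of FP `ads_predictions` sets (may be empty).
#' @param ic_table an `ads_ic` table.
#' @param ... passed to [score_metric()].
#' @return list with `summary` (data.frame: metric, RC, FPS, per-set
#'   signals) and `outputs` (named list of `ads_output` matrices).
#' @export
evaluate_metrics <- function(g, truth, series, metrics = metric_registry(),
                             fp_sets = list(), ic_table = NULL, ...) {
  summaries <- NULL
  outputs <- list()
  for (r in seq_len(nrow(metrics))) {
    spec <- metrics[r, ]
    out <- output_matrix(g, truth, series, spec, ic_table = ic_table, ...)
    outputs[[spec$name]] <- out
    rc <- rank_correlation(out)
    per_fp <- vapply(fp_sets, function(fp) {
      sc <- score_metric(g, truth, fp, spec, ic_table = ic_table, ...)
      fp_signal(sc, out)
    }, numeric(1))
    row <- data.frame(metric = spec$name, RC = rc,
                      FPS = if (length(per_fp)) fps(per_fp) else NA_real_,
                      stringsAsFactors = FALSE)
    for (nm in names(per_fp)) row[[paste0("fp_", nm)]] <- per_fp[[nm]]
    summaries <- rbind(summaries, row)
  }
  list(summary = summaries, outputs = outputs)
}

#' Dilution boxplot with FP-set lines
#'
#' One box per signal level (signal descending left to right), a horizontal
#' line per FP set, and the RC / FPS values in the title.
#'
#' @param out an `ads_output` matrix.
#' @param fp_lines named numeric vector of FP-set metric scores.
#' @param file output file; `.png`, `.svg` or `.pdf` decide the device.
#' @param main plot title prefix (usually the metric name).
#' @return `file`, invisibly.
#' @export
plot_dilution <- function(out, fp_lines = numeric(), file, main = "") {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 600),
         svg = grDevices::svg(file, width = 9, height = 6),
         pdf = grDevices::pdf(file, width = 9, height = 6),
         stop("unsupported plot format: ", ext))
  on.exit(grDevices::dev.off())
  SR <- attr(out, "signal_levels")
  rc <- rank_correlation(out)
  fpv <- if (length(fp_lines)) {
    vapply(fp_lines, fp_signal, numeric(1), out = out)
  } else numeric()
  ttl <- sprintf("%s  RC = %.3f%s", main, rc,
                 if (length(fpv)) sprintf("  FPS = %.3f", max(fpv)) else "")
  cols <- c(naive = "red", small = "blue", random = "darkgreen")
  graphics::boxplot(unclass(out), names = format(SR), xlab = "ADS signal",
                    ylab = "metric score", main = ttl)
  for (nm in names(fp_lines)) {
    graphics::abline(h = fp_lines[[nm]],
                     col = if (nm %in% names(cols)) cols[[nm]] else "grey40",
                     lwd = 2)
  }
  invisible(file)
}

#' RC-versus-FPS scatter of the evaluated metrics
#'
#' @param summary the `summary` data.frame from [evaluate_metrics()].
#' @param file output figure path (`.png`/`.svg`/`.pdf`).
#' @return `file`, invisibly.
#' @export
plot_rc_fps <- function(summary, file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 800, height = 800),
         svg = grDevices::svg(file, width = 8, height = 8),
         pdf = grDevices::pdf(file, width = 8, height = 8),
         stop("unsupported plot format: ", ext))
  on.exit(grDevices::dev.off())
  graphics::plot(summary$FPS, summary$RC, xlim = c(0, 1),
                 xlab = "false-positive signal (FPS)",
                 ylab = "rank correlation (RC)", pch = 19, col = "grey30")
  graphics::text(summary$FPS, summary$RC, summary$metric, pos = 3, cex = 0.6)
  invisible(file)
}

#' Summary table with RC / FPS pass flags
#'
#' Flags each metric against the recommended consistency thresholds
#' `RC > t_rc` and `FPS < t_fps`.
#'
#' @param summary the `summary` data.frame from [evaluate_metrics()].
#' @param t_rc rank-correlation threshold (default 0.95).
#' @param t_fps false-positive-signal threshold (default 0.16).
#' @param file optional TSV output path.
#' @return the flagged data.frame, invisibly if `file` is given.
#' @export
summary_table <- function(summary, t_rc = 0.95, t_fps = 0.16, file = NULL) {
  stopifnot(nrow(summary) >= 1L)
  summary$pass_rc <- summary$RC > t_rc
  summary$pass_fps <- !is.na(summary$FPS) & summary$FPS < t_fps
  if (!is.null(file)) {
    utils::write.table(summary, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(summary))
  }
  summary
}
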
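#' Muscle-series summary statistics
#'
#' Arithmetic mean and population standard deviation (divisor n) of the 900
#' per-ms values. The SD tracks the quantity of jaw/lip movement within the
#' vocalization, the mean its base position.
#'
#' @param series Numeric muscle series (a `muscle_series` or plain vector).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
muscle_stats <- function(series) {
  x <- as.numeric(series)
  mu <- mean(x)
  c(mean = mu, sd = sqrt(mean((x - mu)^2)))
}

#' Standardized regression of salience on muscle statistics
#'
#' Ordinary least squares of z-scored salience on z-scored within-trial
#' muscle SD and mean, mirroring the analysis that asks which features of
#' the motor output predict auditory salience.
#'
#' @param records Data frame with columns `S` (or `salience`), `muscle_sd`,
#'   `muscle_mean`.
#' @return List with standardized coefficients `beta_sd`, `beta_mean`, their
#'   p-values, the fitted `lm` object, and a `degenerate` flag (constant
#'   response).
#' @export
fit_salience_model <- function(records) {
  s <- records$S %||% records$salience
  if (is.null(s)) stop("records must contain a salience column `S`")
  df <- data.frame(S = s, sd = records$muscle_sd, mean = records$muscle_mean)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 10) stop("need at least 10 complete records")
  if (stats::sd(df$sd) == 0 || stats::sd(df$mean) == 0)
    stop("rank deficiency: a predictor is constant")
  if (stats::sd(df$S) == 0) {
    return(list(beta_sd = 0, beta_mean = 0, p_sd = NA_real_,
                p_mean = NA_real_, fit = NULL, degenerate = TRUE))
  }
  z <- function(x) (x - mean(x)) / stats::sd(x)
  fit <- stats::lm(z(S) ~ z(sd) + z(mean), data = df)
  cf <- summary(fit)$coefficients
  list(beta_sd = cf["z(sd)", "Estimate"],
       beta_mean = cf["z(mean)", "Estimate"],
       p_sd = cf["z(sd)", "Pr(>|t|)"],
       p_mean = cf["z(mean)", "Pr(>|t|)"],
       fit = fit, degenerate = FALSE)
}

#' Agonist/antagonist weight-matrix summary
#'
#' The ratio of the mean plastic weight onto agonist motor neurons to the
#' mean onto antagonist motor neurons, plus the SD of all plastic weights.
#' A ratio above 1 reflects a learned bias toward mouth closure.
#'
#' @param weights `n_output x n_motor` plastic weight matrix (columns =
#'   motor neurons).
#' @param agonist_ids,antagonist_ids Column index sets of the two pools.
#' @return Named numeric vector `c(weight_ratio, weight_sd)`.
#' @export
weight_summary <- function(weights, agonist_ids, antagonist_ids) {
  if (max(c(agonist_ids, antagonist_ids)) > ncol(weights))
    stop("dimension mismatch between weights and motor pool indices")
  ratio <- mean(weights[, agonist_ids]) / mean(weights[, antagonist_ids])
  c(weight_ratio = ratio, weight_sd = stats::sd(as.numeric(weights)))
}

#' Start-versus-end salience summary
#'
#' Mean salience over the first 60 and the last 60 vocalizations of a run
#' (the first and last simulated minute).
#'
#' @param records Per-trial record data frame with column `S`.
#' @param n Number of trials in each bracket (default 60).
#' @return Named numeric vector `c(start, end)`.
#' @export
start_end_summary <- function(records, n = 60L) {
  if (nrow(records) < 2 * n)
    stop("need at least ", 2 * n, " records")
  s <- records$S
  c(start = mean(s[seq_len(n)]),
    end = mean(s[seq.int(nrow(records) - n + 1, nrow(records))]))
}

#' Binned trend curves with bootstrap confidence intervals
#'
#' Bins the per-trial records into `n_bins` equal spans of simulation time
#' and returns the binned mean of each metric with basic percentile
#' bootstrap CIs.
#'
#' @param records Per-trial record data frame.
#' @param metrics Character vector of record columns to summarize.
#' @param n_bins Number of time bins.
#' @param n_boot Bootstrap replicates per bin.
#' @param conf Confidence level.
#' @return Long data frame: metric, bin, trial_mid, mean, lower, upper.
#' @export
trend_curves <- function(records,
                         metrics = c("S", "syllable_count", "muscle_mean",
                                     "muscle_sd"),
                         n_bins = 60L, n_boot = 200L, conf = 0.95) {
  metrics <- intersect(metrics, names(records))
  bins <- cut(records$trial_index, breaks = n_bins, labels = FALSE)
  alpha <- (1 - conf) / 2
  rows <- list()
  for (metric in metrics) {
    x_all <- records[[metric]]
    for (b in unique(bins)) {
      x <- x_all[bins == b]
      x <- x[is.finite(x)]
      if (length(x) == 0) next
      boots <- vapply(seq_len(n_boot), function(i)
        mean(sample(x, length(x), replace = TRUE)), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, bin = b,
        trial_mid = mean(records$trial_index[bins == b]),
        mean = mean(x),
        lower = unname(stats::quantile(boots, alpha)),
        upper = unname(stats::quantile(boots, 1 - alpha)))
    }
  }
  do.call(rbind, rows)
}

#' Full analysis of one run (or a run directory)
#'
#' Recomputes the analysis suite from the per-trial log alone: trend curves,
#' the standardized salience regression, the start/end salience summary, and
#' (when weights are available) the agonist/antagonist weight summary.
#'
#' @param run A `babble_run`, or a path to a run directory containing
#'   `trials.csv` (and optionally `weights_final.csv`).
#' @param output_dir Optional directory to write `trends.csv`,
#'   `regression.json` and `weights_summary.csv` into.
#' @return List with `trends`, `regression`, `start_end`, `weights`.
#' @export
analyze_run <- function(run, output_dir = NULL) {
  if (is.character(run)) {
    records <- utils::read.csv(file.path(run, "trials.csv"))
    wfile <- file.path(run, "weights_final.csv")
    weights <- if (file.exists(wfile)) as.matrix(utils::read.csv(wfile))
      else NULL
    agonist_ids <- if (!is.null(weights)) seq_len(ncol(weights) / 2) else NULL
    antagonist_ids <- if (!is.null(weights))
      seq.int(ncol(weights) / 2 + 1, ncol(weights)) else NULL
  } else {
    records <- run$records
    weights <- run$weights_final
    agonist_ids <- run$agonist_ids
    antagonist_ids <- run$antagonist_ids
  }
  trends <- trend_curves(records)
  regression <- tryCatch(fit_salience_model(records), error = function(e) NULL)
  se <- tryCatch(start_end_summary(records), error = function(e) NULL)
  ws <- if (!is.null(weights))
    weight_summary(weights, agonist_ids, antagonist_ids) else NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(trends, file.path(output_dir, "trends.csv"),
                     row.names = FALSE)
    if (!is.null(regression))
      jsonlite::write_json(
        regression[c("beta_sd", "beta_mean", "p_sd", "p_mean", "degenerate")],
        file.path(output_dir, "regression.json"), auto_unbox = TRUE,
        digits = NA)
    if (!is.null(ws))
      utils::write.csv(as.data.frame(t(ws)),
                       file.path(output_dir, "weights_summary.csv"),
                       row.names = FALSE)
    grDevices::png(file.path(output_dir, "trends.png"), width = 900,
                   height = 700)
    plot_trends(trends)
    grDevices::dev.off()
  }
  list(trends = trends, regression = regression, start_end = se,
       weights = ws)
}

#' Plot binned trend curves
#'
#' One panel per metric: binned means with the bootstrap confidence band.
#'
#' @param trends Data frame from [trend_curves()].
#' @return Invisibly, `trends`.
#' @export
plot_trends <- function(trends) {
  metrics <- unique(trends$metric)
  old <- graphics::par(mfrow = c(ceiling(length(metrics) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (metric in metrics) {
    tr <- trends[trends$metric == metric, ]
    graphics::plot(tr$trial_mid, tr$mean, type = "n",
                   ylim = range(tr$lower, tr$upper),
                   xlab = "trial", ylab = metric, main = metric)
    graphics::polygon(c(tr$trial_mid, rev(tr$trial_mid)),
                      c(tr$lower, rev(tr$upper)),
                      col = "grey85", border = NA)
    graphics::lines(tr$trial_mid, tr$mean, lwd = 2)
  }
  invisible(trends)
}
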
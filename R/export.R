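#' Export summary tables
#'
#' Writes the experiment summary as three CSVs mirroring the standard
#' presentation: panel (a) medians with 95% interpercentile ranges per
#' scenario x estimator x sample, panel (b) percentage of iterations
#' maintaining the correct relative prevalence pattern, panel (c) percentage
#' of iterations producing an estimate.
#'
#' @param experiment A `"trauma_experiment"` from [run_experiment()] (or its
#'   `summary` list).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(experiment, dir) {
  summ <- if (inherits(experiment, "trauma_experiment"))
    experiment$summary else experiment
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- summ$estimates
  a <- est[, c("scenario", "estimator", "sample", "median", "lo", "hi")]
  b <- summ$pattern
  c_ <- est[, c("scenario", "estimator", "sample", "pct_produced")]
  paths <- file.path(dir, c("table_a_medians.csv", "table_b_pattern.csv",
                            "table_c_production.csv"))
  utils::write.csv(a, paths[1], row.names = FALSE)
  utils::write.csv(b, paths[2], row.names = FALSE)
  utils::write.csv(c_, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Export long-format per-iteration estimates for plotting
#'
#' Emits one row per scenario x iteration x estimator x sample with the
#' estimate (undefined estimates are omitted), the long format sina/strip
#' plots consume.
#'
#' @param experiment A `"trauma_experiment"` or its `results` data.frame.
#' @param path Output CSV path.
#' @return Invisibly, the long data.frame written.
#' @export
export_plot_data <- function(experiment, path = NULL) {
  results <- if (inherits(experiment, "trauma_experiment"))
    experiment$results else experiment
  long <- list()
  for (e in c("cf", "glm")) {
    for (lab in c("A", "B")) {
      col <- paste0(e, "_", lab)
      if (!col %in% names(results)) next
      keep <- !is.na(results[[col]])
      if (!any(keep)) next
      long[[length(long) + 1L]] <- data.frame(
        scenario = results$scenario[keep],
        iteration = results$iteration[keep],
        estimator = e, sample = lab, estimate = results[[col]][keep])
    }
  }
  long <- do.call(rbind, long)
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(long)
}

#' Strip plot of estimate distributions with benchmark lines
#'
#' Basic jittered strip plot of per-iteration estimates by scenario,
#' estimator and sample, with dotted horizontal lines at the configured
#' benchmarks (10% and 30% by default). Requires ggplot2.
#'
#' @param experiment A `"trauma_experiment"`.
#' @return A ggplot object.
#' @export
plot_estimates <- function(experiment) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_estimates() requires the ggplot2 package")
  long <- export_plot_data(experiment)
  cfg <- experiment$config
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$estimate,
                                     colour = .data$estimator)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.25, size = 0.4) +
    ggplot2::geom_hline(yintercept = c(cfg$prevalence_A, cfg$prevalence_B),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~scenario, nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(y = "trauma prevalence estimate (%)", x = "sample") +
    ggplot2::theme_minimal()
}
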
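#' Configuration of a full cohort evaluation run
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort.
#' @param methods methods to run (subset of MNE, sLORETA, dSPM, cMEM; Ave
#'   is added automatically when at least two methods run).
#' @param thresholds threshold grid in percent (subset of 0..100).
#' @param gee_thresholds thresholds entering the GEE stage (default
#'   `c(30, 60, 90)`).
#' @param depth_exponent,snr solver parameters (see [build_wmne_kernel()]).
#' @param condition apply notch/bandpass conditioning to each simulated
#'   recording before epoching (default `TRUE`).
#' @param out_dir optional output directory; when given, the metrics table,
#'   curves, statistics and a plain-text report are written there as
#'   CSV/text.
#' @param seed overrides `cohort$master_seed` when not `NULL`.
#' @param verbose print per-study progress.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       methods = c("MNE", "sLORETA", "dSPM", "cMEM"),
                       thresholds = seq(0, 100, 10),
                       gee_thresholds = c(30, 60, 90),
                       depth_exponent = 0.5, snr = 3,
                       condition = TRUE, out_dir = NULL, seed = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  methods <- match.arg(methods, c("MNE", "sLORETA", "dSPM", "cMEM"),
                       several.ok = TRUE)
  if (!all(thresholds %in% 0:100)) stop("thresholds must lie in 0..100")
  if (!all(gee_thresholds %in% thresholds)) {
    stop("gee_thresholds must be a subset of thresholds")
  }
  if (!is.null(seed)) cohort$master_seed <- as.integer(seed)
  structure(list(cohort = cohort, methods = methods,
                 thresholds = thresholds, gee_thresholds = gee_thresholds,
                 depth_exponent = depth_exponent, snr = snr,
                 condition = condition, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full evaluation pipeline on a synthetic cohort
#'
#' generate -> preprocess -> solve (per method) -> Ave -> metrics ->
#' threshold curves -> group statistics, in one deterministic pass. Failed
#' studies are logged and skipped; the run aborts if more than half fail.
#'
#' @param config a [run_config()].
#' @return Object of class `dmsi_run`: `metrics` (the long metrics table),
#'   `summary` (per-method medians of Dmin and unthresholded SD),
#'   `stats` (Friedman + pairwise Wilcoxon on Dmin, GEE per curve metric),
#'   `failures`, `config`, `cohort`.
#' @export
run_evaluation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort)
  adjacency <- cohort$adjacency
  metrics <- list()
  failures <- list()
  n_total <- 0L
  for (ip in seq_along(cohort$patients)) {
    pat <- cohort$patients[[ip]]
    for (is in seq_along(pat$study_seeds)) {
      n_total <- n_total + 1L
      study_id <- sprintf("%s_S%02d", pat$patient_id, is)
      res <- tryCatch(
        .evaluate_study(cohort, ip, is, study_id, config, adjacency),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[study_id]] <- conditionMessage(res)
        if (config$verbose) message(study_id, " FAILED: ", conditionMessage(res))
      } else {
        metrics[[study_id]] <- res
        if (config$verbose) message(study_id, " ok")
      }
    }
  }
  if (length(failures) > n_total / 2) {
    stop("more than half of the studies failed; first error: ",
         failures[[1L]])
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  stats <- .cohort_statistics(metrics, config)
  summary_tabs <- list(
    dmin = summarize_results(metrics, "dmin_mm"),
    sd_unthresholded = summarize_results(
      metrics[metrics$threshold_pct == min(metrics$threshold_pct), ], "sd_mm"))
  out <- structure(list(metrics = metrics, summary = summary_tabs,
                        stats = stats, failures = failures,
                        config = config, cohort = cohort),
                   class = "dmsi_run")
  if (!is.null(config$out_dir)) .write_run(out, config$out_dir)
  out
}

.evaluate_study <- function(cohort, ip, is, study_id, config, adjacency) {
  pat <- cohort$patients[[ip]]
  rec <- cohort_recording(cohort, ip, is)
  if (config$condition) {
    rec <- condition_recording(rec, target_rate_hz = rec$sampling_rate_hz)
  }
  study <- epoch_and_average(rec, "type1", patient_id = pat$patient_id,
                             study_id = study_id)
  ncov <- estimate_noise_covariance(study)
  maps <- list()
  for (meth in config$methods) {
    fit <- dmsi(study, cohort$gain, ncov, method = meth, mesh = cohort$mesh,
                depth_exponent = config$depth_exponent, snr = config$snr,
                adjacency = adjacency)
    maps[[meth]] <- fit$map
  }
  if (length(maps) >= 2L) maps$Ave <- average_maps(maps)
  study_metrics(maps, pat$focus, cohort$mesh, patient_id = pat$patient_id,
                study_id = study_id, thresholds = config$thresholds)
}

.cohort_statistics <- function(metrics, config) {
  dm <- unique(metrics[, c("patient_id", "study_id", "method", "dmin_mm")])
  out <- list()
  if (length(unique(dm$method)) < 2L) return(out)   # nothing to compare
  out$friedman_dmin <- friedman_across_methods(dm$dmin_mm, dm$method,
                                               dm$study_id)
  out$wilcoxon_dmin <- pairwise_wilcoxon_bonferroni(dm$dmin_mm, dm$method,
                                                    dm$study_id)
  for (dep in c("sd_mm", "size_vertices", "map_dmin_mm")) {
    out[[paste0("gee_", dep)]] <- gee_threshold_model(
      metrics, dependent = dep, thresholds = config$gee_thresholds)
  }
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary$dmin$study_level,
                   file.path(out_dir, "dmin_summary_study_level.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary$dmin$patient_level,
                   file.path(out_dir, "dmin_summary_patient_level.csv"),
                   row.names = FALSE)
  rpt <- file.path(out_dir, "report.txt")
  con <- file(rpt, "w")
  on.exit(close(con))
  writeLines("dmsi cohort evaluation report", con)
  writeLines(utils::capture.output({
    print(run$config$cohort)
    cat("\nPer-method Dmin (study level):\n")
    print(run$summary$dmin$study_level, row.names = FALSE)
    cat("\nPer-method unthresholded SD (study level):\n")
    print(run$summary$sd_unthresholded$study_level, row.names = FALSE)
    cat("\n")
    if (!is.null(run$stats$friedman_dmin)) {
      print(run$stats$friedman_dmin)
      for (w in run$stats$wilcoxon_dmin) print(w)
      for (dep in c("sd_mm", "size_vertices", "map_dmin_mm")) {
        g <- run$stats[[paste0("gee_", dep)]]
        cat("\nGEE on", dep, ":\n")
        print(g$method); print(g$threshold); print(g$interaction)
      }
    }
    if (length(run$failures)) {
      cat("\nFailed studies:\n")
      for (nm in names(run$failures)) cat(" ", nm, ":", run$failures[[nm]], "\n")
    }
  }), con)
  invisible(rpt)
}

#' @export
print.dmsi_run <- function(x, ...) {
  cat(sprintf("dmsi_run: %d studies x %d methods x %d thresholds (%d failures)\n",
              length(unique(x$metrics$study_id)),
              length(unique(x$metrics$method)),
              length(unique(x$metrics$threshold_pct)), length(x$failures)))
  invisible(x)
}

#' @export
summary.dmsi_run <- function(object, ...) {
  cat("Per-method Dmin (study level):\n")
  print(object$summary$dmin$study_level, row.names = FALSE)
  cat("\nPer-method unthresholded SD (study level):\n")
  print(object$summary$sd_unthresholded$study_level, row.names = FALSE)
  cat("\n")
  if (!is.null(object$stats$friedman_dmin)) print(object$stats$friedman_dmin)
  invisible(object)
}

#' @export
plot.dmsi_run <- function(x, metric = "sd_mm", ...) {
  stopifnot(metric %in% c("sd_mm", "size_vertices", "map_dmin_mm"))
  agg <- stats::aggregate(x$metrics[[metric]],
                          by = list(threshold_pct = x$metrics$threshold_pct,
                                    method = x$metrics$method),
                          FUN = stats::median)
  methods <- unique(agg$method)
  cols <- grDevices::hcl.colors(length(methods), "Dark 3")
  graphics::plot(NA, xlim = range(agg$threshold_pct), ylim = range(agg$x),
                 xlab = "threshold (%)", ylab = paste("median", metric), ...)
  for (i in seq_along(methods)) {
    g <- agg[agg$method == methods[i], ]
    graphics::lines(g$threshold_pct, g$x, col = cols[i], type = "b", pch = 19)
  }
  graphics::legend("topright", legend = methods, col = cols, lty = 1, pch = 19)
  invisible(x)
}
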
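# Structured result serialisation and run provenance. Deterministic field
# ordering throughout; summary files round costs to 2 decimal places and
# QALYs/LYs to 4, while machine-readable JSON keeps full precision, so two
# identical deterministic runs produce byte-identical output.

round_df <- function(df, cost_cols = character(), qaly_cols = character()) {
  for (cc in intersect(cost_cols, names(df))) df[[cc]] <- round(df[[cc]], 2)
  for (qc in intersect(qaly_cols, names(df))) df[[qc]] <- round(df[[qc]], 4)
  df
}

arm_results_list <- function(x) {
  list(arm = x$arm,
       discounted = x$discounted, undiscounted = x$undiscounted,
       time_on_treatment_years = x$time_on_treatment_years,
       person_years = x$person_years,
       events = as.list(x$events),
       event_rates_per_100py = as.list(x$event_rates_per_100py),
       n_cycles = x$n_cycles)
}

ce_results_list <- function(x) {
  list(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
       delta_ly = x$delta_ly, icer_per_qaly = x$icer_per_qaly,
       icer_per_ly = x$icer_per_ly, dominance = x$dominance,
       nmb = x$nmb, cet = x$cet, cost_effective = x$cost_effective)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Write analysis results to an output directory
#'
#' Dispatches on result type: arm results and cost-effectiveness results go
#' to full-precision JSON plus a rounded summary CSV; a tornado table
#' (from [run_dsa()]) to `tornado.csv`; a PSA result to `psa_draws.csv`,
#' `ceac.csv` and `psa_summary.json`; a cohort trace to a cycle-level CSV.
#'
#' @param results A `hfcem_arm_results`, `hfcem_ce_results`,
#'   `hfcem_psa_result`, `hfcem_trace`, or a tornado data frame.
#' @param dir Output directory (created if missing).
#' @param name Basename stem for the files.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, dir, name = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  if (inherits(results, "hfcem_arm_results")) {
    name <- name %||% paste0("arm_", results$arm)
    files <- write_json_file(arm_results_list(results),
                             file.path(dir, paste0(name, ".json")))
  } else if (inherits(results, "hfcem_ce_results")) {
    name <- name %||% "ce_results"
    f1 <- write_json_file(ce_results_list(results),
                          file.path(dir, paste0(name, ".json")))
    summ <- round_df(
      data.frame(delta_cost = results$delta_cost,
                 delta_qaly = results$delta_qaly,
                 delta_ly = results$delta_ly,
                 icer_per_qaly = round(results$icer_per_qaly, 2),
                 nmb = results$nmb, dominance = results$dominance,
                 cost_effective = results$cost_effective),
      cost_cols = c("delta_cost", "nmb"),
      qaly_cols = c("delta_qaly", "delta_ly"))
    f2 <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(summ, f2, row.names = FALSE)
    files <- c(f1, f2)
  } else if (inherits(results, "hfcem_psa_result")) {
    name <- name %||% "psa"
    f1 <- file.path(dir, paste0(name, "_draws.csv"))
    utils::write.csv(results$draws, f1, row.names = FALSE)
    f2 <- file.path(dir, paste0(name, "_ceac.csv"))
    utils::write.csv(results$ceac, f2, row.names = FALSE)
    f3 <- write_json_file(
      list(iterations = results$iterations, seed = results$seed,
           redraws = results$redraws,
           quadrant_shares = as.list(results$quadrant_shares),
           mean_icer_ne = results$mean_icer_ne,
           icer_ratio_of_means = results$icer_ratio_of_means,
           prob_ce_at_cet = results$prob_ce_at_cet, cet = results$cet),
      file.path(dir, paste0(name, "_summary.json")))
    files <- c(f1, f2, f3)
  } else if (inherits(results, "hfcem_trace")) {
    name <- name %||% paste0("trace_", results$arm)
    f1 <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(results), f1, row.names = FALSE)
    files <- f1
  } else if (is.data.frame(results)) {
    name <- name %||% "tornado"
    df <- results
    attr(df, "base_icer") <- NULL
    attr(df, "base_nmb") <- NULL
    f1 <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, f1, row.names = FALSE)
    if (!is.null(attr(results, "base_icer")))
      files <- c(f1, write_json_file(
        list(base_icer = attr(results, "base_icer"),
             base_nmb = attr(results, "base_nmb")),
        file.path(dir, paste0(name, "_base.json"))))
    else files <- f1
  } else {
    stop("unsupported results type: ", paste(class(results), collapse = "/"),
         call. = FALSE)
  }
  invisible(files)
}

#' Write a run manifest
#'
#' Provenance record for an output directory: configuration hash (MD5 of
#' the config file, if any), seeds, package version, cycle counts, wall
#' time and warnings.
#'
#' @param dir Output directory.
#' @param config_path Optional configuration file to hash.
#' @param seeds Named list/vector of seeds used.
#' @param cycle_counts Named cycle counts per arm, if known.
#' @param wall_time_s Elapsed seconds.
#' @param warnings Character vector of warnings raised.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config_path = NULL, seeds = list(),
                           cycle_counts = list(), wall_time_s = NA_real_,
                           warnings = character()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    package = "hfcem",
    version = as.character(utils::packageVersion("hfcem")),
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    seeds = seeds,
    cycle_counts = cycle_counts,
    wall_time_s = wall_time_s,
    warnings = as.list(warnings),
    r_version = R.version.string
  )
  invisible(write_json_file(manifest, file.path(dir, "manifest.json")))
}
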
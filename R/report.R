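# Deterministic report output: every table written by the analysis scripts
# is accompanied by a manifest that makes it reproducible.

#' Run manifest
#'
#' Records what produced a set of result files: the command label, the hash
#' of the configuration that was run, the seed, horizon, cohort size,
#' timestamp and package version.
#'
#' @param command Short label of the analysis (e.g. `"run-base"`).
#' @param params The `dfu_params` that was run.
#' @param seed Master seed.
#' @param n Patients per arm.
#' @param horizon Cycles.
#' @param extra Optional named list of additional settings to record.
#' @return Named list (class `dfu_manifest`).
#' @export
run_manifest <- function(command, params, seed, n, horizon, extra = NULL) {
  cfg_json <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  structure(
    c(list(
      command = command,
      config_sha = .short_hash(cfg_json),
      seed = seed, n = n, horizon_cycles = horizon,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package_version = as.character(utils::packageVersion("dfusim"))
    ), extra),
    class = "dfu_manifest"
  )
}

# dependency-free rolling content hash (hex), enough to identify a config
.short_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a two-arm comparison report
#'
#' Writes the per-arm cohort summaries and the incremental comparison as
#' JSON and CSV under `dir`, together with `manifest.json`. Rounding in the
#' CSV summary mirrors the published tables (2 decimals for LY/QALY, whole
#' EUR); the JSON keeps full precision.
#'
#' @param res Result of [run_two_arm()].
#' @param dir Output directory (created if needed).
#' @param manifest A [run_manifest()].
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(res, dir, manifest) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arms <- lapply(res[c("tlc_nosf", "control")], function(a) {
    list(strategy = a$strategy, n = a$n, horizon_cycles = a$horizon,
         mean = as.list(a$mean), se = as.list(a$se),
         amputation_count = a$amputation_count,
         amputations_per_100 = amputations_per_100(a))
  })
  cmp <- res$comparison
  jsonlite::write_json(
    list(arms = arms,
         comparison = list(d_ly_wo_dfu = cmp$d_ly_wo_dfu, d_qaly = cmp$d_qaly,
                           d_cost = cmp$d_cost, icer = cmp$icer, icur = cmp$icur,
                           dominance = cmp$dominance),
         manifest = unclass(manifest)),
    file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  tab <- data.frame(
    group = c("TLC-NOSF", "Control", "Difference"),
    ly_wo_dfu_years = round(c(res$tlc_nosf$mean[["ly_wo_dfu"]],
                              res$control$mean[["ly_wo_dfu"]], cmp$d_ly_wo_dfu), 2),
    qaly_years = round(c(res$tlc_nosf$mean[["qaly"]],
                         res$control$mean[["qaly"]], cmp$d_qaly), 2),
    total_cost_eur_2019 = round(c(res$tlc_nosf$mean[["cost"]],
                                  res$control$mean[["cost"]], cmp$d_cost)),
    amputations_per_100 = c(amputations_per_100(res$tlc_nosf),
                            amputations_per_100(res$control),
                            amputations_per_100(res$tlc_nosf) -
                              amputations_per_100(res$control))
  )
  write.csv(tab, file.path(dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Export sensitivity-analysis tables
#'
#' CSV writers for the tornado table (parameter, outcome at each bound,
#' swing), the cost-utility plane (one incremental pair per probabilistic
#' sample) and the acceptability curve. Column headers carry the units.
#'
#' @param x A `dfu_dsa`, `dfu_psa` or `dfu_ceac` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(x, path) {
  stopifnot(inherits(x, "dfu_dsa"))
  out <- data.frame(
    parameter = x$parameter, lower_bound = x$lower, upper_bound = x$upper,
    outcome_at_lower = x$outcome_low, outcome_at_upper = x$outcome_high,
    swing = x$swing
  )
  names(out)[4:6] <- paste0(names(out)[4:6], "_",
                            switch(attr(x, "outcome"),
                                   cost = "eur", qaly = "qaly_years", ly = "ly_years"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado_csv
#' @export
write_cu_plane_csv <- function(x, path) {
  stopifnot(inherits(x, "dfu_psa"))
  write.csv(data.frame(sample = x$sample, d_qaly_years = x$d_qaly,
                       d_cost_eur = x$d_cost, dominant = x$dominant),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado_csv
#' @export
write_ceac_csv <- function(x, path) {
  stopifnot(inherits(x, "dfu_ceac"))
  write.csv(data.frame(lambda_eur_per_qaly = x$lambda,
                       p_tlc_nosf = x$p_tlc_nosf, p_control = x$p_control),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a patient-by-cycle trace
#'
#' Long-format CSV of `(patient, cycle, state)` for a cohort run executed
#' with `keep_trace = TRUE`.
#'
#' @param cohort A `dfu_cohort` with a trace.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(cohort, path) {
  if (is.null(cohort$trace)) stop("cohort was run without keep_trace = TRUE", call. = FALSE)
  tr <- cohort$trace
  out <- data.frame(
    patient = rep(seq_len(nrow(tr)), ncol(tr)),
    cycle = rep(0:(ncol(tr) - 1), each = nrow(tr)),
    state = dfu_states()[as.vector(tr)]
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
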
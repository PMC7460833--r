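# End-to-end orchestration: run the flexibility analyses for a panel of
# variants against a designated reference and emit TSV/JSON reports, and
# likewise for the kinetic datasets. Configs are plain R lists, usually
# read from YAML. Results go to files; progress goes to stderr.

.msg <- function(...) message("[upoflex] ", sprintf(...))

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Validate a flexibility-pipeline configuration
#'
#' Checks that every referenced trajectory exists, that exactly one variant
#' is designated as the reference, and that numeric settings are sane.
#' Called by [run_flex_report()] before any computation.
#'
#' @param config config list (see the package vignette for the layout).
#' @return the config, with defaults filled in.
#' @export
validate_flex_config <- function(config) {
  if (is.null(config$variants) || !length(config$variants))
    stop("config error: no variants defined")
  if (is.null(config$reference))
    stop("config error: no reference variant designated")
  if (!config$reference %in% names(config$variants))
    stop("config error: reference '", config$reference,
         "' is not among the variants")
  for (v in names(config$variants)) {
    tp <- config$variants[[v]]$trajectory
    if (is.null(tp))
      stop("config error: variant '", v, "' has no trajectory path")
    if (!file.exists(tp))
      stop("config error: trajectory for '", v, "' not found: ", tp)
  }
  defaults <- list(frame_interval_ps = 10, window_ps = 100,
                   threshold_k = 1.0, span_ns = NULL, last_n_frames = 100,
                   grid_spacing = 1.0, probe_pad = 0, contiguity = FALSE,
                   bin_width = 0.25, seed = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (config$window_ps <= 0) stop("config error: window_ps must be positive")
  if (config$grid_spacing <= 0)
    stop("config error: grid_spacing must be positive")
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the flexibility/topography report for a variant panel
#'
#' Per variant: RMSD series, windowed RMSF profile, differential mobility
#' calls against the reference, cavity volume series over the trailing
#' frames (when sphere recipes are configured), and requested residue-pair
#' distance histograms. TSVs per stage plus a `summary.json` are written to
#' `out_dir`; partial outputs are retained if a stage fails.
#'
#' @param config config list (see [validate_flex_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
run_flex_report <- function(config, out_dir) {
  config <- validate_flex_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  t0 <- Sys.time()

  trajs <- list()
  for (v in names(config$variants)) {
    vc <- config$variants[[v]]
    fmt <- if (is.null(vc$format)) "multimodel_pdb" else vc$format
    .msg("reading trajectory for %s (%s)", v, fmt)
    trajs[[v]] <- .stage(paste0("read:", v), read_trajectory(
      vc$trajectory, format = fmt,
      frame_interval_ps = config$frame_interval_ps))
  }

  span_of <- function(traj) {
    if (is.null(config$span_ns)) NULL
    else span_last_ns(traj, config$span_ns)
  }

  profiles <- list(); summary <- list(variants = list())
  for (v in names(trajs)) {
    tr <- trajs[[v]]
    sel <- select_atoms(tr$topology)
    .msg("RMSD series: %s", v)
    rs <- .stage(paste0("rmsd:", v), rmsd_series(tr, 1, sel))
    .write_tsv(rs, file.path(out_dir, paste0(v, "_rmsd.tsv")))
    .msg("windowed RMSF: %s", v)
    pr <- .stage(paste0("rmsf:", v), windowed_rmsf(
      tr, sel, span = span_of(tr), window_ps = config$window_ps))
    profiles[[v]] <- pr
    .write_tsv(as.data.frame(pr),
               file.path(out_dir, paste0(v, "_rmsf.tsv")))
    summary$variants[[v]] <- list(
      n_frames = nframes(tr), n_residues = length(pr$residue_ids),
      mean_rmsf_A = mean(pr$rmsf), n_windows = pr$n_windows)

    vc <- config$variants[[v]]
    if (!is.null(vc$sphere_recipes)) {
      .msg("cavity volumes: %s", v)
      recipes <- lapply(vc$sphere_recipes, function(rc)
        sphere_recipe(unlist(rc$residues), unlist(rc$atoms),
                      radius = if (is.null(rc$radius)) 4 else rc$radius))
      vols <- .stage(paste0("volume:", v), volume_series(
        tr, recipes,
        last_n_frames = min(config$last_n_frames, nframes(tr)),
        grid_spacing = config$grid_spacing, probe_pad = config$probe_pad,
        contiguity = config$contiguity))
      .write_tsv(as.data.frame(vols),
                 file.path(out_dir, paste0(v, "_volume.tsv")))
      summary$variants[[v]]$mean_volume_A3 <- mean(vols$volume_A3)
    }

    if (!is.null(config$distances)) {
      for (pair in config$distances) {
        pair <- unlist(pair)
        .msg("distance %d-%d: %s", pair[1], pair[2], v)
        ds <- .stage(paste0("distance:", v), pair_distance_series(
          tr, pair[1], pair[2], span = span_of(tr)))
        tag <- sprintf("%s_dist_%d_%d", v, pair[1], pair[2])
        .write_tsv(as.data.frame(ds), file.path(out_dir,
                                                paste0(tag, ".tsv")))
        .write_tsv(distance_histogram(ds, config$bin_width),
                   file.path(out_dir, paste0(tag, "_hist.tsv")))
      }
    }
  }

  ref <- config$reference
  summary$mobility <- list()
  for (v in setdiff(names(profiles), ref)) {
    .msg("differential mobility: %s vs %s", v, ref)
    calls <- .stage(paste0("mobility:", v), differential_mobility(
      profiles[[v]], profiles[[ref]], threshold_k = config$threshold_k))
    .write_tsv(as.data.frame(calls),
               file.path(out_dir, paste0(v, "_mobility.tsv")))
    fl <- flagged_residues(calls)
    summary$mobility[[v]] <- list(
      increased = fl$residue_id[fl$label == "increased"],
      decreased = fl$residue_id[fl$label == "decreased"],
      mean_delta_A = attr(calls, "mean_delta"),
      sd_delta_A = attr(calls, "sd_delta"))
  }
  summary$reference <- ref
  summary$settings <- config[c("window_ps", "span_ns", "threshold_k",
                               "last_n_frames", "grid_spacing",
                               "probe_pad", "contiguity", "seed")]
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .msg("flex report done in %.1f s",
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(summary)
}

#' Run the kinetics report for a panel of variant datasets
#'
#' Fits Michaelis-Menten parameters per (variant, substrate) rate table and
#' first-order inactivation per decay table, computes TTN entries, and
#' writes `kinetics.tsv`, `inactivation.tsv`, `ttn.tsv` and
#' `kinetics_summary.json` to `out_dir`. A failing dataset is reported and
#' skipped; the run continues.
#'
#' @param config list with elements `rates` (each: `variant`, `substrate`,
#'   `enzyme_nM`, and `file` (TSV: substrate_uM, rate) or inline `data`),
#'   `inactivation` (each: `variant`, `file` (TSV: time_min, activity) or
#'   `data`), and optional `ttn` (each: `variant`, `substrate`,
#'   `converted_uM`, `enzyme_nM`).
#' @param out_dir output directory.
#' @return invisibly, a list with the three report data frames.
#' @export
run_kinetics_report <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  read_table <- function(entry, cols) {
    if (!is.null(entry$data)) {
      df <- as.data.frame(lapply(entry$data, unlist))
    } else {
      if (is.null(entry$file) || !file.exists(entry$file))
        stop("dataset file missing: ", entry$file)
      df <- utils::read.delim(entry$file)
    }
    if (!all(cols %in% names(df)))
      stop("dataset must have columns ", paste(cols, collapse = ", "))
    df
  }

  mm_rows <- list()
  for (entry in config$rates) {
    tag <- paste(entry$variant, entry$substrate, sep = "/")
    res <- tryCatch({
      df <- read_table(entry, c("substrate_uM", "rate"))
      if (!nrow(df)) stop("empty table")
      fit <- fit_mm(rate_dataset(df$substrate_uM, df$rate,
                                 entry$enzyme_nM))
      data.frame(variant = entry$variant, substrate = entry$substrate,
                 kcat = fit$kcat, kcat_se = fit$kcat_se, Km = fit$Km,
                 Km_se = fit$Km_se, kcat_over_Km = fit$kcat_over_Km,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("kinetics dataset ", tag, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) mm_rows[[tag]] <- res
  }
  mm_tab <- if (length(mm_rows)) do.call(rbind, mm_rows) else
    data.frame(variant = character(), substrate = character(),
               kcat = numeric(), kcat_se = numeric(), Km = numeric(),
               Km_se = numeric(), kcat_over_Km = numeric())
  .write_tsv(mm_tab, file.path(out_dir, "kinetics.tsv"))

  inact_rows <- list()
  for (entry in config$inactivation) {
    res <- tryCatch({
      df <- read_table(entry, c("time_min", "activity"))
      if (!nrow(df)) stop("empty table")
      fit <- fit_inactivation(df$time_min, df$activity)
      data.frame(variant = entry$variant, k_inact = fit$k_inact,
                 k_inact_se = fit$k_inact_se, t_half = fit$t_half,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("inactivation dataset ", entry$variant, " skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) inact_rows[[entry$variant]] <- res
  }
  inact_tab <- if (length(inact_rows)) do.call(rbind, inact_rows) else
    data.frame(variant = character(), k_inact = numeric(),
               k_inact_se = numeric(), t_half = numeric())
  .write_tsv(inact_tab, file.path(out_dir, "inactivation.tsv"))

  ttn_tab <- data.frame(variant = character(), substrate = character(),
                        ttn = numeric())
  if (!is.null(config$ttn)) {
    ttn_tab <- do.call(rbind, lapply(config$ttn, function(entry)
      data.frame(variant = entry$variant, substrate = entry$substrate,
                 ttn = ttn(entry$converted_uM, entry$enzyme_nM),
                 stringsAsFactors = FALSE)))
    .write_tsv(ttn_tab, file.path(out_dir, "ttn.tsv"))
  }

  jsonlite::write_json(
    list(kinetics = mm_tab, inactivation = inact_tab, ttn = ttn_tab),
    file.path(out_dir, "kinetics_summary.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  invisible(list(kinetics = mm_tab, inactivation = inact_tab,
                 ttn = ttn_tab))
}
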
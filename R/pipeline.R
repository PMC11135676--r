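## Reproducible pipeline runners over the module functions.  All randomness
## derives from one master seed via fixed per-call offsets, so every command
## is deterministic given its config.

deep_merge <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- deep_merge(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Build a run configuration
#'
#' Default parameters for every stage, optionally overridden from a YAML
#' file and/or a named list (list overrides file overrides defaults).
#'
#' @param file optional YAML config file.
#' @param overrides optional named list of overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(file = NULL, overrides = NULL) {
  cfg <- list(
    master_seed = 1,
    outdir = "results",
    synth = list(
      t_start = 0, t_end = 30, t_step = 0.5,
      replicates = 3,
      growth_noise_sd = 0.002,
      production_noise_sd = 0.005,
      flow_events = 5000, flow_trials = 3,
      footprint = list(attenuation = 0.3, noise_sd = 0, jitter_sd = 0,
                       peak_spacing_scans = 10, peak_width_scans = 1.2,
                       base_height = 1000)),
    growth = list(window_points = 5, r2_min = 0.99, deviation_frac = 0.05,
                  run_length = 3, od_min = 0.05, delta_floor = 0.005,
                  range_floor = 0.02),
    footprint = list(tau = 0.02, min_run = 3, tol_bp = 0.5,
                     tss_offset_atg = -100))
  if (!is.null(file)) {
    pk_assert(file.exists(file), sprintf("config file not found: %s", file),
              class = "io_error")
    cfg <- deep_merge(cfg, yaml::read_yaml(file))
  }
  if (!is.null(overrides)) cfg <- deep_merge(cfg, overrides)
  structure(cfg, class = "run_config")
}

synth_times <- function(config) {
  seq(config$synth$t_start, config$synth$t_end, by = config$synth$t_step)
}

#' Generate all synthetic datasets
#'
#' Writes growth, production and flow event tables, the with/without trace
#' pairs for every footprint preset, and a ground-truth manifest recording
#' the generating parameters.  Idempotent for a fixed master seed.
#'
#' @param config a [run_config()].
#' @return list of written file paths, invisibly.
#' @export
run_synth <- function(config = run_config()) {
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ms <- config$master_seed
  meta <- c(seed = as.character(ms), config = config_hash(config))
  times <- synth_times(config)
  gps <- genotype_presets()
  reps <- config$synth$replicates

  growth <- do.call(rbind, lapply(seq_along(gps), function(si) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      gc <- generate_growth_curve(gps[[si]], times,
                                  config$synth$growth_noise_sd,
                                  seed = derive_seed(ms, 100 * si + r),
                                  replicate = paste0("r", r))
      data.frame(strain = gc$strain, replicate = gc$replicate,
                 time_h = gc$times, od600 = gc$od600)
    }))
  }))
  prod <- do.call(rbind, lapply(seq_along(gps), function(si) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      pc <- generate_production_curve(gps[[si]], times,
                                      config$synth$production_noise_sd,
                                      seed = derive_seed(ms, 1000 + 100 * si + r),
                                      replicate = paste0("r", r))
      data.frame(strain = pc$strain, replicate = pc$replicate,
                 time_h = pc$times, a410 = pc$a410)
    }))
  }))
  fps <- flow_presets()
  flow <- do.call(rbind, lapply(seq_len(config$synth$flow_trials), function(tr) {
    do.call(rbind, lapply(seq_along(fps), function(si) {
      fs <- generate_flow_sample(fps[[si]], config$synth$flow_events,
                                 seed = derive_seed(ms, 2000 + 100 * tr + si),
                                 sample_id = paste0(fps[[si]]$name, "_t", tr))
      data.frame(trial = tr, sample_id = fs$sample_id, strain = fs$strain,
                 is_control = fs$is_control, fluorescence = fs$events)
    }))
  }))

  probe <- yvmc_probe(config$footprint$tss_offset_atg)
  specs <- footprint_presets(config$synth$footprint$attenuation)
  fpc <- config$synth$footprint
  trace_paths <- character(0)
  for (si in seq_along(specs)) {
    pair <- generate_trace_pair(
      specs[[si]], probe,
      peak_spacing_scans = fpc$peak_spacing_scans,
      peak_width_scans = fpc$peak_width_scans,
      base_height = fpc$base_height, noise_sd = fpc$noise_sd,
      jitter_sd = fpc$jitter_sd, seed = derive_seed(ms, 3000 + si))
    for (lab in c("with", "without")) {
      tr <- pair[[lab]]
      p <- file.path(out, sprintf("trace_%s_%s.tsv",
                                  specs[[si]]$protein, lab))
      write_tsv(data.frame(scan = tr$scan, sample_signal = tr$sample_signal,
                           ladder_signal = tr$ladder_signal,
                           label = tr$label),
                p, meta)
      trace_paths <- c(trace_paths, p)
    }
  }

  manifest <- list(
    master_seed = ms,
    genotypes = lapply(gps, function(g)
      list(od_params = g$od_params,
           prod_params = unclass(g$prod_params)[c("y0", "K", "mumax",
                                                  "lambda")])),
    flow = lapply(fps, function(f)
      list(positive_fraction = f$positive_fraction,
           is_control = f$is_control)),
    footprints = lapply(specs, function(s)
      list(window_start_tss = s$window_start_tss,
           window_end_tss = s$window_end_tss,
           attenuation = s$attenuation)),
    probe = list(label_end_atg = probe$label_end_atg,
                 probe_len = probe$probe_len,
                 tss_offset_atg = probe$tss_offset_atg))
  paths <- list(growth = file.path(out, "growth.tsv"),
                production = file.path(out, "production.tsv"),
                flow = file.path(out, "flow.tsv"),
                traces = trace_paths,
                manifest = file.path(out, "manifest.yaml"))
  write_tsv(growth, paths$growth, meta)
  write_tsv(prod, paths$production, meta)
  write_tsv(flow, paths$flow, meta)
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

#' Run the production-kinetics analysis
#'
#' Reads the growth and production tables, detects T0 per strain/replicate,
#' fits the Gompertz model per replicate, summarizes the four kinetic
#' parameters per strain (start times measured against the WT background
#' fits), and writes the summary plus Bonferroni-corrected pairwise
#' comparison tables.
#'
#' @param config a [run_config()].
#' @param reference strain used as the production baseline (default "WT").
#' @return list with `summaries`, `comparisons`, `t0`, invisibly.
#' @export
run_growth <- function(config = run_config(), reference = "WT") {
  out <- config$outdir
  g <- read_tsv(file.path(out, "growth.tsv"),
                c("strain", "replicate", "time_h", "od600"))
  p <- read_tsv(file.path(out, "production.tsv"),
                c("strain", "replicate", "time_h", "a410"))
  gc <- config$growth
  key <- function(d) interaction(d$strain, d$replicate, drop = TRUE)
  fits <- list(); t0s <- list()
  for (piece in split(g, key(g))) {
    piece <- piece[order(piece$time_h), ]
    cv <- growth_curve(piece$strain[1], piece$replicate[1],
                       piece$time_h, piece$od600)
    t0s[[paste(piece$strain[1], piece$replicate[1])]] <-
      detect_transition_time(cv, gc$window_points, gc$r2_min,
                             gc$deviation_frac, gc$run_length, gc$od_min)
  }
  for (piece in split(p, key(p))) {
    piece <- piece[order(piece$time_h), ]
    cv <- production_curve(piece$strain[1], piece$replicate[1],
                           piece$time_h, piece$a410)
    fits[[paste(piece$strain[1], piece$replicate[1])]] <-
      fit_gompertz(cv, range_floor = gc$range_floor)
  }
  strains <- unique(p$strain)
  by_strain <- function(lst, s) {
    keys <- names(lst)[startsWith(names(lst), paste0(s, " "))]
    lst[sort(keys)]
  }
  ref_fits <- by_strain(fits, reference)
  summaries <- lapply(strains, function(s) {
    f <- by_strain(fits, s)
    t0 <- by_strain(t0s, s)
    refs <- if (s == reference) NULL else ref_fits[seq_along(f)]
    summarize_strain(f, t0, reference_fits = refs,
                     delta_floor = gc$delta_floor,
                     t_min = min(p$time_h), t_max = max(p$time_h))
  })
  names(summaries) <- strains

  sum_df <- do.call(rbind, lapply(summaries, function(s)
    cbind(strain = s$strain, s$stats)))
  rownames(sum_df) <- NULL
  params <- c("start_time", "duration", "max_rate", "max_a410")
  comp <- do.call(rbind, lapply(params, function(prm) {
    keep <- summaries
    if (prm == "start_time")  # the reference has no start time
      keep <- keep[!vapply(keep, function(s)
        anyNA(s$replicates$start_time), logical(1))]
    if (length(keep) < 2) return(NULL)
    cbind(parameter = prm, compare_parameters(keep, prm))
  }))
  if (is.null(comp))
    comp <- data.frame(parameter = character(0), strain_a = character(0),
                       strain_b = character(0), raw_p = numeric(0),
                       adj_p = numeric(0), significant = logical(0))
  meta <- c(seed = as.character(config$master_seed),
            config = config_hash(config))
  write_tsv(sum_df, file.path(out, "kinetics_summary.tsv"), meta)
  write_tsv(comp, file.path(out, "kinetics_comparisons.tsv"), meta)
  invisible(list(summaries = summaries, comparisons = comp, t0 = t0s))
}

#' Run the flow-cytometry gating analysis
#'
#' Reads the event table, requires exactly one control sample per trial,
#' gates every sample in a trial at that control's maximum, and writes
#' per-sample gate results plus per-strain summaries.
#'
#' @param config a [run_config()].
#' @return list with `gates` and `summary` data.frames, invisibly.
#' @export
run_flow <- function(config = run_config()) {
  out <- config$outdir
  ev <- read_tsv(file.path(out, "flow.tsv"),
                 c("trial", "sample_id", "strain", "is_control",
                   "fluorescence"))
  results <- list()
  for (d in split(ev, ev$trial)) {
    ctrl_ids <- unique(d$sample_id[d$is_control])
    if (length(ctrl_ids) != 1)
      pk_stop(sprintf("trial %s has %d control samples; need exactly 1",
                      d$trial[1], length(ctrl_ids)), "configuration_error")
    mk <- function(sd) flow_sample(sd$sample_id[1], sd$strain[1],
                                   sd$fluorescence,
                                   is_control = sd$is_control[1])
    thr <- gate_threshold(mk(d[d$sample_id == ctrl_ids, ]))
    for (sd in split(d, d$sample_id))
      results[[sd$sample_id[1]]] <- percent_positive(mk(sd), thr)
  }
  gates <- do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, strain = r$strain,
               threshold = r$threshold,
               percent_positive = r$percent_positive,
               median_fluorescence = r$median_fluorescence,
               n_events = r$n_events)))
  rownames(gates) <- NULL
  summary <- summarize_trials(results)
  meta <- c(seed = as.character(config$master_seed),
            config = config_hash(config))
  write_tsv(gates, file.path(out, "flow_gates.tsv"), meta)
  write_tsv(summary, file.path(out, "flow_summary.tsv"), meta)
  invisible(list(gates = gates, summary = summary))
}

#' Run the footprinting analysis
#'
#' Reads each with/without trace pair written by [run_synth()], runs the
#' full differential peak-height pipeline, and writes the calibrated
#' profile and called regions per protein.
#'
#' @param config a [run_config()].
#' @param proteins protein labels to analyze (default: the footprint
#'   presets).
#' @return named list of [analyze_footprint()] results, invisibly.
#' @export
run_footprint <- function(config = run_config(),
                          proteins = names(footprint_presets())) {
  out <- config$outdir
  probe <- yvmc_probe(config$footprint$tss_offset_atg)
  fc <- config$footprint
  meta <- c(seed = as.character(config$master_seed),
            config = config_hash(config))
  res <- list()
  for (p in proteins) {
    tr <- lapply(c("with", "without"), function(lab) {
      d <- read_tsv(file.path(out, sprintf("trace_%s_%s.tsv", p, lab)),
                    c("scan", "sample_signal", "ladder_signal", "label"))
      fa_trace(d$scan, d$sample_signal, d$ladder_signal, d$label[1])
    })
    ana <- tryCatch(
      analyze_footprint(tr[[1]], tr[[2]], probe, tol_bp = fc$tol_bp,
                        tau = fc$tau, min_run = fc$min_run),
      error = function(e) {
        if (inherits(e, "calibration_failure"))
          pk_stop(sprintf("%s: %s", p, conditionMessage(e)),
                  "calibration_failure")
        stop(e)
      })
    write_tsv(data.frame(position = ana$profile$positions,
                         differential = ana$profile$values),
              file.path(out, sprintf("profile_%s.tsv", p)), meta)
    write_tsv(ana$regions, file.path(out, sprintf("regions_%s.tsv", p)),
              meta)
    res[[p]] <- ana
  }
  invisible(res)
}
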
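#' Configure an end-to-end pipeline run
#'
#' Bundles the per-stage configurations, stage toggles, a single global seed
#' (from which every stage derives its own sub-seed, so one value reproduces
#' the whole run) and the output directory.
#'
#' @param seed global integer seed.
#' @param outdir directory for all written artifacts (created if needed).
#' @param stages named logical vector toggling `profiles`, `chip`,
#'   `extrusion`, `contacts`; `contacts` requires `extrusion`.
#' @param profile_cfg a [profile_sim_config()], or a path to a traces TSV to
#'   ingest instead of simulating.
#' @param region_cfg a [region_config()].
#' @param test_channel channel compared between signal and control regions.
#' @param fish_channel channel used to locate the signal region.
#' @param chip_cfg a [chip_sim_config()], or a path to a chip TSV.
#' @param positive_control,negative_control ChIP normaliser / baseline loci.
#' @param fiber a [fiber_spec()] for the extrusion stage.
#' @param model a [contact_model()] for the contacts stage.
#' @param star_thresholds star-label threshold table.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            outdir = tempfile("hetloop_run_"),
                            stages = c(profiles = TRUE, chip = TRUE,
                                       extrusion = TRUE, contacts = TRUE),
                            profile_cfg = profile_sim_config(),
                            region_cfg = region_config(),
                            test_channel = "DNA",
                            fish_channel = "FISH",
                            chip_cfg = chip_sim_config(),
                            positive_control = "maSat",
                            negative_control = "act",
                            fiber = fiber_spec(6e6,
                                               het_intervals = list(c(2e6, 4e6)),
                                               het_multiplier = 3),
                            model = contact_model(),
                            star_thresholds = c("**" = 0.001, "*" = 0.05)) {
  stop_if_not_scalar_number(seed, "seed")
  stopifnot(is.logical(stages), !is.null(names(stages)))
  want <- c("profiles", "chip", "extrusion", "contacts")
  st <- stats::setNames(rep(FALSE, length(want)), want)
  st[names(stages)] <- stages
  if (st["contacts"] && !st["extrusion"])
    stop("the contacts stage requires the extrusion stage", call. = FALSE)
  # validate resolvable inputs up front
  if (st["profiles"] && is.character(profile_cfg) &&
      !file.exists(profile_cfg))
    stop(sprintf("profile stage: traces file not found: %s", profile_cfg),
         call. = FALSE)
  if (st["chip"] && is.character(chip_cfg) && !file.exists(chip_cfg))
    stop(sprintf("chip stage: table file not found: %s", chip_cfg),
         call. = FALSE)
  structure(list(seed = seed, outdir = outdir, stages = st,
                 profile_cfg = profile_cfg, region_cfg = region_cfg,
                 test_channel = test_channel, fish_channel = fish_channel,
                 chip_cfg = chip_cfg, positive_control = positive_control,
                 negative_control = negative_control,
                 fiber = fiber, model = model,
                 star_thresholds = star_thresholds),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate or ingest
#' traces, bin and average profiles, select signal/control regions, KS
#' comparison, ChIP enrichment statistics, loop-extrusion simulation,
#' contact sampling, P(s) curves (het and eu, N50-truncated) and drop-off
#' detection — writing each intermediate artifact in its standard format
#' under `config$outdir` and returning a structured report. Re-running with
#' the same configuration reproduces every output byte for byte; the report
#' is also written to `report.json` with seed and parameter provenance.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly a nested list of stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logmsg <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  report <- list(seed = config$seed,
                 stages = names(config$stages)[config$stages])
  st <- config$stages

  if (st["profiles"]) {
    logmsg("profile", "building chromosome intensity profiles")
    if (is.character(config$profile_cfg)) {
      traces <- read_traces(config$profile_cfg)
      prof_seed <- NA_real_
    } else {
      pcfg <- config$profile_cfg
      prof_seed <- derive_seed(config$seed, "profiles")
      pcfg$seed <- prof_seed
      traces <- simulate_trace_set(pcfg)
      write_traces(traces, file.path(config$outdir, "traces.tsv"))
    }
    test_binned <- bin_traces(traces, config$test_channel)
    test_prof <- average_binned(test_binned)
    fish_prof <- average_binned(bin_traces(traces, config$fish_channel))
    write_profile_bedgraph(test_prof,
                           file.path(config$outdir, "profile_test.bedgraph"))
    write_profile_bedgraph(fish_prof,
                           file.path(config$outdir, "profile_fish.bedgraph"))
    signal <- select_signal_region(fish_prof, config$region_cfg)
    controls <- select_control_regions(test_prof, signal, config$region_cfg)
    write_regions_bed(c(list(signal), controls),
                      file.path(config$outdir, "regions.bed"),
                      n_bins = test_prof$n_bins)
    ks <- lapply(controls, function(ctrl)
      region_ks_test(test_binned, signal, ctrl, config$star_thresholds))
    ks_df <- do.call(rbind, lapply(seq_along(ks), function(i)
      data.frame(region_a = "signal", region_b = controls[[i]]$label,
                 D = ks[[i]]$statistic_D, p = ks[[i]]$p_value,
                 n = ks[[i]]$n_a, star = ks[[i]]$star_label)))
    write_tsv(ks_df, file.path(config$outdir, "ks_results.tsv"))
    report$profiles <- list(
      seed = prof_seed, n_images = test_prof$n_images,
      signal_bins = signal$bin_indices,
      control_bins = lapply(controls, function(r) r$bin_indices),
      ks = ks_df)
  }

  if (st["chip"]) {
    logmsg("chip", "computing ChIP-qPCR enrichment statistics")
    if (is.character(config$chip_cfg)) {
      chip <- read_chip_table(config$chip_cfg)
      chip_seed <- NA_real_
    } else {
      ccfg <- config$chip_cfg
      chip_seed <- derive_seed(config$seed, "chip")
      ccfg$seed <- chip_seed
      chip <- simulate_chip_table(ccfg)
      write_chip_table(chip, file.path(config$outdir, "chip.tsv"))
    }
    enr <- normalize_to_positive(chip, config$positive_control,
                                 config$negative_control)
    summ <- summarize_enrichment(enr, config$star_thresholds)
    write_tsv(summ, file.path(config$outdir, "chip_results.tsv"))
    report$chip <- list(seed = chip_seed, summary = summ)
  }

  if (st["extrusion"]) {
    logmsg("extrusion", "simulating condensin loop extrusion")
    fib <- config$fiber
    ext_seed <- derive_seed(config$seed, "extrusion")
    fib$seed <- ext_seed
    array <- simulate_extrusion(fib)
    write_loops_bed(array, file.path(config$outdir, "loops.bed"))
    stats <- pool_loop_stats(loop_statistics(array, fib))
    write_tsv(stats, file.path(config$outdir, "loop_stats.tsv"))
    report$extrusion <- list(seed = ext_seed, n_loops = nrow(array$loops),
                             stats = stats)
  }

  if (st["contacts"]) {
    logmsg("contacts", "sampling contacts and estimating P(s)")
    mdl <- config$model
    con_seed <- derive_seed(config$seed, "contacts")
    mdl$seed <- con_seed
    contacts <- sample_contacts(array, mdl)
    write_pairs(contacts, file.path(config$outdir, "contacts.tsv"))
    regions <- fiber_regions(fib)
    curves <- list()
    drop <- list()
    for (lb in unique(regions$label)) {
      r <- regions[regions$label == lb, , drop = FALSE][1, ]
      sub <- subset_contacts(contacts, r$start, r$end, lb)
      cs <- contig_set(stats::setNames(r$end - r$start, lb))
      curve <- ps_curve(sub, cs, truncation = "n50")
      write_ps_curve(curve, file.path(config$outdir,
                                      sprintf("ps_%s.tsv", lb)))
      curves[[lb]] <- curve
      drop[[lb]] <- dropoff_distance(curve)
    }
    report$contacts <- list(seed = con_seed,
                            n_contacts = nrow(contacts),
                            dropoff_bp = drop)
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  logmsg("report", "written to %s", file.path(config$outdir, "report.json"))
  invisible(report)
}
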
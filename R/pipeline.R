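#' Pipeline configuration
#'
#' Defaults mirror the published analysis: 10-ms bins, 200-ms windows slid
#' in 10-ms steps, threshold percentiles 85-90, 45 surrogate iterations for
#' reciprocity normalization, 50 decoder repeats. Any field can be
#' overridden.
#'
#' @param out_dir output directory
#' @param seed master seed for every stochastic stage
#' @param cohort a [cohort_config()] for the simulate stage (its `seed` is
#'   overridden by `seed`)
#' @param stages character vector of stages to run, in dependency order from
#'   `c("simulate", "build_fn", "surrogate", "gas", "reciprocity", "decode",
#'   "embed")`
#' @param bin_width,window,step FN geometry (s)
#' @param align_event alignment event for windowed stages
#' @param percentiles reciprocity threshold percentiles
#' @param n_surrogates surrogate iterations (45)
#' @param n_repeats decoder repeats per cell (50)
#' @param decode_offsets,decode_modes decoding windows (s post-event) and
#'   feature sets
#' @param reciprocity_extent,embed_mode further stage knobs
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort = cohort_config(),
                            stages = c("simulate", "build_fn", "surrogate",
                                       "gas", "reciprocity", "decode",
                                       "embed"),
                            bin_width = 0.010, window = 0.200, step = 0.010,
                            align_event = "instruction",
                            percentiles = 85:90, n_surrogates = 45L,
                            n_repeats = 50L,
                            decode_offsets = seq(0, 0.5, by = 0.1),
                            decode_modes = c("FR", "FN", "FRFN", "nullFN"),
                            reciprocity_extent = c(0, 0.6),
                            embed_mode = "full_trial") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated cohort (or
#' on spike/trial tables already in `out_dir` from a previous run), writing
#' every intermediate table as delimited text plus a JSON run manifest
#' (seeds, parameters, package version, per-stage timing). Stage failures
#' halt the run with the stage name; completed outputs are retained.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return (invisibly) list with the in-memory results of each stage and the
#'   manifest
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "dynfn",
                   version = as.character(utils::packageVersion("dynfn")),
                   seed = config$seed, timing_s = list(),
                   parameters = config[setdiff(names(config), "cohort")],
                   cohort = unclass(config$cohort))
  res <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    say("[%s] running ...", name)
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$timing_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  res$cohort <- run_stage("simulate", function() {
    cc <- config$cohort
    cc$seed <- config$seed
    cohort <- generate_cohort(cc)
    write_spike_events(cohort$spikes, file.path(config$out_dir, "spikes.tsv"))
    write_trial_table(cohort$trials, file.path(config$out_dir, "trials.tsv"))
    write_kinematics(cohort$kinematics,
                     file.path(config$out_dir, "kinematics.tsv"))
    cohort
  })
  spikes <- res$cohort$spikes
  trials <- res$cohort$trials
  if (is.null(spikes)) {
    spikes <- read_spike_events(file.path(config$out_dir, "spikes.tsv"))
    trials <- filter_trials(read_trial_table(
      file.path(config$out_dir, "trials.tsv")))
  }
  ids <- included_trials(trials)
  dirs <- trials$target_direction[match(ids, trials$trial_id)]

  res$fns <- run_stage("build_fn", function() {
    fns <- build_trial_fns(spikes, trials, mode = "full",
                           bin_width = config$bin_width)
    for (i in seq_along(fns))
      write_fn(fns[[i]], file.path(config$out_dir,
                                   sprintf("fn_trial%03d.tsv", i)))
    fns
  })

  res$null_fns <- run_stage("surrogate", function() {
    build_null_fns(spikes, trials, n_iterations = config$n_surrogates,
                   mode = "full", bin_width = config$bin_width,
                   seed = derive_seed(config$seed, 7L))
  })

  res$gas <- run_stage("gas", function() {
    stopifnot(!is.null(res$fns))
    g <- group_gas_by_target_delta(res$fns, dirs)
    utils::write.table(g, file.path(config$out_dir, "gas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    g
  })

  res$reciprocity <- run_stage("reciprocity", function() {
    ext <- config$reciprocity_extent
    t_i <- trials$t_instruction[match(ids, trials$trial_id)]
    tfns <- build_trial_fns(spikes, trials, mode = "temporal",
                            window = config$window, step = config$step,
                            bin_width = config$bin_width,
                            align_event = config$align_event,
                            t_start = min(t_i) + ext[1] - config$window,
                            t_stop = min(t_i) + ext[2])
    null_tfns <- build_null_fns(spikes, trials,
                                n_iterations = config$n_surrogates,
                                mode = "temporal", window = config$window,
                                step = config$step,
                                bin_width = config$bin_width,
                                align_event = config$align_event,
                                t_start = min(t_i) + ext[1] - config$window,
                                t_stop = min(t_i) + ext[2],
                                seed = derive_seed(config$seed, 13L))
    rt <- reciprocity_timeline(tfns, null_tfns,
                               percentiles = config$percentiles)
    utils::write.table(rt, file.path(config$out_dir, "reciprocity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rt
  })

  res$decoding <- run_stage("decode", function() {
    d <- decoding_timeline(spikes, trials, offsets = config$decode_offsets,
                           modes = config$decode_modes,
                           align_event = config$align_event,
                           n_repeats = config$n_repeats,
                           seed = derive_seed(config$seed, 23L),
                           window = config$window,
                           bin_width = config$bin_width)
    utils::write.table(d, file.path(config$out_dir, "decoding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })

  res$embedding <- run_stage("embed", function() {
    stopifnot(!is.null(res$fns))
    vec <- do.call(rbind, lapply(res$fns, vectorize_fn))
    nn <- min(50L, nrow(vec) - 1L)
    emb <- embed_fns(vec, mode = config$embed_mode,
                     seed = derive_seed(config$seed, 31L),
                     n_neighbors = nn,
                     metadata = data.frame(trial = ids, direction = dirs))
    utils::write.table(
      data.frame(trial = ids, direction = dirs, x = emb$coords[, 1],
                 y = emb$coords[, 2]),
      file.path(config$out_dir, "embedding.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emb
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  say("pipeline complete: %s", config$out_dir)
  invisible(res)
}
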
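#' Pipeline configuration
#'
#' Bundles and validates the per-stage settings of the full survey pipeline.
#' Defaults reproduce the acquisition and serving conditions of the survey
#' this package emulates: seven 60 x 60 montages of 6144 x 4090 px tiles with
#' a 120-um field of view, 12.5% overlap and 8 s dwell; quorum 3 of up to 4
#' views; a specimen density of 207/cm^2 with the [default_taxon_mix()];
#' 271 volunteers with the calibrated default error model.
#'
#' @param montage List: `n_cols`, `n_rows`, `tile_px_x`, `tile_px_y`,
#'   `fov_width_um`, `overlap_frac`, `dwell_s`.
#' @param n_montages Number of montages (default 7).
#' @param consensus List: `quorum`, `max_views`, `order_aware`.
#' @param review List: `seconds_per_image`, `miss_rate`, `escalation_rate`.
#' @param census List: `epsilon_um`.
#' @param simulation List: `density_per_cm2`, `n_volunteers`, plus any
#'   [volunteer_profiles()] rate overrides, and `mix` (a [taxon_mix()] or
#'   named frequency vector).
#' @param master_seed Integer master seed; all stage substream seeds derive
#'   from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(montage = list(), n_montages = 7,
                            consensus = list(), review = list(),
                            census = list(), simulation = list(),
                            master_seed = 1L) {
  m <- utils::modifyList(list(
    n_cols = 60, n_rows = 60, tile_px_x = 6144, tile_px_y = 4090,
    fov_width_um = 120, overlap_frac = 0.125, dwell_s = 8
  ), montage)
  cns <- utils::modifyList(list(quorum = 3, max_views = 4,
                                order_aware = TRUE), consensus)
  rev <- utils::modifyList(list(seconds_per_image = 5, miss_rate = 0,
                                escalation_rate = 0), review)
  cen <- utils::modifyList(list(epsilon_um = 10), census)
  sim <- utils::modifyList(list(density_per_cm2 = 207, n_volunteers = 271,
                                mix = NULL), simulation)
  grid <- tile_grid(m$n_cols, m$n_rows, m$tile_px_x, m$tile_px_y,
                    m$fov_width_um, m$overlap_frac, m$dwell_s)
  if (cns$quorum > cns$max_views) {
    stop("consensus: `quorum` must be <= `max_views`", call. = FALSE)
  }
  expert_oracle(rev$miss_rate, rev$escalation_rate) # validates rates
  if (cen$epsilon_um < 0) stop("census: `epsilon_um` must be >= 0",
                               call. = FALSE)
  if (sim$density_per_cm2 < 0) {
    stop("simulation: `density_per_cm2` must be >= 0", call. = FALSE)
  }
  structure(
    list(montage = m, n_montages = as.integer(n_montages), grid = grid,
         consensus = cns, review = rev, census = cen, simulation = sim,
         master_seed = as.integer(master_seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may define any subset of the blocks `montage`, `consensus`,
#' `review`, `census`, `simulation`, plus `n_montages` and `master_seed`;
#' missing entries fall back to the [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    montage = y$montage %||% list(),
    n_montages = y$n_montages %||% 7,
    consensus = y$consensus %||% list(),
    review = y$review %||% list(),
    census = y$census %||% list(),
    simulation = y$simulation %||% list(),
    master_seed = y$master_seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-stage substream seeds derived from the master seed
stage_seeds <- function(master_seed) {
  set.seed(master_seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("specimens", "transcriptions", "expert", "profiles"))
}

#' Run the full survey pipeline
#'
#' Executes, in order: synthetic specimen-field generation and volunteer
#' simulation (or ingestion of a transcription export), consensus
#' aggregation, expert review of the queue, overlap deduplication, and the
#' census, writing every report to `out_dir` when given. All randomness
#' derives from the configuration's master seed, so reports are reproducible
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param input `"simulate"` (default) or the path of a transcription export.
#' @param schema Schema for reading a transcription export
#'   ([transcription_schema()]).
#' @param out_dir Optional output directory (created if needed).
#' @return A list with elements `grids`, `specimens`, `annotations`,
#'   `responses`, `verdicts`, `flow`, `queue`, `review`, `dedup`, `census`,
#'   `performance`, `seeds` (simulation-only elements are `NULL` when running
#'   on an external export, where no ground truth or expert oracle exists).
#' @export
run_pipeline <- function(config, input = "simulate",
                         schema = synthetic_schema(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$master_seed)
  grids <- stats::setNames(rep(list(config$grid), config$n_montages),
                           sprintf("m%d", seq_len(config$n_montages)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, object, file, ...) {
    if (!is.null(out_dir)) writer(object, file.path(out_dir, file), ...)
  }

  simulate <- identical(input, "simulate")
  specimens <- annotations <- profiles <- NULL
  if (simulate) {
    sim <- config$simulation
    mix <- if (is.null(sim$mix)) default_taxon_mix() else {
      if (inherits(sim$mix, "taxon_mix")) sim$mix else taxon_mix(unlist(sim$mix))
    }
    prof_args <- sim[setdiff(names(sim),
                             c("density_per_cm2", "n_volunteers", "mix"))]
    profiles <- do.call(volunteer_profiles,
                        c(list(n = sim$n_volunteers, seed = seeds[["profiles"]],
                               taxa = mix_taxa(mix)), prof_args))
    specimens <- withCallingHandlers(
      generate_specimens(grids, sim$density_per_cm2, mix,
                         seed = seeds[["specimens"]]),
      error = function(e) stop("stage `simulate`: ", conditionMessage(e),
                               call. = FALSE)
    )
    annotations <- truth_annotations(specimens, grids)
    responses <- simulate_transcriptions(
      annotations, grids, profiles,
      quorum = config$consensus$quorum,
      max_views = config$consensus$max_views,
      seed = seeds[["transcriptions"]]
    )
    emit(function(o, p) readr::write_csv(o, p), specimens,
         "ground_truth_specimens.csv")
    emit(write_transcriptions, responses, "transcriptions.csv")
  } else {
    parsed <- tryCatch(read_transcriptions(input, schema),
                       error = function(e) stop("stage `ingest`: ",
                                                conditionMessage(e),
                                                call. = FALSE))
    responses <- parsed$responses
  }

  verdicts <- tryCatch(
    consensus_verdicts(responses,
                       quorum = config$consensus$quorum,
                       max_views = config$consensus$max_views,
                       order_aware = config$consensus$order_aware),
    error = function(e) stop("stage `consensus`: ", conditionMessage(e),
                             call. = FALSE)
  )
  flow <- flow_report(verdicts)
  emit(write_flow_json, flow, "flow_report.json", seed = config$master_seed)
  queue <- build_review_queue(verdicts)
  if (!is.null(out_dir)) {
    writeLines(queue, file.path(out_dir, "review_queue.txt"))
  }

  review <- dedup <- census <- performance <- NULL
  if (simulate) {
    review <- tryCatch(
      expert_verify(queue, annotations,
                    expert_oracle(config$review$miss_rate,
                                  config$review$escalation_rate),
                    all_images = unlist(lapply(names(grids), function(mid) {
                      all_image_ids(grids[[mid]], mid)
                    }), use.names = FALSE),
                    seed = seeds[["expert"]]),
      error = function(e) stop("stage `review`: ", conditionMessage(e),
                               call. = FALSE)
    )
    emit(write_detections, review$detections, "expert_detections.csv")
    totals <- dataset_totals(grids)
    dedup <- deduplicate_detections(review$detections, grids,
                                    config$census$epsilon_um)
    census <- census_table(dedup$specimens, totals$total_area_cm2_exact)
    emit(write_census_csv, census, "census.csv")
    emit(write_census_json, census, "census.json",
         seed = config$master_seed)
    performance <- detection_performance(specimens, dedup$specimens,
                                         config$census$epsilon_um)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(report = "performance", seed = config$master_seed,
             recall = performance$recall, n_truth = performance$n_truth,
             n_matched = performance$n_matched,
             n_false = performance$n_false),
        file.path(out_dir, "performance.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
  }

  list(grids = grids, specimens = specimens, annotations = annotations,
       responses = responses, verdicts = verdicts, flow = flow,
       queue = queue, review = review, dedup = dedup, census = census,
       performance = performance, seeds = seeds)
}
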
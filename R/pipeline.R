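#' Experiment configuration for a replicate-precision study
#'
#' Describes a full study grid: one phantom, a set of named imaging /
#' segmentation conditions (each producing a replicate set), and a list of
#' condition pairs to compare. Two condition modes exist: `"mesh"`
#' perturbs the phantom surface directly (fast path; a [noise_spec()]),
#' and `"volume"` rasterizes a synthetic CT per replicate and segments it
#' (full path; an [imaging_spec()] plus segmentation parameters). Observer
#' variability is emulated on the full path by perturbing the
#' region-growing threshold per replicate (`threshold_jitter_sd`, HU).
#'
#' @param phantom list with `kind`, `dimensions` and optional `resolution`
#'   for [make_base_shape()].
#' @param conditions named list; each element a list with `n_replicates`
#'   (>= 2), `mode` (`"mesh"` or `"volume"`), and a `noise` list (mesh
#'   mode) or `imaging` + `segmentation` lists (volume mode).
#' @param comparisons list of 2-element character vectors naming
#'   conditions to compare.
#' @param thresholds SD cutoffs in mm (see [sd_thresholds()]).
#' @param estimator `"rms"` or `"sample_sd"`.
#' @param seed master integer seed; all condition and replicate streams
#'   derive from it.
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(phantom, conditions, comparisons = list(),
                              thresholds = c(0.07, 0.175, 0.35, 0.7),
                              estimator = "rms", seed = 1L) {
  cfg <- structure(list(phantom = phantom, conditions = conditions,
                        comparisons = comparisons,
                        thresholds = sd_thresholds(thresholds),
                        estimator = estimator, seed = as.integer(seed)),
                   class = "experiment_config")
  validate_config(cfg)
  cfg
}

config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validate_config <- function(config) {
  if (is.null(config$phantom$kind) || is.null(config$phantom$dimensions))
    config_error("config: phantom needs 'kind' and 'dimensions'")
  if (length(config$conditions) == 0 ||
      is.null(names(config$conditions)) ||
      any(!nzchar(names(config$conditions))))
    config_error("config: conditions must be a named list")
  for (lab in names(config$conditions)) {
    cond <- config$conditions[[lab]]
    if (is.null(cond$n_replicates) || cond$n_replicates < 2)
      config_error(sprintf("config: condition '%s' needs n_replicates >= 2",
                           lab))
    mode <- cond$mode %||% "mesh"
    if (!mode %in% c("mesh", "volume"))
      config_error(sprintf("config: condition '%s' has unknown mode '%s'",
                           lab, mode))
    if (mode == "volume" && (is.null(cond$imaging) ||
                             is.null(cond$segmentation)))
      config_error(sprintf(
        "config: volume condition '%s' needs 'imaging' and 'segmentation'",
        lab))
  }
  for (pair in config$comparisons) {
    if (length(pair) != 2)
      config_error("config: each comparison must name two conditions")
    miss <- setdiff(pair, names(config$conditions))
    if (length(miss) > 0)
      config_error(sprintf("config: comparison references undefined condition '%s'",
                           miss[1]))
  }
  if (!config$estimator %in% c("rms", "sample_sd"))
    config_error(sprintf("config: unknown estimator '%s'", config$estimator))
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment configuration from YAML or JSON
#' @param path configuration file.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s",
                                               path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else config_error(sprintf("unsupported config format '%s'", ext))
  # comparisons may arrive as a list of vectors or a 2-column structure
  comps <- raw$comparisons %||% list()
  if (is.matrix(comps) || is.data.frame(comps))
    comps <- lapply(seq_len(nrow(comps)), function(i)
      as.character(unlist(comps[i, ])))
  experiment_config(phantom = raw$phantom, conditions = raw$conditions,
                    comparisons = comps,
                    thresholds = raw$thresholds %||%
                      c(0.07, 0.175, 0.35, 0.7),
                    estimator = raw$estimator %||% "rms",
                    seed = raw$seed %||% 1L)
}

#' Produce the replicate set of one named condition
#'
#' Mesh-mode conditions perturb the phantom directly; volume-mode
#' conditions rasterize one synthetic CT per replicate (independent noise
#' substreams) and segment each. Deterministic given the config's master
#' seed.
#'
#' @param config an [experiment_config()].
#' @param label condition name.
#' @param base optional pre-built phantom mesh (rebuilt from the config
#'   when omitted).
#' @return a [replicate_set()].
#' @export
run_condition <- function(config, label, base = NULL) {
  validate_config(config)
  if (!label %in% names(config$conditions))
    config_error(sprintf("run_condition: undefined condition '%s'", label))
  cond <- config$conditions[[label]]
  cond_index <- match(label, names(config$conditions))
  cond_seed <- derive_seed(config$seed, cond_index)
  if (is.null(base))
    base <- make_base_shape(config$phantom$kind, config$phantom$dimensions,
                            config$phantom$resolution)
  mode <- cond$mode %||% "mesh"
  if (mode == "mesh") {
    ns <- cond$noise %||% list()
    spec <- noise_spec(global_sigma = ns$global_sigma %||% 0,
                       patches = ns$patches %||% list(),
                       resample_fraction = ns$resample_fraction %||% 0,
                       seed = cond_seed)
    return(perturb_replicates(base, cond$n_replicates, spec, label = label))
  }
  im <- cond$imaging
  sg <- cond$segmentation
  meshes <- vector("list", cond$n_replicates)
  for (i in seq_len(cond$n_replicates)) {
    rep_seed <- derive_seed(cond_seed, i)
    spec <- imaging_spec(spacing = im$spacing %||% 0.5,
                         slice_thickness = im$slice_thickness %||% 0.9,
                         exposure_fraction = im$exposure_fraction %||% 1,
                         hu_bone = im$hu_bone %||% 400,
                         hu_background = im$hu_background %||% 0,
                         noise_sigma_ref = im$noise_sigma_ref %||% 0,
                         seed = rep_seed)
    vol <- rasterize_volume(base, spec)
    lower <- sg$lower
    if (!is.null(sg$threshold_jitter_sd) && sg$threshold_jitter_sd > 0)
      lower <- lower + with_seed(derive_seed(cond_seed, 10000L + i),
                                 rnorm(1, 0, sg$threshold_jitter_sd))
    meshes[[i]] <- tryCatch(
      segment(vol, lower = lower, upper = sg$upper,
              close_radius = sg$close_radius %||% 0,
              smooth_sigma = sg$smooth_sigma %||% 0),
      error = function(e) stop(sprintf(
        "run_condition '%s', replicate %d: %s", label, i,
        conditionMessage(e)), call. = FALSE))
  }
  replicate_set(meshes, label = label)
}

#' Compare two replicate sets of one study
#'
#' Balanced single-point SD per set, threshold fraction rows, the
#' two-sample KS result, and one colour-mapped mesh per side.
#'
#' @param config an [experiment_config()].
#' @param pair character vector of two condition labels.
#' @param sets named list of [replicate_set()] objects containing both.
#' @export
run_comparison <- function(config, pair, sets) {
  if (!all(pair %in% names(sets)))
    config_error(sprintf("run_comparison: missing condition '%s'",
                         setdiff(pair, names(sets))[1]))
  fa <- balanced_sd(sets[[pair[1]]], config$estimator)
  fb <- balanced_sd(sets[[pair[2]]], config$estimator)
  list(pair = pair,
       ks = ks_compare(fa, fb),
       fractions = list(fraction_table(fa, config$thresholds),
                        fraction_table(fb, config$thresholds)),
       colour_meshes = list(colour_map(fa, config$thresholds),
                            colour_map(fb, config$thresholds)))
}

#' Run a full study: all conditions, then all comparisons
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory; when given, the fraction
#'   table (CSV + JSON), per-comparison KS results (JSON), colour-mapped
#'   PLY meshes and a machine-readable run manifest are written there.
#' @return a `report_bundle`: fraction table over all conditions, KS
#'   results per comparison, colour meshes, and the manifest.
#' @export
run_study <- function(config, out_dir = NULL) {
  validate_config(config)
  base <- make_base_shape(config$phantom$kind, config$phantom$dimensions,
                          config$phantom$resolution)
  sets <- lapply(names(config$conditions), function(lab)
    run_condition(config, lab, base = base))
  names(sets) <- names(config$conditions)
  fields <- lapply(sets, balanced_sd, estimator = config$estimator)
  rows <- lapply(fields, fraction_table, thresholds = config$thresholds)
  fractions <- result_table(rows, config$thresholds)
  comparisons <- lapply(config$comparisons, function(pair)
    run_comparison(config, pair, sets))
  manifest <- list(
    package = "meshprecision",
    version = as.character(packageVersion("meshprecision")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    phantom = config$phantom,
    thresholds = as.numeric(config$thresholds),
    estimator = config$estimator,
    conditions = config$conditions,
    comparisons = config$comparisons)
  bundle <- structure(list(fractions = fractions,
                           comparisons = comparisons,
                           fields = fields,
                           manifest = manifest),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  print(as.data.frame(x$fractions))
  for (cmp in x$comparisons) {
    cat(sprintf("%s vs %s: ", cmp$pair[1], cmp$pair[2]))
    print(cmp$ks)
  }
  invisible(x)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(bundle$fractions, file.path(out_dir, "fractions.csv"))
  write_table(bundle$fractions, file.path(out_dir, "fractions.json"))
  ks <- lapply(bundle$comparisons, function(cmp)
    c(list(pair = cmp$pair), unclass(cmp$ks)))
  jsonlite::write_json(ks, file.path(out_dir, "ks_results.json"),
                       auto_unbox = TRUE, digits = NA)
  for (cmp in bundle$comparisons)
    for (s in 1:2)
      write_mesh(cmp$colour_meshes[[s]],
                 file.path(out_dir, sprintf("colour_%s.ply", cmp$pair[s])),
                 with_colours = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
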
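# End-to-end driver: preprocess -> superpixels -> (optional generator
# training) -> relevance -> evaluation, with a reproducibility manifest.
# Single-process and deterministic: all stage randomness derives from the
# one config seed via named substreams.

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Preprocess a volume per the pipeline configuration
#'
#' Center crop and per-channel min-max normalization, in the configured
#' order (default: normalize after cropping).
#'
#' @param v a [volume()].
#' @param config a [pipeline_config()].
#' @return The preprocessed [volume()].
#' @export
preprocess_volume <- function(v, config) {
  stopifnot(inherits(config, "pipeline_config"))
  crop <- function(x) if (is.null(config$crop_shape)) x
                      else center_crop(x, config$crop_shape)
  if (config$normalize_order == "before_crop") crop(normalize_minmax(v))
  else normalize_minmax(crop(v))
}

#' Run the full relevance-map pipeline
#'
#' Executes every stage on a set of cases and writes all artifacts
#' (relevance heatmaps as NIfTI, per-case JSON sidecars, an evaluation
#' report TSV when references exist, and a run manifest) under
#' `out_dir`. Inputs are never mutated.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param cases list of cases, each a list with `volume` (a [volume()])
#'   and optional `reference` ([binary_mask()]) and `case_id`. Phantom
#'   samples from [generate_dataset()] are accepted directly (their
#'   lesion masks become references).
#' @param phantom optional [phantom_spec()]; when given (and `cases` is
#'   `NULL`), `n_cases` phantoms are generated from the config seed.
#' @param n_cases number of phantoms to generate in phantom mode.
#' @param classifier a classifier honouring [predict_prob()], or
#'   `"oracle"` (phantom mode only) for a per-case
#'   [oracle_region_classifier()] over the lesion on the superpixel
#'   channel.
#' @param generator optional `mask_generator`, required when
#'   `config$perturbation_kind == "optimal"` unless
#'   `train_generator = TRUE`.
#' @param train_generator train a generator on the cases' superpixel
#'   decomposition before scoring (optimal kind only).
#' @param generator_epochs epochs for that training (default 25).
#' @param max_rank depth of the ranked/combined evaluation tables.
#' @return Invisibly, a list with `report` (data.frame or `NULL`),
#'   `manifest`, and per-case relevance maps.
#' @export
run_pipeline <- function(config, out_dir, cases = NULL, phantom = NULL,
                         n_cases = 5L, classifier = "oracle",
                         generator = NULL, train_generator = FALSE,
                         generator_epochs = 25L, max_rank = 3L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$perturbation_kind == "optimal" && is.null(generator) &&
      !isTRUE(train_generator))
    stop("perturbation_kind 'optimal' requires a generator ",
         "(pass `generator` or set train_generator = TRUE)")
  if (is.null(cases)) {
    if (is.null(phantom)) stop("provide `cases` or a `phantom` spec")
    cases <- generate_dataset(phantom, n_cases,
                              seed = derive_seed(config$seed, "pipeline_phantom"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  norm_cases <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    list(volume = preprocess_volume(cs$volume, config),
         reference = if (!is.null(cs$reference)) cs$reference
                     else cs$lesion_mask,
         case_id = if (!is.null(cs$case_id)) cs$case_id
                   else sprintf("case_%03d", i))
  })

  sps <- lapply(norm_cases, function(cs)
    compute_superpixels(cs$volume, config$superpixel_channel,
                        config$n_superpixels_requested, config$compactness,
                        seed = derive_seed(config$seed, "slic")))

  clf_for <- function(i) {
    if (!identical(classifier, "oracle")) return(classifier)
    ref <- norm_cases[[i]]$reference
    if (is.null(ref)) stop("classifier = 'oracle' needs reference masks")
    oracle_region_classifier(ref,
      resolve_channel(norm_cases[[i]]$volume, config$superpixel_channel))
  }

  if (config$perturbation_kind == "optimal" && is.null(generator)) {
    ts <- build_training_set(lapply(seq_along(norm_cases), function(i)
      list(volume = norm_cases[[i]]$volume, sp = sps[[i]],
           case_id = norm_cases[[i]]$case_id)))
    if (identical(classifier, "oracle"))
      stop("generator training needs a single trained classifier, ",
           "not per-case oracles")
    generator <- train_generator(ts, classifier, epochs = generator_epochs,
                                 seed = derive_seed(config$seed, "generator"))
  }

  chash <- config_hash(config)
  rms <- vector("list", length(norm_cases))
  for (i in seq_along(norm_cases)) {
    cs <- norm_cases[[i]]
    rm <- tryCatch(
      suppressWarnings(
        compute_relevance_map(clf_for(i), cs$volume, sps[[i]],
                              config$perturbation_kind,
                              generator = generator)),
      error = function(e) stop("stage 'relevance' failed for case ",
                               cs$case_id, ": ", conditionMessage(e)))
    rms[[i]] <- rm
    hm <- relevance_heatmap(rm, sps[[i]])
    arr <- hm$data[1L, , , ]
    dim(arr) <- spatial_shape(hm)
    write_nifti(arr, file.path(out_dir, paste0(cs$case_id, "_relevance.nii.gz")),
                spacing = if (is.null(cs$volume$spacing)) c(1, 1, 1)
                          else cs$volume$spacing)
    save_relevance_json(rm,
                        file.path(out_dir, paste0(cs$case_id, "_relevance.json")),
                        extra = list(case_id = cs$case_id,
                                     config_hash = chash))
  }

  report <- NULL
  have_refs <- all(vapply(norm_cases, function(cs) !is.null(cs$reference),
                          TRUE))
  if (have_refs) {
    eval_cases <- lapply(seq_along(norm_cases), function(i)
      list(rm = rms[[i]], sp = sps[[i]],
           reference = norm_cases[[i]]$reference))
    bg <- vapply(seq_along(eval_cases), function(i)
      best_grouping_dsc(rms[[i]], sps[[i]],
                        norm_cases[[i]]$reference)$dsc, 0)
    mr <- min(max_rank, min(vapply(rms, function(r) r$K, 0L)))
    ranked <- evaluate_ranked(eval_cases, mr)
    combined <- evaluate_combined(eval_cases, mr)
    report <- data.frame(
      metric = c("mean_best_grouping_dsc",
                 paste0("mean_rank", ranked$rank, "_dsc"),
                 paste0("mean_combined_top", combined$k, "_dsc")),
      value = c(mean(bg), ranked$mean_dsc, combined$mean_dsc))
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("relmap3d")),
                   config = unclass(config), config_hash = chash,
                   n_cases = length(norm_cases),
                   case_ids = vapply(norm_cases, `[[`, "", "case_id"),
                   classifier_id = if (identical(classifier, "oracle"))
                     "oracle_per_case" else classifier_id(classifier),
                   generator_id = if (!is.null(generator)) generator$id,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, manifest = manifest, relevance_maps = rms,
                 superpixel_maps = sps))
}
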
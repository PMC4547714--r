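# End-to-end pipeline driver: phantom -> segmentation -> centerline ->
# normalization -> features -> models -> comparison, from one config.

#' Run the curve-assessment pipeline from a config
#'
#' The config (JSON path or list) names inputs per stage; stages present in
#' the config run in order, write their artifacts under `out_dir`, and a run
#' log (parameters, seed, package version, per-stage counts) is written as
#' `run_log.json`. Identical config + seed give identical outputs.
#'
#' Config sections (all optional, at least one required):
#' \describe{
#'   \item{`phantom`}{[phantom_spec()] arguments; writes `phantom_vol.nii.gz`,
#'     `phantom_mask.nii.gz`, `phantom_curve.csv`, `phantom_landmarks.json`.}
#'   \item{`volume`}{either `path` + `landmarks` (file paths) or
#'     `use_phantom: true`; segments the canal, extracts and normalizes the
#'     centerline, writes `mask.nii.gz`, `centerline.csv`, `normalized.csv`,
#'     `features.csv`.}
#'   \item{`groups`}{array of `{label, n, reference}` (or explicit
#'     `params` mean/sd pairs); simulates populations, writes per-group
#'     feature tables and model JSONs.}
#'   \item{`compare`}{`{group_a, group_b, K, alpha}` referring to simulated
#'     group labels; writes `report.json`.}
#' }
#'
#' @param config a list or path to a JSON file.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir` or a temp directory.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% tempfile("canalcurve_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log <- list(seed = seed,
              package_version = as.character(utils::packageVersion("canalcurve")),
              stages = list())
  res <- list(out_dir = out_dir)

  has <- function(nm) !is.null(config[[nm]])
  if (!has("phantom") && !has("volume") && !has("groups"))
    stop("config must request at least one of: phantom, volume, groups",
         call. = FALSE)
  # validate before any compute
  if (has("volume")) {
    v <- config$volume
    if (is.null(v$use_phantom) || !isTRUE(v$use_phantom)) {
      if (is.null(v$path) || is.null(v$landmarks))
        stop("volume stage needs `path` and `landmarks` (or use_phantom)",
             call. = FALSE)
      if (!isTRUE(has("phantom")) && !file.exists(v$path))
        stop("volume file not found: ", v$path, call. = FALSE)
    } else if (!has("phantom")) {
      stop("volume stage asked for the phantom but no phantom stage given",
           call. = FALSE)
    }
  }
  if (has("compare") && !has("groups"))
    stop("compare stage needs simulated groups", call. = FALSE)

  phantom <- NULL
  if (has("phantom")) {
    args <- config$phantom
    if (isTRUE(args)) args <- list()
    args$rng_seed <- args$rng_seed %||% seed
    spec <- do.call(phantom_spec, args)
    phantom <- synthesize_volume(spec)
    write_volume(phantom$volume, file.path(out_dir, "phantom_vol.nii.gz"))
    write_volume(phantom$mask, file.path(out_dir, "phantom_mask.nii.gz"))
    write_curve(phantom$curve, file.path(out_dir, "phantom_curve.csv"))
    write_landmarks(phantom$landmarks,
                    file.path(out_dir, "phantom_landmarks.json"))
    log$stages$phantom <- list(seed = spec$rng_seed, dim = spec$dim,
                               mask_voxels = sum(phantom$mask$data))
    res$phantom <- phantom
  }
  if (has("volume")) {
    v <- config$volume
    if (isTRUE(v$use_phantom)) {
      vol <- phantom$volume
      lm <- phantom$landmarks
    } else {
      vol <- read_volume(v$path)
      lm <- read_landmarks(v$landmarks)
    }
    params <- if (!is.null(v$params)) do.call(segmentation_params, v$params)
              else segmentation_params()
    mask <- segment_canal(vol, params = params)
    ctr <- extract_centerline(mask, step = v$step %||% 1,
                              window = v$window %||% 5)
    cropped <- crop_to_landmarks(ctr, lm)
    norm <- normalize_curve(cropped)
    feats <- compute_features(norm)
    write_volume(mask, file.path(out_dir, "mask.nii.gz"))
    write_curve(ctr, file.path(out_dir, "centerline.csv"))
    write_curve(norm, file.path(out_dir, "normalized.csv"))
    readr::write_csv(feats, file.path(out_dir, "features.csv"))
    log$stages$volume <- c(attr(mask, "segmentation_log")[
      c("coarse_voxels", "refined_voxels")],
      list(centerline_points = nrow(ctr),
           scale_mm = attr(norm, "scale_mm")))
    res$volume <- list(mask = mask, centerline = ctr, normalized = norm,
                       features = feats)
  }
  groups <- list()
  if (has("groups")) {
    gdefs <- config$groups
    if (is.data.frame(gdefs)) gdefs <- split(gdefs, seq_len(nrow(gdefs)))
    for (gi in seq_along(gdefs)) {
      g <- as.list(gdefs[[gi]])
      pars <- if (!is.null(g$reference)) reference_group_params(g$reference)
              else do.call(group_params, c(list(label = g$label), g$params))
      gseed <- seed + gi
      curves <- sample_population(pars, n = g$n, rng_seed = gseed)
      lbl <- g$label %||% pars$label
      groups[[lbl]] <- curves
      feats <- population_features(curves)
      readr::write_csv(feats, file.path(out_dir,
                                        paste0("features_", lbl, ".csv")))
      mod <- build_model(curves, K = g$K %||% 100, label = lbl)
      write_model(mod, file.path(out_dir, paste0("model_", lbl, ".json")))
      log$stages$groups[[lbl]] <- list(n = g$n, seed = gseed)
    }
    res$groups <- groups
  }
  if (has("compare")) {
    cc <- config$compare
    ga <- groups[[cc$group_a %||% names(groups)[1]]]
    gb <- groups[[cc$group_b %||% names(groups)[2]]]
    if (is.null(ga) || is.null(gb))
      stop("compare stage refers to unknown group labels", call. = FALSE)
    rep <- compare_models(ga, gb, K = cc$K %||% 20,
                          alpha = cc$alpha %||% 0.05,
                          welch = isTRUE(cc$welch),
                          dorsal_sign = isTRUE(cc$dorsal_sign))
    write_report(rep, file.path(out_dir, "report.json"))
    log$stages$compare <- list(
      sig_y = count_significant(
        dplyr::filter(rep$pointwise, .data$axis == "y"), rep$alpha),
      sig_x = count_significant(
        dplyr::filter(rep$pointwise, .data$axis == "x"), rep$alpha))
    res$report <- rep
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
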
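#' Monotone nonlinear intensity remapping
#'
#' Square-root transfer over the intensity range: breaks SSD's assumption
#' of comparable intensity scales while preserving all structure, which is
#' exactly the regime where mutual information remains informative.
#'
#' @param vol a [vol3d()].
#' @return remapped [vol3d()] on the same range.
#' @export
remap_intensities <- function(vol) {
  v <- vol$voxels
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) return(vol)
  t <- (v - lo) / (hi - lo)
  vol3d(lo + (hi - lo) * sqrt(t), vol$spacing, vol$origin)
}

exp_methods <- c("atlas-ssd", "atlas-mi", "asm-classic", "asm-knn", "gpmm")

#' Configuration of the phantom comparison experiment
#'
#' Validates names strictly: unknown settings are rejected.
#'
#' @param spec a [phantom_spec()].
#' @param n_cases,n_train cohort size and training split.
#' @param methods subset of
#'   `c("atlas-ssd", "atlas-mi", "asm-classic", "asm-knn", "gpmm")`.
#' @param seed master seed for the split and all seeded stages.
#' @param remap_test apply the monotone intensity remap to test images
#'   before segmenting (atlas methods; used for the MI vs SSD contrast).
#' @param registration [registration_config()] for the atlas methods.
#' @param asm an [asm_config()].
#' @param gpmm list: `iterations`, `candidates`, `model_vertices` (NULL =
#'   the cohort's own resolution).
#' @param output_dir optional directory for CSV/JSON/YAML artifacts.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(spec = phantom_spec(), n_cases = 20L,
                              n_train = 10L, methods = exp_methods,
                              seed = 1L, remap_test = FALSE,
                              registration = registration_config(
                                levels = c(0.25, 0.5, 1),
                                max_iter = c(30L, 15L, 8L),
                                grid_spacing_mm = 28,
                                min_overlap = 0.5),
                              asm = asm_config(),
                              gpmm = list(iterations = 150L, candidates = 15L,
                                          model_vertices = NULL),
                              output_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!all(methods %in% exp_methods))
    stop("unknown method(s): ", paste(setdiff(methods, exp_methods), collapse = ", "))
  allowed_gpmm <- c("iterations", "candidates", "model_vertices")
  if (!all(names(gpmm) %in% allowed_gpmm))
    stop("unknown gpmm setting(s): ",
         paste(setdiff(names(gpmm), allowed_gpmm), collapse = ", "))
  structure(list(spec = spec, n_cases = as.integer(n_cases),
                 n_train = as.integer(n_train), methods = methods,
                 seed = as.integer(seed), remap_test = isTRUE(remap_test),
                 registration = registration, asm = asm, gpmm = gpmm,
                 output_dir = output_dir), class = "experiment_config")
}

train_shape_models <- function(cohort, train_idx, config, model_vertices = NULL) {
  if (is.null(model_vertices) ||
      model_vertices == cohort$spec$n_vertices) {
    ref <- cohort$reference
    lm_sets <- lapply(cohort$cases[train_idx], function(cs) cs$mesh$vertices)
  } else {
    ref <- make_reference_organ(model_vertices)
    fields <- cohort_true_fields(cohort, at = ref$vertices, cases = train_idx)
    lm_sets <- lapply(fields, function(f) ref$vertices + f)
  }
  list(reference = ref, landmarks = lm_sets,
       volumes = lapply(cohort$cases[train_idx], `[[`, "image"))
}

segment_with_method <- function(method, tm, cohort, train_idx, target,
                                config, models_env) {
  key <- paste0(method, "/", nrow(tm$reference$vertices))
  if (method %in% c("atlas-ssd", "atlas-mi")) {
    metric <- sub("atlas-", "", method)
    atlas_idx <- train_idx[1] # first training case by sorted id
    atl <- atlas_case(cohort$cases[[atlas_idx]]$image,
                      cohort$cases[[atlas_idx]]$mask)
    return(segment_single_atlas(atl, target, metric, config$registration)$mask)
  }
  if (method %in% c("asm-classic", "asm-knn")) {
    if (is.null(models_env[[key]])) {
      al <- procrustes_align(tm$landmarks)
      pdm <- build_pdm(al$aligned, list(type = "variance", frac = 0.98))
      app <- if (method == "asm-classic")
        build_profile_model(tm$volumes, tm$landmarks, tm$reference$faces, config$asm)
      else
        build_feature_model(tm$volumes, tm$landmarks, tm$reference$faces, config$asm)
      mean_world <- Reduce(`+`, tm$landmarks) / length(tm$landmarks)
      models_env[[key]] <- list(pdm = pdm, app = app, mean_world = mean_world)
    }
    m <- models_env[[key]]
    init <- init_shape_moments(target, m$mean_world, tm$reference$faces)
    fit <- fit_asm(target, m$pdm, m$app, init$shape, config$asm,
                   if (method == "asm-classic") "classic" else "knn")
    return(fit$mask)
  }
  # gpmm
  if (is.null(models_env[[key]])) {
    fields <- lapply(tm$landmarks, function(lm) lm - tm$reference$vertices)
    egp <- build_empirical_gp(fields, tm$reference)
    full_cfg <- asm_config(resolutions = 1,
                           profile_length = config$asm$profile_length,
                           candidate_positions = config$asm$candidate_positions)
    prof <- build_profile_model(tm$volumes, tm$landmarks, tm$reference$faces,
                                full_cfg)
    mean_world <- tm$reference$vertices + egp$mean_field
    models_env[[key]] <- list(egp = egp, prof = prof, mean_world = mean_world)
  }
  m <- models_env[[key]]
  init <- init_shape_moments(target, m$mean_world, tm$reference$faces)
  # translation-only pose: the empirical span absorbs residual size/shape,
  # and a scale error would push the model out of its own span
  pose <- similarity3d(diag(3), init$pose$translation, 1, init$pose$center)
  fit <- fit_gpmm(target, m$egp, m$prof, pose,
                  iterations = config$gpmm$iterations,
                  candidates = config$gpmm$candidates,
                  seed = config$seed)
  fit$mask
}

#' Run the phantom method-comparison experiment
#'
#' Generates (or reuses) a seeded phantom cohort, trains every requested
#' method on the training split, segments each test case, and scores all
#' three quality measures.  Per-case and mean rows are returned and,
#' when `output_dir` is set, written as CSV together with the exact
#' configuration (YAML) and a seed manifest (JSON).
#'
#' @param config an [experiment_config()].
#' @param cohort optional pre-generated [generate_cohort()] cohort matching
#'   `config$spec` (to share one cohort across experiments).
#' @return list with `per_case` and `summary` data frames and `paths` of
#'   written artifacts.
#' @export
run_experiment <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$spec, config$n_cases)
  split <- split_train_test(cohort, config$n_train, config$seed)
  models_env <- new.env(parent = emptyenv())
  rows <- list()
  for (method in config$methods) {
    tm <- train_shape_models(cohort, split$train, config,
                             if (method == "gpmm") config$gpmm$model_vertices
                             else NULL)
    for (ti in split$test) {
      target <- cohort$cases[[ti]]$image
      if (config$remap_test) target <- remap_intensities(target)
      pred <- tryCatch(
        segment_with_method(method, tm, cohort, split$train, target,
                            config, models_env),
        error = function(e) {
          warning(sprintf("%s failed on %s: %s", method,
                          cohort$cases[[ti]]$id, conditionMessage(e)))
          NULL
        })
      row <- if (is.null(pred)) {
        data.frame(case_id = cohort$cases[[ti]]$id, dice_percent = NA_real_,
                   msd_mm = NA_real_, hausdorff_mm = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        evaluate_case(pred, cohort$cases[[ti]]$mask, cohort$cases[[ti]]$id)
      }
      row$method <- method
      rows[[length(rows) + 1L]] <- row
    }
  }
  per_case <- do.call(rbind, rows)[, c("case_id", "method", "dice_percent",
                                       "msd_mm", "hausdorff_mm")]
  summary <- do.call(rbind, lapply(split(per_case, per_case$method), function(d)
    data.frame(method = d$method[1],
               dice_percent = mean(d$dice_percent),
               msd_mm = mean(d$msd_mm),
               hausdorff_mm = mean(d$hausdorff_mm),
               n_cases = nrow(d), stringsAsFactors = FALSE)))
  summary <- summary[match(config$methods, summary$method), , drop = FALSE]
  rownames(summary) <- NULL
  paths <- list()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths$per_case <- file.path(config$output_dir, "report_per_case.csv")
    paths$summary <- file.path(config$output_dir, "report_summary.csv")
    paths$config <- file.path(config$output_dir, "experiment_config.yaml")
    paths$manifest <- file.path(config$output_dir, "manifest.json")
    utils::write.csv(per_case, paths$per_case, row.names = FALSE)
    utils::write.csv(summary, paths$summary, row.names = FALSE)
    cfg_list <- config
    cfg_list$spec <- unclass(cfg_list$spec)
    cfg_list$asm <- unclass(cfg_list$asm)
    yaml::write_yaml(lapply(unclass(cfg_list), function(x)
      if (is.list(x)) x else x), paths$config)
    jsonlite::write_json(list(seed = config$seed, train = split$train,
                              test = split$test,
                              true_alpha = lapply(cohort$cases, `[[`, "true_alpha")),
                         paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(per_case = per_case, summary = summary, paths = paths,
       split = split)
}
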
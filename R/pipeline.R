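# End-to-end driver: from input tables (or in-memory cohorts) to a result
# bundle on disk. Used by the analysis/ scripts; all defaults mirror the
# reported SCN workflow (grid 0.05-0.40 step 0.01, 5000 permutations, 1000
# reported nulls, alpha 0.05, q 0.05, backbone alpha 0.001).

.default_config <- function() {
  list(grid = list(start = 0.05, stop = 0.40, step = 0.01),
       covariates = c("age", "icv"),
       n_perm = 5000, n_null = 1000, n_null_inner = 100,
       alpha = 0.05, q = 0.05, backbone_alpha = 0.001,
       properties = c(.global_properties, .nodal_properties),
       n_jobs = 1)
}

#' Read and validate a run configuration
#'
#' @param config A YAML file path or a named list. Recognised fields:
#'   `input` (list: `stats` = character vector of stats-table paths,
#'   `covariates` = covariate-table path, `measure_kind`), or `cohorts`
#'   (list of two `cohort` objects, as produced by [fixture_cohort()]);
#'   `atlas`; `groups` (two labels to compare); `covariates`; `grid`
#'   (start/stop/step); `n_perm`; `n_null`; `n_null_inner`; `alpha`; `q`;
#'   `backbone_alpha`; `properties`; `seed` (mandatory); `outdir`;
#'   `n_jobs`.
#' @return Validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_config(), config)
  # YAML deserializes vectors as lists; flatten the character fields
  cfg$properties <- unlist(cfg$properties)
  cfg$groups <- unlist(cfg$groups)
  cfg$covariates <- unlist(cfg$covariates)
  if (!is.null(cfg$input)) cfg$input$stats <- unlist(cfg$input$stats)
  if (is.null(cfg$seed)) {
    stop("config must set an integer seed; silent nondeterminism is not ",
         "allowed", call. = FALSE)
  }
  if (is.null(cfg$outdir)) stop("config must set outdir", call. = FALSE)
  if (!is.null(cfg$input)) {
    for (f in c(cfg$input$stats, cfg$input$covariates)) {
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    }
  } else if (is.null(cfg$cohorts)) {
    stop("config needs either input file paths or in-memory cohorts",
         call. = FALSE)
  }
  cfg
}

.config_hash <- function(cfg) {
  # outdir and worker count do not affect the results and are excluded
  keep <- cfg[setdiff(names(cfg), c("cohorts", "outdir", "n_jobs"))]
  keep <- keep[order(names(keep))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full SCN comparison pipeline
#'
#' Loads (or takes) two group cohorts, residualizes age and ICV, builds
#' each group's positive-rectified covariance matrix and thresholded graph
#' stack, computes metric curves with rewired-null normalization and their
#' AUCs, checks the small-world range criterion, extracts correlation-
#' significance edge backbones, runs the unpaired permutation test, and
#' writes the bundle to `config$outdir`.
#'
#' @param config See [read_run_config()].
#' @return Invisibly, a list with `cohorts`, `covariance`, `curves`,
#'   `small_world_fraction`, `backbone`, `test`, `files`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  grid <- sparsity_grid(cfg$grid$start, cfg$grid$stop, cfg$grid$step)

  if (!is.null(cfg$cohorts)) {
    cohorts <- cfg$cohorts
    stopifnot(length(cohorts) == 2L)
    names(cohorts) <- vapply(cohorts, function(co)
      co$subjects$group[1L], character(1))
  } else {
    atlas <- load_atlas(cfg$atlas)
    tables <- lapply(cfg$input$stats, read_stats_table,
                     measure_kind = cfg$input$measure_kind %||% "volume")
    covs <- read_covariates(cfg$input$covariates)
    full <- assemble_cohort(tables, covs, atlas)
    if (is.null(cfg$groups)) {
      stop("config must name the two group labels to compare",
           call. = FALSE)
    }
    cohorts <- lapply(cfg$groups, function(g) {
      idx <- .group_rows(full, g)
      structure(list(subjects = full$subjects[idx, , drop = FALSE],
                     values = full$values[idx, , drop = FALSE],
                     measure_kind = full$measure_kind, atlas = full$atlas),
                class = "cohort")
    })
    names(cohorts) <- cfg$groups
  }
  glab <- names(cohorts)

  message("covnet: residualizing and building group covariance matrices")
  combined <- structure(list(
    subjects = rbind(cohorts[[1L]]$subjects[, c("subject_id", "group",
                                                "age", "icv")],
                     cohorts[[2L]]$subjects[, c("subject_id", "group",
                                                "age", "icv")]),
    values = rbind(cohorts[[1L]]$values, cohorts[[2L]]$values),
    measure_kind = cohorts[[1L]]$measure_kind,
    atlas = cohorts[[1L]]$atlas), class = "cohort")
  resid <- residualize(combined, cfg$covariates)
  covm <- lapply(glab, function(g) covariance_matrix(resid, g))
  names(covm) <- glab

  message("covnet: metric curves with ", cfg$n_null, " rewired nulls")
  curves <- list(); swf <- list(); backbone <- list()
  for (g in glab) {
    stack <- build_graph_stack(covm[[g]], grid)
    set.seed(cfg$seed)
    curves[[g]] <- compute_metric_curves(stack, n_null = cfg$n_null)
    set.seed(cfg$seed)
    swf[[g]] <- suppressWarnings(
      check_small_world_range(stack, n_null = max(20, cfg$n_null_inner)))
    if (as.numeric(swf[[g]]) <= 0.90) {
      message("covnet: WARNING group ", g, ": only ",
              round(100 * as.numeric(swf[[g]])),
              "% of sparsity values are small-world (sigma > 1.1)")
    }
    backbone[[g]] <- edge_backbone(covm[[g]], alpha = cfg$backbone_alpha)
  }

  message("covnet: permutation test (", cfg$n_perm, " permutations)")
  test <- permutation_test_unpaired(
    cohorts[[1L]], cohorts[[2L]], grid = grid, n_perm = cfg$n_perm,
    n_null_inner = cfg$n_null_inner, properties = cfg$properties,
    covariate_names = cfg$covariates, seed = cfg$seed,
    n_jobs = cfg$n_jobs)

  results <- list(cohorts = cohorts, covariance = covm, curves = curves,
                  small_world_fraction = swf, backbone = backbone,
                  test = test, grid = grid, config = cfg)
  results$files <- write_results(results, cfg$outdir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result bundle to disk
#'
#' Deterministic file naming `{comparison}_{atlas}_{content}.tsv`;
#' re-running with an identical config and seed reproduces every file
#' byte-identically. NaN values are serialized as `NA`.
#'
#' @param results List as assembled by [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_results <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create outdir: ", outdir,
                                call. = FALSE)
  glab <- names(results$covariance)
  cmp <- paste(glab, collapse = "-vs-")
  atlas <- results$cohorts[[1L]]$atlas$name
  stem <- function(x) file.path(outdir, paste0(cmp, "_", atlas, "_", x))
  files <- character(0)

  wtsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) ifelse(is.nan(v), NA, v))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  for (g in glab) {
    files <- c(files,
               write_matrix_tsv(results$covariance[[g]],
                                stem(paste0("cov_", g, ".tsv"))),
               wtsv(curves_long(results$curves[[g]], group = g),
                    stem(paste0("curves_", g, ".tsv"))))
    auc <- results$curves[[g]]
    auc_df <- rbind(
      data.frame(group = g, property = names(auc$auc_global),
                 node = "global", auc = unname(auc$auc_global),
                 stringsAsFactors = FALSE),
      data.frame(group = g,
                 property = rep(rownames(auc$auc_nodal),
                                times = ncol(auc$auc_nodal)),
                 node = rep(colnames(auc$auc_nodal),
                            each = nrow(auc$auc_nodal)),
                 auc = as.vector(t(auc$auc_nodal)),
                 stringsAsFactors = FALSE))
    files <- c(files, wtsv(auc_df, stem(paste0("auc_", g, ".tsv"))))
  }
  tst <- results$test$results
  tst$n_perm <- results$test$n_perm
  tst$seed <- results$test$seed
  files <- c(files, wtsv(tst, stem("permutation.tsv")))

  sw <- data.frame(group = glab,
                   fraction_small_world =
                     vapply(results$small_world_fraction, as.numeric,
                            numeric(1)),
                   criterion = "sigma > 1.1 at > 90% of grid",
                   stringsAsFactors = FALSE)
  files <- c(files, wtsv(sw, stem("smallworld_range.tsv")))

  manifest <- list(
    comparison = cmp, atlas = atlas,
    groups = glab,
    n_subjects = vapply(results$cohorts, function(co) nrow(co$values),
                        numeric(1)),
    grid = list(start = attr(results$grid, "start"),
                stop = attr(results$grid, "stop"),
                step = attr(results$grid, "step"),
                n_values = length(results$grid)),
    n_perm = results$config$n_perm, n_null = results$config$n_null,
    n_null_inner = results$config$n_null_inner,
    alpha = results$config$alpha, q = results$config$q,
    backbone_alpha = results$config$backbone_alpha,
    seed = results$config$seed,
    config_hash = .config_hash(results$config),
    covnet_version = as.character(utils::packageVersion("covnet")))
  mf <- stem("manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, mf)
}
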
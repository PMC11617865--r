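# Readers/writers for FreeSurfer-style stats tables (aparcstats2table /
# asegstats2table layout: one subject per row, first column the subject id,
# remaining columns ROI measurements plus summary columns such as eTIV).

# Summary columns that are not parcellation nodes; they are split off and
# offered as covariate candidates (eTIV in particular backs the icv fallback).
.non_roi_patterns <- c(
  "eTIV", "EstimatedTotalIntraCranialVol", "BrainSegVol", "BrainSegVolNotVent",
  "MaskVol", "CortexVol", "CerebralWhiteMatterVol", "SupraTentorialVol",
  "MeanThickness", "WhiteSurfArea", "NumVert", "SurfaceHoles"
)

.is_non_roi <- function(labels) {
  hit <- rep(FALSE, length(labels))
  for (p in .non_roi_patterns) hit <- hit | grepl(p, labels, fixed = TRUE)
  hit
}

#' Read a FreeSurfer-style regional stats table
#'
#' Reads a tab- (or whitespace-) separated table whose first column is the
#' subject identifier and whose remaining columns are per-ROI measurements.
#' Whole-brain summary columns (eTIV, BrainSegVol, MeanThickness, ...) are
#' recognised by name, removed from the ROI matrix and returned separately as
#' covariate candidates.
#'
#' @param path Path to the table.
#' @param measure_kind `"thickness"` (mm) or `"volume"` (mm^3). Thickness
#'   values must be strictly positive.
#' @return An object of class `roi_table`: `subject_ids`, `values` (subjects
#'   x ROIs numeric matrix with dimnames), `measure_kind`, and
#'   `covariate_candidates` (data.frame, possibly zero-column).
#' @export
read_stats_table <- function(path, measure_kind = c("thickness", "volume")) {
  measure_kind <- match.arg(measure_kind)
  if (!file.exists(path)) stop("stats table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty or malformed stats table: ", path, call. = FALSE)
  }
  subject_ids <- df[[1L]]
  labels <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric or non-finite value '", raw[bad[1, 1], bad[1, 2]],
         "' in ", path, " at subject '", subject_ids[bad[1, 1]],
         "', column '", labels[bad[1, 2]], "'", call. = FALSE)
  }
  dimnames(num) <- list(subject_ids, labels)
  non_roi <- .is_non_roi(labels)
  cand <- as.data.frame(num[, non_roi, drop = FALSE])
  values <- num[, !non_roi, drop = FALSE]
  if (ncol(values) == 0L) {
    stop("stats table ", path, " contains no ROI columns", call. = FALSE)
  }
  if (measure_kind == "thickness" && any(values <= 0)) {
    stop("thickness table ", path, " contains non-positive values",
         call. = FALSE)
  }
  structure(list(subject_ids = subject_ids, values = values,
                 measure_kind = measure_kind,
                 covariate_candidates = cand),
            class = "roi_table")
}

#' Write a regional stats table
#'
#' Inverse of [read_stats_table()]: writes the ROI matrix (and any covariate
#' candidate columns) as a tab-separated table that [read_stats_table()]
#' reads back identically up to float formatting.
#'
#' @param x An `roi_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(x, path) {
  stopifnot(inherits(x, "roi_table"))
  df <- data.frame(subject = x$subject_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  if (ncol(x$covariate_candidates) > 0L) {
    df <- cbind(df, x$covariate_candidates)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' Tab-separated with a header; required columns `subject_id`, `group`,
#' `age` (years) and, unless supplied through an eTIV column at cohort
#' assembly, `icv` (mm^3). Optional: `pair_id`, `session`.
#'
#' @param path Path to the covariate table.
#' @return A data.frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("covariate table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Assemble a validated cohort
#'
#' Joins one or more ROI tables (e.g. left- and right-hemisphere
#' aparcstats2table outputs) with a covariate table and an atlas, reorders
#' ROI columns to atlas order and subjects to covariate-table order, and
#' enforces the cohort invariants (matching subject sets, full atlas
#' coverage, finite values).
#'
#' If the covariate table has no `icv` column, an `eTIV`-like covariate
#' candidate column from one of the ROI tables is used instead; it is an
#' error if neither exists.
#'
#' @param tables An `roi_table` or list of `roi_table`s sharing a subject set.
#' @param covariates Data.frame as returned by [read_covariates()].
#' @param atlas An `atlas_spec` from [load_atlas()].
#' @return An object of class `cohort`: `subjects` (data.frame with
#'   `subject_id`, `group`, `age`, `icv` and optional `pair_id`), `values`
#'   (subjects x ROI matrix in atlas order), `measure_kind`, `atlas`.
#' @export
assemble_cohort <- function(tables, covariates, atlas) {
  stopifnot(inherits(atlas, "atlas_spec"))
  if (inherits(tables, "roi_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "roi_table")))
  kinds <- unique(vapply(tables, `[[`, character(1), "measure_kind"))
  if (length(kinds) != 1L) {
    stop("all ROI tables must share one measure_kind; got: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  ids <- covariates$subject_id
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids in covariate table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (tb in tables) {
    extra <- setdiff(tb$subject_ids, ids)
    missing <- setdiff(ids, tb$subject_ids)
    if (length(extra) || length(missing)) {
      stop("subject sets differ between a stats table and the covariate ",
           "table; missing from covariates: ",
           paste(extra, collapse = ", "), "; missing from table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  values <- do.call(cbind, lapply(tables, function(tb) {
    tb$values[match(ids, tb$subject_ids), , drop = FALSE]
  }))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate ROI columns across input tables: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(atlas$roi_names, colnames(values))
  if (length(uncovered) > 0L) {
    stop("atlas ROI(s) absent from all input tables: ",
         paste(utils::head(uncovered, 10L), collapse = ", "),
         if (length(uncovered) > 10L) ", ...", call. = FALSE)
  }
  values <- values[, atlas$roi_names, drop = FALSE]
  rownames(values) <- ids

  icv <- covariates[["icv"]]
  if (is.null(icv)) {
    for (tb in tables) {
      cand <- tb$covariate_candidates
      hit <- grep("eTIV|EstimatedTotalIntraCranialVol", colnames(cand))
      if (length(hit) > 0L) {
        icv <- cand[match(ids, tb$subject_ids), hit[1L]]
        break
      }
    }
    if (is.null(icv)) {
      stop("no 'icv' column in covariates and no eTIV column in any stats ",
           "table", call. = FALSE)
    }
  }
  subjects <- data.frame(subject_id = ids,
                         group = as.character(covariates$group),
                         age = as.numeric(covariates$age),
                         icv = as.numeric(icv),
                         stringsAsFactors = FALSE)
  if ("pair_id" %in% colnames(covariates)) {
    subjects$pair_id <- as.character(covariates$pair_id)
  }
  if (anyNA(subjects$age) || anyNA(subjects$icv)) {
    stop("non-finite age or icv in covariate table", call. = FALSE)
  }
  small <- table(subjects$group)
  small <- names(small)[small < 4L]
  if (length(small) > 0L) {
    warning("group(s) with fewer than 4 subjects cannot enter a covariance ",
            "analysis: ", paste(small, collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, values = values,
                 measure_kind = kinds, atlas = atlas),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(x$subjects$group)
  cat("<cohort> ", nrow(x$values), " subjects x ", ncol(x$values),
      " ROIs (", x$measure_kind, ", atlas ", x$atlas$name, ")\n  groups: ",
      paste(sprintf("%s=%d", names(grp), as.integer(grp)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Internal: subset a cohort's rows by group label.
.group_rows <- function(cohort, group) {
  idx <- which(cohort$subjects$group == group)
  if (length(idx) == 0L) {
    stop("no subjects with group label '", group, "'", call. = FALSE)
  }
  idx
}
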
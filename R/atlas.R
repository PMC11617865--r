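#' Packaged parcellation node lists
#'
#' Four region-of-interest (ROI) sets are shipped with the package, matching
#' the parcellations commonly exported from FreeSurfer stats tables:
#'
#' * `desikan_killiany` — 68 cortical parcels (34 per hemisphere).
#' * `destrieux` — 148 cortical parcels (74 per hemisphere).
#' * `subcortical17` — bilateral thalamus, caudate, putamen, pallidum,
#'   hippocampus and amygdala (left/right interleaved per structure) plus the
#'   five cingulate subdivisions taken as bilateral structures, 17 nodes in
#'   all. The 12-bilateral-plus-5-cingulate arithmetic is the only reading
#'   that yields a 17-node network from these structures; the cingulate
#'   subdivisions are therefore merged across hemispheres.
#' * `hipp_amyg_subfields` — 28 hippocampal-subfield and amygdala-nucleus
#'   labels per hemisphere, 56 nodes.
#'
#' @return Character vector of the packaged atlas identifiers.
#' @export
atlases <- function() {
  c("desikan_killiany", "destrieux", "subcortical17", "hipp_amyg_subfields")
}

.atlas_n_nodes <- c(
  desikan_killiany = 68L, destrieux = 148L,
  subcortical17 = 17L, hipp_amyg_subfields = 56L
)

.atlas_hemisphere <- function(labels) {
  hemi <- rep("bilateral", length(labels))
  hemi[startsWith(labels, "lh_") | startsWith(labels, "Left-")]  <- "lh"
  hemi[startsWith(labels, "rh_") | startsWith(labels, "Right-")] <- "rh"
  hemi
}

#' Load an atlas node list
#'
#' @param name One of the identifiers in [atlases()], or a path to a custom
#'   plain-text node list (one ROI label per line; lines starting with `#`
#'   ignored).
#' @return An object of class `atlas_spec` with fields `name`, `roi_names`
#'   (ordered ROI labels), `hemisphere` (per-ROI `"lh"`, `"rh"` or
#'   `"bilateral"`) and `n_nodes`.
#' @examples
#' load_atlas("subcortical17")
#' @export
load_atlas <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% atlases()) {
    path <- system.file("extdata", "atlases", paste0(name, ".txt"),
                        package = "covnet", mustWork = TRUE)
    atlas_name <- name
  } else if (file.exists(name)) {
    path <- name
    atlas_name <- tools::file_path_sans_ext(basename(name))
  } else {
    stop("atlas not found: '", name, "' is neither a packaged identifier (",
         paste(atlases(), collapse = ", "), ") nor an existing file",
         call. = FALSE)
  }
  labels <- readLines(path)
  labels <- trimws(labels)
  labels <- labels[nzchar(labels) & !startsWith(labels, "#")]
  if (anyDuplicated(labels)) {
    stop("invalid atlas '", atlas_name, "': duplicate ROI labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) < 2L) {
    stop("invalid atlas '", atlas_name, "': fewer than 2 ROI labels",
         call. = FALSE)
  }
  spec <- structure(
    list(name = atlas_name, roi_names = labels,
         hemisphere = .atlas_hemisphere(labels),
         n_nodes = length(labels)),
    class = "atlas_spec")
  if (atlas_name %in% atlases() &&
      spec$n_nodes != .atlas_n_nodes[[atlas_name]]) {
    stop("packaged atlas '", atlas_name, "' has ", spec$n_nodes,
         " labels, expected ", .atlas_n_nodes[[atlas_name]], call. = FALSE)
  }
  spec
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat("<atlas_spec> ", x$name, ": ", x$n_nodes, " nodes (",
      sum(x$hemisphere == "lh"), " lh / ", sum(x$hemisphere == "rh"),
      " rh / ", sum(x$hemisphere == "bilateral"), " bilateral)\n", sep = "")
  invisible(x)
}
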
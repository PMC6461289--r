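.TRIALS_SCHEMA <- "voxphantom-trials-1"

#' Published post-mortem volumes of DBS target nuclei
#'
#' Literature table of hemispheric volume estimates for the subthalamic
#' nucleus (STN) and internal globus pallidus (GPi), the deep-brain-
#' stimulation targets whose size motivates the study phantom
#' (STN average 129.7 mm^3, GPi average 376.8 mm^3).
#'
#' @return A data.frame with columns `structure`, `author`, `method`,
#'   `volume_mm3`.
#' @export
load_literature_volumes <- function() {
  path <- system.file("extdata", "literature_volumes.csv",
                      package = "voxphantom")
  if (path == "") stop("packaged literature table not found")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "author", "method", "volume_mm3")
  if (!all(need %in% names(out)) || !nrow(out) ||
      any(!out$structure %in% c("STN", "GPi")) || any(out$volume_mm3 <= 0))
    stop("packaged literature table is corrupted")
  out
}

#' Mean and SD of the literature volumes per structure
#'
#' @param table output of [load_literature_volumes()] (loaded if missing).
#' @return A data.frame with columns `structure`, `n`, `mean_mm3`, `sd_mm3`.
#' @export
literature_volume_summary <- function(table = load_literature_volumes()) {
  parts <- split(table$volume_mm3, table$structure)
  out <- data.frame(structure = names(parts),
                    n = vapply(parts, length, 0L),
                    mean_mm3 = vapply(parts, mean, 0),
                    sd_mm3 = vapply(parts, stats::sd, 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read trial records as CSV
#'
#' Lossless round-trip of [run_design()] records. The first line carries a
#' schema tag (`# voxphantom-trials-1`); reading a file with a different
#' tag is an explicit error.
#'
#' @param records trial-record data.frame (may have zero rows).
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the records.
#' @export
write_trials <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", .TRIALS_SCHEMA), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 1)
  if (!identical(header, paste0("# ", .TRIALS_SCHEMA)))
    stop(sprintf("schema mismatch in '%s': expected '# %s', found '%s'",
                 path, .TRIALS_SCHEMA, header))
  out <- tryCatch(
    utils::read.csv(path, skip = 1, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed trial file '%s': %s", path,
                                     conditionMessage(e))))
  out
}

#' Export a volume or mask as NIfTI-1
#'
#' Writes the array with the grid's (possibly anisotropic) voxel dimensions
#' in the NIfTI header. Masks are written as unsigned 8-bit, images as
#' 32-bit float.
#'
#' @param x an `image_volume` or `label_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "label_mask")) {
    arr <- array(as.integer(x$data), dim = x$grid$matrix_dims)
    dtype <- "uint8"
  } else if (inherits(x, "image_volume")) {
    arr <- x$data
    dtype <- "float"
  } else stop("x must be an image_volume or label_mask")
  attr(arr, "pixdim") <- x$grid$voxel_dims
  nii <- RNifti::asNifti(arr, datatype = dtype, internal = FALSE)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a NIfTI file back as an image volume or mask
#'
#' The grid is rebuilt from the header's voxel dimensions and matrix size;
#' binary-valued files are returned as [label_mask()]s.
#'
#' @param path NIfTI file path.
#' @param fov optional FoV override (defaults to `dim * pixdim`).
#' @return An `image_volume` or `label_mask`.
#' @export
read_nifti <- function(path, fov = NULL) {
  nii <- RNifti::readNifti(path)
  dims <- dim(nii)
  if (length(dims) != 3) stop("expected a 3D NIfTI volume")
  vox <- RNifti::pixdim(nii)[1:3]
  if (is.null(fov)) fov <- dims * vox
  thickness <- vox[3] / vox[1]
  if (abs(vox[1] - vox[2]) > 1e-6)
    stop("non-square in-plane voxels are not part of the design")
  grid <- grid_spec(vox[1], thickness, fov)
  arr <- array(as.numeric(as.array(nii)), dims)
  vals <- unique(as.vector(arr))
  if (all(vals %in% c(0, 1))) label_mask(arr == 1, grid)
  else image_volume(arr, grid, rescaled = FALSE, raw_range = range(arr))
}

#' Build an experiment design from a YAML/JSON config block
#'
#' Reads a config file with any of the fields `n_variants`, `orientations`,
#' `in_plane`, `thickness_factors`, `fov`, `master_seed`,
#' `reference_in_plane`, `bounds` (with `translation` / `rotation` ranges)
#' and `ellipsoid` (with `semi_axes`, `center`, `rotation`, `intensity`).
#' Missing fields fall back to the study defaults.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return An [experiment_design()].
#' @export
design_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_variants", "orientations", "in_plane", "thickness_factors",
              "fov", "master_seed", "reference_in_plane"))
    if (!is.null(cfg[[f]])) args[[f]] <- unlist(cfg[[f]])
  if (!is.null(cfg$bounds))
    args$bounds <- rigid_bounds(
      translation = unlist(cfg$bounds$translation),
      rotation = unlist(cfg$bounds$rotation))
  if (!is.null(cfg$ellipsoid))
    args$objects <- do.call(ellipsoid, lapply(cfg$ellipsoid, unlist))
  do.call(experiment_design, args)
}
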
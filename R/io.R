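# NIfTI is the single volumetric format: maps float32, masks/labels uint8.

#' Write a map set (and optional labels) to NIfTI
#'
#' One float32 volume per map plus a uint8 brain mask, with the voxel size
#' carried in the NIfTI header. `NA` voxels are stored as 0 outside the
#' mask (the mask volume is the authority on exclusion).
#'
#' @param maps A [physio_maps()] object.
#' @param dir Output directory (created if needed).
#' @param labels Optional [region_labels()] written as `labels.nii.gz`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_map_set <- function(maps, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  vs <- maps$voxel_size_mm
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vs
    img
  }
  for (nm in names(maps$maps)) {
    arr <- maps$maps[[nm]]
    arr[is.na(arr)] <- 0
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(as_img(arr), p, datatype = "float")
    paths[nm] <- p
  }
  paths["mask"] <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(as_img(array(as.integer(maps$mask), dim(maps$mask))),
                     paths[["mask"]], datatype = "uint8")
  if (!is.null(labels)) {
    paths["labels"] <- file.path(dir, "labels.nii.gz")
    RNifti::writeNifti(as_img(array(as.integer(labels$labels),
                                    dim(labels$labels))),
                       paths[["labels"]], datatype = "uint8")
  }
  invisible(paths)
}

#' Load a validated map set from NIfTI volumes
#'
#' Reads named map volumes plus a brain mask, checks that every volume
#' shares the grid (shape identical; voxel sizes within 1e-4 mm) naming the
#' offending files otherwise, masks the maps, and flags any non-finite
#' voxels inside the mask.
#'
#' @param map_paths Named character vector of NIfTI paths (names become map
#'   names).
#' @param mask_path Path to the uint8 brain mask volume.
#' @return A [physio_maps()] object; attribute `n_nonfinite` counts
#'   non-finite in-mask voxels per map (also warned about).
#' @export
load_map_set <- function(map_paths, mask_path) {
  if (is.null(names(map_paths)) || any(names(map_paths) == "")) {
    abort("`map_paths` must be a named vector of NIfTI paths.")
  }
  mask_img <- RNifti::readNifti(mask_path)
  mask_dim <- dim(mask_img)
  mask_vs <- RNifti::pixdim(mask_img)[1:3]
  mask <- array(as.array(mask_img) > 0, mask_dim)
  if (!any(mask)) abort("Brain mask contains 0 voxels.")
  maps <- list()
  nonfinite <- c()
  for (nm in names(map_paths)) {
    img <- RNifti::readNifti(map_paths[[nm]])
    if (!identical(dim(img), mask_dim)) {
      abort(sprintf("Grid mismatch: '%s' is %s but mask '%s' is %s.",
                    map_paths[[nm]], paste(dim(img), collapse = "x"),
                    mask_path, paste(mask_dim, collapse = "x")))
    }
    vs <- RNifti::pixdim(img)[1:3]
    if (any(abs(vs - mask_vs) > 1e-4)) {
      abort(sprintf("Voxel-size mismatch: '%s' (%s mm) vs mask (%s mm).",
                    map_paths[[nm]], paste(signif(vs, 6), collapse = "x"),
                    paste(signif(mask_vs, 6), collapse = "x")))
    }
    arr <- array(as.numeric(as.array(img)), mask_dim)
    nf <- sum(!is.finite(arr[mask]))
    nonfinite[nm] <- nf
    if (nf > 0) {
      warn(sprintf("Map '%s' has %d non-finite voxels inside the mask.", nm, nf))
    }
    maps[[nm]] <- arr
  }
  out <- physio_maps(maps, mask_vs, mask)
  attr(out, "n_nonfinite") <- nonfinite
  out
}

#' Read/write time-value tables
#'
#' Input functions and TACs travel as CSV with columns `time_min`, `value`;
#' frame schedules as CSV with `frame_start_min`, `frame_end_min`.
#'
#' @param path CSV path.
#' @return `read_aif_csv()` an input-function tibble; `read_schedule_csv()`
#'   a frame-schedule tibble.
#' @export
read_aif_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_input_function(df)
}

#' @rdname read_aif_csv
#' @param x Object to write.
#' @export
write_aif_csv <- function(x, path) {
  readr::write_csv(x[, c("time_min", "value")], path)
  invisible(path)
}

#' @rdname read_aif_csv
#' @export
read_schedule_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_frame_schedule(df)
}
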
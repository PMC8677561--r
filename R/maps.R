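#' Co-registered parametric map set
#'
#' A set of 3D parametric maps sharing one voxel grid and brain mask:
#' typically CBF, CBV, OEF, CMRO2 and the FDG maps (K1, k2, k3, Ki, LC,
#' CMRG, MR). Maps are numeric arrays with `NA` outside the mask, so masked
#' voxels can never leak into summaries. OEF is stored as a fraction;
#' tabular summaries report it in percent.
#'
#' @param maps Named list of numeric 3D arrays with identical dimensions.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param mask Logical 3D array; `TRUE` inside the brain.
#' @return An object of class `physio_maps`.
#' @export
physio_maps <- function(maps, voxel_size_mm, mask) {
  if (!is.list(maps) || is.null(names(maps)) || any(names(maps) == "")) {
    abort("`maps` must be a named list of arrays.")
  }
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 3 positive values.")
  }
  if (!is.logical(mask) || length(dim(mask)) != 3) {
    abort("`mask` must be a logical 3D array.")
  }
  if (!any(mask)) abort("Brain mask is empty.")
  for (nm in names(maps)) {
    check_same_dim(maps[[nm]], mask, sprintf("map '%s' and mask", nm))
    maps[[nm]][!mask] <- NA_real_
    if ("OEF" == nm) {
      inb <- maps[[nm]][mask]
      if (any(is.finite(inb) & (inb < 0 | inb > 1))) {
        abort("OEF must lie in [0, 1] inside the mask (stored as fraction).")
      }
    }
  }
  structure(list(maps = maps, voxel_size_mm = as.numeric(voxel_size_mm),
                 mask = mask),
            class = "physio_maps")
}

#' @export
print.physio_maps <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<physio_maps> %dx%dx%d voxels @ %s mm; %d in-mask; maps: %s\n",
              d[1], d[2], d[3], paste(x$voxel_size_mm, collapse = "x"),
              sum(x$mask), paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Structural region label volume
#'
#' Integer labels on the shared grid: 0 excluded, 1 lesion core, 2 penumbra,
#' 3 peri-penumbra, 4 normal-appearing. Labels partition the brain mask.
#'
#' @param labels Integer 3D array of labels 0-4.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return An object of class `region_labels`.
#' @export
region_labels <- function(labels, voxel_size_mm) {
  if (length(dim(labels)) != 3) abort("`labels` must be a 3D array.")
  if (!all(labels %in% 0:4)) abort("Labels must be integers 0-4.")
  structure(list(labels = labels, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "region_labels")
}

REGION_LEVELS <- c("core", "penumbra", "peri_penumbra", "normal_appearing")

region_name <- function(code) {
  c("excluded", REGION_LEVELS)[code + 1L]
}

#' @export
print.region_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:4,
                      labels = c("excluded", REGION_LEVELS)))
  cat("<region_labels>\n")
  print(tab)
  invisible(x)
}

# Volume in ml of a voxel count on this grid.
voxels_to_ml <- function(n, voxel_size_mm) {
  n * prod(voxel_size_mm) / 1000
}
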
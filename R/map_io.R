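# Voxel masks, mask intersection, downsampling and volume <-> matrix
# flattening. All analyses downstream operate on subject x voxel matrices;
# this module fixes the voxel-order convention that makes those columns a
# stable voxel identity.

#' Construct a voxel mask
#'
#' A voxel mask is a 3-D logical grid plus its geometry (voxel size, 4x4
#' grid-to-world affine) and a fixed flattening convention: in-mask voxels
#' are numbered in R column-major order (first grid axis fastest), using
#' 0-based grid coordinates in the voxel table. World coordinates are only
#' obtained through the affine.
#'
#' @param grid 3-D logical (or 0/1 numeric) array; at least one voxel must
#'   be `TRUE`.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param affine Optional 4x4 grid-to-world matrix; defaults to
#'   `diag(c(voxel_size, 1))`.
#' @return An object of class `voxel_mask` with fields `grid`, `voxel_size`,
#'   `affine`, `flatten_order`.
#' @export
voxel_mask <- function(grid, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop_mmfuse("mask grid must be a 3-D array", "mmfuse_argument_error")
  grid <- array(as.logical(grid), dim = dim(grid))
  if (anyNA(grid)) stop_mmfuse("mask grid contains NA", "mmfuse_argument_error")
  if (!any(grid)) stop_mmfuse("mask is empty (no TRUE voxel)", "mmfuse_empty_mask_error")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(grid = grid, voxel_size = as.double(voxel_size),
                 affine = affine, flatten_order = "column-major"),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %s grid, %d in-mask voxels, voxel size %s mm\n",
              paste(dim(x$grid), collapse = "x"), sum(x$grid),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' Number of in-mask voxels
#' @param mask A `voxel_mask`.
#' @return Integer count of `TRUE` voxels.
#' @export
mask_size <- function(mask) sum(mask$grid)

#' Voxel lookup table of a mask
#'
#' @param mask A `voxel_mask`.
#' @return Integer matrix (n_voxels x 3) of 0-based (i, j, k) grid
#'   coordinates; row `v` is the grid location of flat column `v`.
#' @export
voxel_table <- function(mask) {
  idx <- which(mask$grid)
  arrayInd(idx, dim(mask$grid)) - 1L
}

same_geometry <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-8))
}

#' Intersect masks across modalities
#'
#' Returns the logical AND of all masks: only voxels that contain data in
#' every modality survive. All masks must share grid dimensions and affine.
#'
#' @param masks List of `voxel_mask` objects.
#' @return A `voxel_mask`; errors if the intersection is empty.
#' @export
intersect_masks <- function(masks) {
  stopifnot(length(masks) >= 1)
  ref <- masks[[1]]
  grid <- ref$grid
  for (m in masks[-1]) {
    if (!same_geometry(ref, m))
      stop_mmfuse("masks have incompatible grids or affines", "mmfuse_geometry_error")
    grid <- grid & m$grid
  }
  if (!any(grid))
    stop_mmfuse("mask intersection is empty", "mmfuse_empty_mask_error")
  voxel_mask(grid, ref$voxel_size, ref$affine)
}

#' Downsample a volume and its mask by an integer factor
#'
#' Each coarse voxel is the mean of its in-mask children in the
#' `factor^3` fine-grid block; a coarse mask voxel is kept when at least
#' half of its children are in-mask (ties included). Trailing fine voxels
#' that do not fill a complete block are truncated. The voxel size is
#' multiplied by `factor`.
#'
#' @param volume 3-D numeric array on the mask grid.
#' @param mask A `voxel_mask`.
#' @param factor Integer >= 1.
#' @return List with `volume` (coarse 3-D array, NA outside the coarse
#'   mask) and `mask` (coarse `voxel_mask`).
#' @export
downsample_volume <- function(volume, mask, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop_mmfuse("factor must be a single integer >= 1", "mmfuse_argument_error")
  factor <- as.integer(factor)
  if (!identical(dim(volume), dim(mask$grid)))
    stop_mmfuse("volume does not conform to mask grid", "mmfuse_geometry_error")
  if (factor == 1L) return(list(volume = volume, mask = mask))

  fine <- dim(mask$grid)
  coarse <- fine %/% factor
  if (any(coarse < 1))
    stop_mmfuse("factor larger than grid extent", "mmfuse_argument_error")
  out <- array(NA_real_, dim = coarse)
  grid <- array(FALSE, dim = coarse)
  half <- factor^3 / 2
  for (k in seq_len(coarse[3])) {
    for (j in seq_len(coarse[2])) {
      for (i in seq_len(coarse[1])) {
        ii <- ((i - 1) * factor + 1):(i * factor)
        jj <- ((j - 1) * factor + 1):(j * factor)
        kk <- ((k - 1) * factor + 1):(k * factor)
        inm <- mask$grid[ii, jj, kk]
        n_in <- sum(inm)
        if (n_in > 0) out[i, j, k] <- mean(volume[ii, jj, kk][inm])
        grid[i, j, k] <- n_in >= half
      }
    }
  }
  if (!any(grid))
    stop_mmfuse("downsampled mask is empty", "mmfuse_empty_mask_error")
  scale4 <- diag(c(rep(factor, 3), 1))
  list(volume = out,
       mask = voxel_mask(grid, mask$voxel_size * factor, mask$affine %*% scale4))
}

#' Flatten a volume to the mask's voxel vector
#'
#' @param volume 3-D array conforming to the mask grid.
#' @param mask A `voxel_mask`.
#' @return Numeric vector of length `mask_size(mask)` in flatten order.
#' @export
flatten_volume <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask$grid)))
    stop_mmfuse("volume does not conform to mask grid", "mmfuse_geometry_error")
  as.double(volume[mask$grid])
}

#' Expand a flat voxel vector back into a volume
#'
#' Inverse of [flatten_volume()] on the mask support.
#'
#' @param values Numeric vector of length `mask_size(mask)`.
#' @param mask A `voxel_mask`.
#' @param fill Value used outside the mask (default `NA`).
#' @return 3-D numeric array.
#' @export
unflatten_volume <- function(values, mask, fill = NA_real_) {
  if (length(values) != mask_size(mask))
    stop_mmfuse("value length does not match mask size", "mmfuse_incompatible_data_error")
  out <- array(fill, dim = dim(mask$grid))
  out[mask$grid] <- values
  out
}

#' Read per-subject volumes into a flat dataset
#'
#' Reads one NIfTI volume per subject, checks geometry against the mask,
#' and flattens each onto the mask support. Row order follows `paths`.
#'
#' @param paths Character vector of NIfTI file paths, one per subject.
#' @param mask A `voxel_mask`.
#' @return A `flat_dataset`: list with `matrix` (subjects x voxels),
#'   `voxel_table` and `mask`.
#' @export
read_subject_maps <- function(paths, mask) {
  v <- mask_size(mask)
  mat <- matrix(NA_real_, nrow = length(paths), ncol = v)
  for (s in seq_along(paths)) {
    img <- read_nifti(paths[s])
    if (length(dim(img$data)) != 3L || !identical(dim(img$data), dim(mask$grid)))
      stop_mmfuse(paste0("volume geometry mismatch: ", paths[s]), "mmfuse_geometry_error")
    mat[s, ] <- flatten_volume(img$data, mask)
  }
  if (anyNA(mat))
    stop_mmfuse("missing values inside the mask", "mmfuse_incompatible_data_error")
  structure(list(matrix = mat, voxel_table = voxel_table(mask), mask = mask),
            class = "flat_dataset")
}

#' Write a flat voxel vector as a NIfTI volume
#'
#' @param values Flat voxel vector on the mask support.
#' @param mask A `voxel_mask`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param fill Out-of-mask fill value (default 0, NIfTI has no NA).
#' @return `path`, invisibly.
#' @export
write_map_volume <- function(values, mask, path, fill = 0) {
  vol <- unflatten_volume(values, mask, fill = fill)
  write_nifti(vol, path, affine = mask$affine, voxel_size = mask$voxel_size,
              datatype = "float64")
}

#' Write a mask as a binary NIfTI volume
#' @param mask A `voxel_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(mask, path) {
  write_nifti(array(as.integer(mask$grid), dim = dim(mask$grid)), path,
              affine = mask$affine, voxel_size = mask$voxel_size,
              datatype = "uint8")
}

#' Read a mask from a binary NIfTI volume
#' @param path NIfTI file with nonzero values inside the mask.
#' @return A `voxel_mask`.
#' @export
read_mask_volume <- function(path) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 3L)
    stop_mmfuse("mask volume must be 3-D", "mmfuse_geometry_error")
  voxel_mask(img$data != 0, img$voxel_size, img$affine)
}

#' Read a pre-flattened subject x voxel matrix from CSV/TSV
#'
#' Expects a header row of voxel identifiers and one row per subject; the
#' delimiter is inferred from the extension (`.tsv` = tab, otherwise comma).
#'
#' @param path CSV or TSV file.
#' @return Numeric matrix (subjects x voxels) with voxel ids as colnames.
#' @export
read_flat_matrix <- function(path) {
  if (!file.exists(path)) stop_mmfuse(paste0("file not found: ", path), "mmfuse_io_error")
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop_mmfuse("flat matrix contains missing values",
                              "mmfuse_incompatible_data_error")
  mat
}

#' Write a subject x voxel matrix to CSV/TSV
#' @param mat Numeric matrix; colnames used as the voxel-id header (defaults
#'   to `v1..vV`).
#' @param path Output path (`.tsv` writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_flat_matrix <- function(mat, path) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(mat, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
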
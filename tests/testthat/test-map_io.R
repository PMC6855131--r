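# Masks, intersection, downsampling, flattening and NIfTI round trips.

test_that("intersect_masks follows set arithmetic and validates geometry", {
  # idempotence
  m <- toy_mask(1:40)
  self <- intersect_masks(list(m, m))
  expect_identical(self$grid, m$grid)

  # 100 and 80 true voxels sharing 60 -> 60
  a <- toy_mask(1:100)
  b <- toy_mask(c(41:100, 106:125))
  expect_equal(mask_size(intersect_masks(list(a, b))), 60)

  # disjoint masks -> empty -> error
  expect_error(intersect_masks(list(toy_mask(1:10), toy_mask(11:20))),
               class = "mmfuse_empty_mask_error")
  # grid mismatch
  expect_error(intersect_masks(list(toy_mask(1:10), toy_mask(1:10, dims = c(4, 5, 5)))),
               class = "mmfuse_geometry_error")
})

test_that("downsample_volume matches a naive triple-loop oracle", {
  set.seed(31)
  vol <- array(rnorm(512), c(8, 8, 8))
  grid <- array(runif(512) < 0.7, c(8, 8, 8))
  grid[1, 1, 1] <- TRUE
  mask <- voxel_mask(grid, voxel_size = 2)
  for (f in c(2L, 4L)) {
    got <- downsample_volume(vol, mask, f)
    cd <- dim(vol) %/% f
    exp_vol <- array(NA_real_, cd)
    exp_grid <- array(FALSE, cd)
    for (i in 1:cd[1]) for (j in 1:cd[2]) for (k in 1:cd[3]) {
      ii <- ((i - 1) * f + 1):(i * f); jj <- ((j - 1) * f + 1):(j * f)
      kk <- ((k - 1) * f + 1):(k * f)
      inm <- grid[ii, jj, kk]
      if (any(inm)) exp_vol[i, j, k] <- mean(vol[ii, jj, kk][inm])
      exp_grid[i, j, k] <- sum(inm) >= f^3 / 2
    }
    expect_equal(got$volume, exp_vol)
    expect_identical(got$mask$grid, exp_grid)
    expect_equal(got$mask$voxel_size, rep(2 * f, 3))
  }
})

test_that("downsample_volume identities and edge handling", {
  vol <- array(3.5, c(4, 4, 4))
  mask <- voxel_mask(array(TRUE, c(4, 4, 4)))
  # factor 1 is the identity
  id <- downsample_volume(vol, mask, 1)
  expect_identical(id$volume, vol)
  # constant volume stays constant under any factor
  expect_true(all(downsample_volume(vol, mask, 2)$volume == 3.5))
  # 4x4x4 with known block means
  vol2 <- array(seq_len(64), c(4, 4, 4))
  got <- downsample_volume(vol2, mask, 2)
  expect_equal(got$volume[1, 1, 1], mean(vol2[1:2, 1:2, 1:2]))
  expect_equal(got$volume[2, 2, 2], mean(vol2[3:4, 3:4, 3:4]))
  # edge truncation: 5^3 grid at factor 2 -> 2^3 coarse grid
  mask5 <- voxel_mask(array(TRUE, c(5, 5, 5)))
  expect_equal(dim(downsample_volume(array(0, c(5, 5, 5)), mask5, 2)$volume),
               c(2, 2, 2))
  expect_error(downsample_volume(vol, mask, 0), class = "mmfuse_argument_error")
})

test_that("flatten/unflatten are mutual inverses on the mask support", {
  set.seed(5)
  for (rep in 1:5) {
    grid <- array(runif(60) < 0.5, c(3, 4, 5))
    grid[2, 2, 2] <- TRUE
    mask <- voxel_mask(grid)
    vals <- rnorm(mask_size(mask))
    vol <- unflatten_volume(vals, mask)
    expect_equal(flatten_volume(vol, mask), vals)
    # single in-mask coordinate lands in the right column
    v1 <- array(0, dim(grid))
    coord <- voxel_table(mask)[3, ] + 1L
    v1[coord[1], coord[2], coord[3]] <- 9.25
    flat <- flatten_volume(v1, mask)
    expect_equal(flat[3], 9.25)
    expect_true(all(flat[-3] == 0))
  }
})

test_that("NIfTI volumes round-trip through write/read", {
  set.seed(17)
  vol <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -20, 5)
  p32 <- tempfile(fileext = ".nii")
  write_nifti(vol, p32, affine = aff, voxel_size = c(2, 2, 2))
  got <- read_nifti(p32)
  expect_equal(got$data, vol, tolerance = 1e-6)   # float32 storage
  expect_equal(got$affine, aff)
  expect_equal(got$voxel_size, c(2, 2, 2))

  pgz <- tempfile(fileext = ".nii.gz")
  write_nifti(vol, pgz, datatype = "float64")
  expect_equal(read_nifti(pgz)$data, vol)          # float64 is exact

  expect_error(read_nifti(tempfile(fileext = ".nii")), class = "mmfuse_io_error")
})

test_that("NIfTI output agrees with an independent reader (nibabel)", {
  vol <- array(seq(0, 1, length.out = 24), c(2, 3, 4))
  p <- tempfile(fileext = ".nii")
  write_nifti(vol, p, voxel_size = c(4, 4, 4), datatype = "float64")
  out <- tempfile(fileext = ".txt")
  script <- sprintf(
    "import nibabel, numpy as np\nimg = nibabel.load('%s')\nnp.savetxt('%s', np.asarray(img.dataobj).reshape(-1, order='F'))\nprint(img.shape)", p, out)
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  expect_equal(scan(out, quiet = TRUE), as.numeric(vol), tolerance = 1e-12)

  # and the reverse direction: a nibabel-written file read back in R
  p2 <- tempfile(fileext = ".nii")
  script2 <- sprintf(
    "import nibabel, numpy as np\nd = np.arange(24, dtype=np.float64).reshape(2,3,4, order='F')\nnibabel.save(nibabel.Nifti1Image(d, np.diag([4.,4.,4.,1.])), '%s')", p2)
  system2("python", c("-c", shQuote(script2)))
  got <- read_nifti(p2)
  expect_equal(as.numeric(got$data), as.numeric(0:23))
  expect_equal(dim(got$data), c(2L, 3L, 4L))
})

test_that("read_subject_maps preserves list order and validates geometry", {
  grid <- array(TRUE, c(3, 3, 2))
  mask <- voxel_mask(grid)
  paths <- character(3)
  vals <- list()
  for (s in 1:3) {
    vals[[s]] <- array(rnorm(18, mean = s * 10), c(3, 3, 2))
    paths[s] <- tempfile(fileext = ".nii")
    write_nifti(vals[[s]], paths[s], datatype = "float64")
  }
  ds <- read_subject_maps(paths, mask)
  expect_equal(nrow(ds$matrix), 3)
  for (s in 1:3) expect_equal(ds$matrix[s, ], flatten_volume(vals[[s]], mask))
  bad <- tempfile(fileext = ".nii")
  write_nifti(array(0, c(4, 3, 2)), bad)
  expect_error(read_subject_maps(c(paths, bad), mask), class = "mmfuse_geometry_error")
})

test_that("flat CSV/TSV matrices round-trip", {
  m <- matrix(rnorm(12), 3, dimnames = list(NULL, paste0("vox", 1:4)))
  for (ext in c(".csv", ".tsv")) {
    p <- tempfile(fileext = ext)
    write_flat_matrix(m, p)
    got <- read_flat_matrix(p)
    expect_equal(unname(got), unname(m), tolerance = 1e-12)
    expect_equal(colnames(got), colnames(m))
  }
})
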
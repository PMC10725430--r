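# Stack processing: z-resampling, CED filtering, segmentation, domain area
# and leaflet volume fraction.

test_that("z-resampling preserves constants and lines and tracks a sinusoid", {
  nz <- 11; ny <- 6; nx <- 5
  const <- image_stack(array(3.5, dim = c(nz, ny, nx)),
                       lateral_res = 0.2, z_step = 1)
  rc <- resample_z(const)
  expect_equal(rc$z_step, 0.2)
  expect_true(all(abs(rc$voxels - 3.5) < 1e-12))

  lin <- array(0, dim = c(nz, ny, nx))
  for (z in 1:nz) lin[z, , ] <- 2 * (z - 1) + 1
  rl <- resample_z(image_stack(lin, 0.2, 1))
  zn <- (seq_len(dim(rl$voxels)[1]) - 1) * 0.2
  expect_equal(rl$voxels[, 2, 2], 2 * zn + 1, tolerance = 1e-9)
  # z-extent preserved
  expect_equal(max(zn), (nz - 1) * 1)

  sine <- array(0, dim = c(nz, ny, nx))
  for (z in 1:nz) sine[z, , ] <- sin(2 * pi * (z - 1) / 8) + 2
  rs <- resample_z(image_stack(sine, 0.2, 1))
  zn <- (seq_len(dim(rs$voxels)[1]) - 1) * 0.2
  expect_lt(max(abs(rs$voxels[, 3, 3] - (sin(2 * pi * zn / 8) + 2))), 0.05)

  one <- image_stack(array(1, dim = c(1, 4, 4)), 0.2, 1)
  expect_error(resample_z(one), "single z-plane")
})

test_that("CED filter is identity at zero iterations and inert on constants", {
  set.seed(2)
  st <- image_stack(array(abs(rnorm(5 * 16 * 16)), dim = c(5, 16, 16)), 0.2, 0.2)
  expect_identical(ced_filter(st, n_iter = 0)$voxels, st$voxels)
  cst <- image_stack(array(2, dim = c(2, 16, 16)), 0.2, 0.2)
  out <- ced_filter(cst, n_iter = 5)
  expect_true(all(abs(out$voxels - 2) < 1e-9))
  expect_error(ced_filter(st, contrast_param = -1), "contrast_param")
})

test_that("CED does not reduce line contrast nor expand the range", {
  set.seed(5)
  img <- matrix(rnorm(64 * 64), 64, 64)
  img[32, ] <- img[32, ] + 6
  st <- image_stack(array(pmax(img, 0), dim = c(1, 64, 64)), 0.2, 0.2)
  f <- ced_filter(st, n_iter = 10)
  contrast <- function(a)
    (mean(a[1, 32, ]) - mean(a[1, -32, ])) / sd(a[1, -32, ])
  expect_gte(contrast(f$voxels), contrast(st$voxels))
  expect_gte(min(f$voxels), min(st$voxels) - 1e-9)
  expect_lte(max(f$voxels), max(st$voxels) + 1e-9)
})

test_that("segmentation removes sub-threshold structures and keeps the sphere", {
  st <- planted_stack(seed = 101)
  m <- segment_astrocyte(st)
  res <- st$lateral_res
  analytic <- 4 / 3 * pi * 3^3 / res^3
  expect_lt(abs(sum(m$mask) - analytic) / analytic, 0.10)
  # 99-voxel blob and 8-pixel square are removed by the stated filters
  expect_equal(sum(m$mask[6:10, 30:35, 30:35]), 0)
  expect_equal(sum(m$mask[12, 200:203, 200:201]), 0)
})

test_that("an isolated 8-pixel square is removed by the 9-pixel rule", {
  vox <- array(abs(rnorm(10 * 64 * 64, 0, 0.01)), dim = c(10, 64, 64))
  vox[5, 30:33, 30:31] <- 100
  m <- segment_astrocyte(image_stack(vox, 0.2, 0.2))
  expect_equal(sum(m$mask), 0)
})

test_that("pure-noise stacks segment to an empty mask", {
  empties <- vapply(1:20, function(s) {
    set.seed(s)
    st <- image_stack(array(abs(rnorm(20 * 64 * 64)), dim = c(20, 64, 64)),
                      0.2, 0.2)
    sum(segment_astrocyte(st)$mask) == 0
  }, logical(1))
  expect_gte(sum(empties), 19)
})

test_that("domain area from the mask projection matches a column scan", {
  mask <- array(FALSE, dim = c(4, 8, 8))
  mask[2, 3, 4] <- TRUE
  expect_equal(domain_area_from_mask(mask, lateral_res = 0.2), 0.04)
  full <- array(TRUE, dim = c(2, 8, 8))
  expect_equal(domain_area_from_mask(full, lateral_res = 0.2), 64 * 0.04)
  set.seed(4)
  rnd <- array(runif(5 * 12 * 12) > 0.7, dim = c(5, 12, 12))
  manual <- 0
  for (y in 1:12) for (x in 1:12) if (any(rnd[, y, x])) manual <- manual + 1
  expect_equal(domain_area_from_mask(rnd, lateral_res = 0.5), manual * 0.25)
  expect_error(domain_area_from_mask(array(FALSE, dim = c(2, 2, 2)), 0.2),
               "empty mask")
})

test_that("domain area is monotone under mask union", {
  set.seed(8)
  a <- array(runif(4 * 10 * 10) > 0.8, dim = c(4, 10, 10))
  b <- array(runif(4 * 10 * 10) > 0.8, dim = c(4, 10, 10))
  expect_gte(domain_area_from_mask(a | b, 0.2), domain_area_from_mask(a, 0.2))
})

test_that("leaflet VF normalization: uniform stack reads 100%, dark reads ~0%", {
  st <- image_stack(array(50, dim = c(1, 201, 201)), 0.5, 0.5)
  v <- leaflet_vf(st, soma_center = c(101, 101), soma_z = 1,
                  soma_boundary_radius = 4)
  expect_equal(v$characteristic_vf, 100, tolerance = 1e-9)

  img <- matrix(0, 201, 201)
  cu <- ((1:201) - 101) * 0.5
  rr <- sqrt(outer(cu^2, cu^2, "+"))
  img[rr <= 4] <- 80
  st2 <- image_stack(array(img, dim = c(1, 201, 201)), 0.5, 0.5)
  v2 <- leaflet_vf(st2, soma_center = c(101, 101), soma_z = 1)
  expect_lt(v2$characteristic_vf, 0.5)
})

test_that("branch-crossing excursions are excised to within 1 VF point", {
  for (fog in c(5, 7, 10)) {
    img <- gen_vf_image(fog_vf = fog, seed = 11)
    v <- leaflet_vf(img, soma_center = attr(img, "ground_truth")$center_px,
                    soma_z = 1)
    expect_lt(abs(v$characteristic_vf - fog), 1)
  }
})

test_that("characteristic VF is invariant to positive rescaling", {
  img <- gen_vf_image(fog_vf = 7, seed = 5)
  v1 <- leaflet_vf(img, soma_center = attr(img, "ground_truth")$center_px,
                   soma_z = 1)
  img2 <- img
  img2$voxels <- img$voxels * 4.2
  v2 <- leaflet_vf(img2, soma_center = attr(img, "ground_truth")$center_px,
                   soma_z = 1)
  expect_equal(v1$characteristic_vf, v2$characteristic_vf, tolerance = 1e-9)
})

test_that("segmented domain area tracks the generating tree size", {
  areas <- truth <- numeric(0)
  for (s in 1:20) {
    g <- gen_astrocyte(n_primary = 5, branching_prob = 0.25,
                       mean_segment_um = 8,
                       max_radius_um = 10 + s,
                       soma_radius_um = 3, fog_vf = 3, noise_sd = 1,
                       lateral_res = 0.4, seed = 100 + s)
    m <- segment_astrocyte(g$stack)
    areas <- c(areas, domain_area_from_mask(m))
    truth <- c(truth, oracle_hull_area(g$ground_truth$tip_xy))
  }
  expect_gt(cor(areas, truth, method = "spearman"), 0.8)
})

test_that("TIFF stack round trip preserves relative intensities", {
  dir <- withr::local_tempdir()
  set.seed(6)
  st <- image_stack(array(runif(4 * 16 * 16), dim = c(4, 16, 16)), 0.2, 1)
  f <- file.path(dir, "stack.tif")
  write_stack(st, f)
  rd <- read_stack(f, lateral_res = 0.2, z_step = 1)
  sc <- max(st$voxels)
  expect_lt(max(abs(rd$voxels * sc - st$voxels)), sc / 100)
})
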
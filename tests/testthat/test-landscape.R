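# Landscape-pattern metrics: golden fixtures, unit conversions,
# arrangement properties, and a brute-force oracle on random rasters.

test_that("uniform and checkerboard rasters delineate as expected", {
  uni <- gm_raster(matrix(1L, 4, 4), cell_size = 10)
  p <- delineate_patches(uni)
  expect_equal(nrow(p$patches), 1)
  expect_equal(lpi(p), 100)
  expect_equal(edge_density(p), 0)
  expect_equal(shdi(uni), 0)

  cb <- gm_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2), cell_size = 10)
  expect_equal(nrow(delineate_patches(cb, connectivity = 4)$patches), 4)
  expect_equal(nrow(delineate_patches(cb, connectivity = 8)$patches), 2)

  # patches partition the landscape
  r <- gm_raster(matrix(sample(1:3, 36, TRUE), 6, 6), cell_size = 5)
  ps <- delineate_patches(r)
  expect_equal(sum(ps$patches$area), ps$landscape_area)
  expect_equal(sum(ps$patches$n_cells), 36)

  all_nd <- gm_raster(matrix(-9999, 2, 2), cell_size = 1)
  expect_error(delineate_patches(all_nd), "nodata")
})

test_that("LPI, PD, ED and SHDI reproduce hand-computed golden values", {
  # 4x4 raster whose largest patch covers 8 cells -> LPI 50
  v <- matrix(2L, 4, 4)
  v[1:2, ] <- 1L # top 8 cells are one patch
  p <- delineate_patches(gm_raster(v, cell_size = 10))
  expect_equal(lpi(p), 50)

  # one patch on a 100-ha landscape -> PD 1; two patches -> 2
  land100 <- gm_raster(matrix(1L, 10, 10), cell_size = 100) # 1e6 m2 = 100 ha
  expect_equal(patch_density(delineate_patches(land100)), 1)
  v2 <- matrix(1L, 10, 10)
  v2[, 6:10] <- 2L
  expect_equal(patch_density(delineate_patches(gm_raster(v2, cell_size = 100))), 2)
  # splitting a patch strictly increases PD
  v3 <- v2
  v3[, 3] <- 2L # cuts class-1 block in two
  expect_gt(
    patch_density(delineate_patches(gm_raster(v3, cell_size = 100))),
    patch_density(delineate_patches(gm_raster(v2, cell_size = 100)))
  )

  # 1-ha half-plane fixture: one straight 100 m boundary -> ED 100 m/ha
  hp <- matrix(1L, 10, 10)
  hp[, 6:10] <- 2L
  expect_equal(edge_density(delineate_patches(gm_raster(hp, cell_size = 10))), 100)
  # refining the cells on the same geometry leaves ED unchanged
  hp2 <- matrix(1L, 20, 20)
  hp2[, 11:20] <- 2L
  expect_equal(edge_density(delineate_patches(gm_raster(hp2, cell_size = 5))), 100)

  # SHDI: two equal classes -> ln 2; k equal classes -> ln k
  expect_equal(shdi(gm_raster(hp, cell_size = 10)), log(2))
  k4 <- gm_raster(matrix(rep(1:4, each = 4), 4, 4), cell_size = 10)
  expect_equal(shdi(k4), log(4))
})

test_that("metrics are invariant to class relabeling; only SHDI ignores arrangement", {
  v <- matrix(sample(1:3, 64, TRUE), 8, 8)
  r1 <- gm_raster(v, cell_size = 10)
  relab <- matrix(c(3L, 1L, 2L)[v], 8, 8) # permute class ids
  r2 <- gm_raster(relab, cell_size = 10)
  expect_equal(landscape_metrics(r1)[, c("lpi", "pd", "ed", "shdi")],
    landscape_metrics(r2)[, c("lpi", "pd", "ed", "shdi")])

  # rearranged fixture: same composition, different arrangement
  a <- matrix(c(rep(1L, 32), rep(2L, 32)), 8, 8) # two blocks
  b <- matrix(rep(c(1L, 2L), 32), 8, 8) # stripes
  ra <- gm_raster(a, cell_size = 10)
  rb <- gm_raster(b, cell_size = 10)
  expect_equal(shdi(ra), shdi(rb))
  ma <- landscape_metrics(ra)
  mb <- landscape_metrics(rb)
  expect_false(isTRUE(all.equal(ma$lpi, mb$lpi)))
  expect_false(isTRUE(all.equal(ma$ed, mb$ed)))
})

test_that("all metrics agree with a brute-force oracle on random small rasters", {
  set.seed(2024)
  for (draw in 1:100) {
    nr <- sample(2:8, 1)
    nc <- sample(2:8, 1)
    k <- sample(1:3, 1)
    cs <- sample(c(5, 10, 30), 1)
    conn <- sample(c(4, 8), 1)
    v <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
    r <- gm_raster(v, cell_size = cs)
    ps <- delineate_patches(r, connectivity = conn)
    oracle <- brute_landscape(v, cs, connectivity = conn)
    expect_equal(nrow(ps$patches), oracle$n_patches)
    expect_equal(lpi(ps), oracle$lpi)
    expect_equal(patch_density(ps), oracle$pd)
    expect_equal(edge_density(ps), oracle$ed)
    expect_equal(shdi(r), oracle$shdi)
  }
})
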
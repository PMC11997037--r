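test_that("lattice adjacency has the expected degrees", {
  g3 <- generate_spot_grid(square_cfg(extent = c(300, 300), pitch = 100))
  adj <- build_adjacency(g3)
  deg <- lengths(adj)
  r <- sqrt((g3$x_um - 150)^2 + (g3$y_um - 150)^2)
  expect_equal(deg[r > 120], rep(2L, 4), ignore_attr = TRUE)   # corners
  expect_equal(deg[[which.min(r)]], 4L)                        # center
  gh <- generate_spot_grid(hex_cfg(section_extent_um = c(900, 900),
                                   tumor_radius_um = 300,
                                   zone_edges_um = c(60, 120, 180, 240)))
  adjh <- build_adjacency(gh)
  interior <- gh$x_um > 150 & gh$x_um < 750 & gh$y_um > 150 & gh$y_um < 750
  expect_true(all(lengths(adjh)[interior] == 6))
  # symmetric, no self loops
  for (i in seq_along(adjh)) {
    expect_false(i %in% adjh[[i]])
    expect_true(all(vapply(adjh[[i]], function(j) i %in% adjh[[j]],
                           logical(1))))
  }
})

test_that("adjacency matches the all-pairs threshold oracle on random grids", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(20:60, 1)
    grid <- toy_grid(runif(n, 0, 10), runif(n, 0, 10), lattice = "hex",
                     pitch = 2)
    adj <- build_adjacency(grid)
    oracle <- bf_adjacency(grid, 1.05 * 2)
    expect_equal(lapply(adj, sort), lapply(oracle, sort),
                 ignore_attr = TRUE)
  }
})

test_that("connected tumor components become separate regions", {
  cfg <- square_cfg(extent = c(900, 900), pitch = 100)
  grid <- generate_spot_grid(cfg)
  adj <- build_adjacency(grid)
  # two blobs separated by a normal column
  left <- grid$barcode[grid$x_um <= 250]
  right <- grid$barcode[grid$x_um >= 550]
  comp <- toy_comp(grid, c(left, right))
  regs <- extract_tumor_regions(comp, adj, grid, min_spots = 1L)
  expect_length(regs, 2L)
  # single-spot region: the spot is its own boundary at distance zero
  comp1 <- toy_comp(grid, grid$barcode[1])
  regs1 <- extract_tumor_regions(comp1, adj, grid, min_spots = 1L)
  fld <- spot_edge_distance(regs1[[1]], grid)
  expect_equal(fld$distance_um, 0)
  # min_spots filtering drops small components and can empty the list
  expect_message(
    regs2 <- extract_tumor_regions(comp, adj, grid, min_spots = 30L),
    "dropped")
  expect_length(regs2, 1L)
  expect_error(extract_tumor_regions(comp1, adj, grid, min_spots = 2L),
               "no tumor region")
})

test_that("boundary spots match a brute-force neighbor scan", {
  gh <- generate_spot_grid(hex_cfg(section_extent_um = c(1500, 1500),
                                   tumor_radius_um = 500,
                                   zone_edges_um = c(100, 200, 300, 400)))
  adjh <- build_adjacency(gh)
  for (s in 1:10) {
    blob <- random_tumor_blob(gh, adjh, n_target = 40, seed = s)
    comp <- toy_comp(gh, blob)
    regs <- extract_tumor_regions(comp, adjh, gh, min_spots = 1L)
    got <- sort(unlist(lapply(regs, `[[`, "boundary")))
    want <- sort(gh$barcode[bf_boundary(gh, adjh, comp,
                                        match(blob, gh$barcode), 6L)])
    expect_equal(got, want)
  }
})

test_that("spot edge distances equal the brute-force oracle exactly", {
  gh <- generate_spot_grid(hex_cfg(section_extent_um = c(1500, 1500),
                                   tumor_radius_um = 500,
                                   zone_edges_um = c(100, 200, 300, 400)))
  adjh <- build_adjacency(gh)
  for (s in 1:10) {
    blob <- random_tumor_blob(gh, adjh, n_target = 60, seed = 100 + s)
    comp <- toy_comp(gh, blob)
    regs <- extract_tumor_regions(comp, adjh, gh, min_spots = 1L)
    for (rg in regs) {
      fld <- spot_edge_distance(rg, gh)
      want <- bf_spot_dist(gh, match(rg$barcodes, gh$barcode),
                           match(rg$boundary, gh$barcode))
      expect_equal(fld$distance_um, want)
    }
  }
})

test_that("a filled square block has center distance of three pitches", {
  gs <- generate_spot_grid(square_cfg(extent = c(900, 900), pitch = 100))
  ctr <- which(gs$x_um == 450 & gs$y_um == 450)
  block <- gs$barcode[abs(gs$x_um - 450) <= 300 & abs(gs$y_um - 450) <= 300]
  comp <- toy_comp(gs, block)  # 7x7 block; perimeter is the boundary
  adjs <- build_adjacency(gs)
  regs <- extract_tumor_regions(comp, adjs, gs, min_spots = 1L)
  fld <- spot_edge_distance(regs[[1]], gs)
  expect_equal(fld$distance_um[fld$subject_id == gs$barcode[ctr]], 300,
               tolerance = 1e-9)
  # a thin ring is all boundary, all distances zero
  ring <- setdiff(block, gs$barcode[abs(gs$x_um - 450) <= 200 &
                                    abs(gs$y_um - 450) <= 200])
  compr <- toy_comp(gs, ring)
  regr <- extract_tumor_regions(compr, adjs, gs, min_spots = 1L)
  fldr <- spot_edge_distance(regr[[1]], gs)
  expect_true(all(fldr$distance_um == 0))
})

test_that("cell distance transform respects disc geometry", {
  # circular mask of radius 500 um at 10 um pixels
  px <- 10
  n <- 110
  ctr <- n / 2 * px
  cx <- (col(matrix(0, n, n)) - 0.5) * px
  cy <- (row(matrix(0, n, n)) - 0.5) * px
  mask <- (cx - ctr)^2 + (cy - ctr)^2 <= 500^2
  rg <- region_from_mask(mask, px, c(0, 0))
  cells <- toy_cells(ctr, ctr)
  fld <- cell_edge_distance(rg, cells)
  # pixel-bounded: cell-to-pixel snapping plus the half-open boundary-pixel
  # layer each contribute up to ~one pixel
  expect_lt(abs(fld$distance_um - 500), 2 * px + 1e-9)
  # cells outside the mask are excluded with a message
  far <- toy_cells(c(ctr, 1), c(ctr, 1))
  expect_message(fld2 <- cell_edge_distance(rg, far), "excluded")
  expect_equal(nrow(fld2), 1L)
})

test_that("cell EDT matches a brute-force boundary-pixel scan", {
  for (s in 1:8) {
    set.seed(s)
    n <- 40
    # random blobby mask: union of a few discs
    cx <- (col(matrix(0, n, n)) - 0.5); cy <- (row(matrix(0, n, n)) - 0.5)
    mask <- matrix(FALSE, n, n)
    for (k in 1:3) {
      c0 <- runif(2, 8, 32); r0 <- runif(1, 5, 12)
      mask <- mask | ((cx - c0[1])^2 + (cy - c0[2])^2 <= r0^2)
    }
    if (!any(mask)) next
    rg <- region_from_mask(mask, px_size_um = 5)
    got <- edgeniche:::region_edt(rg)
    want <- bf_edt(mask)
    inm <- which(mask)
    expect_lt(max(abs(got[inm] - want[inm])), sqrt(2) / 2 + 1e-9)
  }
})

test_that("shell profiles conserve counts and handle empty input", {
  rg <- strip_region(L = 1000, W = 200)
  cells <- simulate_region_cells(rg, 150, 0, 100, seed = 4)
  fld <- cell_edge_distance(rg, cells)
  pr <- shell_profile(fld, rg, cells)
  dp <- pr[pr$class == "CD44+PTN+", ]
  expect_equal(sum(dp$count), nrow(cells))
  expect_equal(dp$density_per_mm2, dp$count / dp$area_mm2)
  # shell areas sum to the mask area
  expect_equal(sum(dp$area_mm2), sum(rg$mask$px) * (10 / 1000)^2)
  # homogeneous cells: per-bin densities near the global density
  glob <- nrow(cells) / sum(dp$area_mm2)
  se <- 3 * sqrt(glob / dp$area_mm2)
  expect_true(all(abs(dp$density_per_mm2 - glob) <= se))
  # zero cells: densities zero, areas intact
  none <- cells[0, ]
  fld0 <- cell_edge_distance(rg, none)
  pr0 <- shell_profile(fld0, rg, none)
  expect_true(all(pr0$density_per_mm2 == 0))
  expect_true(all(pr0$area_mm2 > 0))
})

test_that("exclusive and superset class semantics differ as documented", {
  rg <- strip_region(L = 600, W = 150)
  cells <- rbind(
    simulate_region_cells(rg, 100, 0, 100, class = "CD44+", seed = 1),
    simulate_region_cells(rg, 100, 0, 100, class = "CD44+PTN+", seed = 2))
  cells$cell_id <- sprintf("C-%04d", seq_len(nrow(cells)))
  cells <- edgeniche:::new_cell_table(cells)
  fld <- cell_edge_distance(rg, cells)
  excl <- shell_profile(fld, rg, cells, superset = FALSE)
  sup <- shell_profile(fld, rg, cells, superset = TRUE)
  n_single <- sum(cells$CD44_pos & !cells$PTN_pos)
  n_all <- sum(cells$CD44_pos)
  expect_equal(sum(excl$count[excl$class == "CD44+"]), n_single)
  expect_equal(sum(sup$count[sup$class == "CD44+"]), n_all)
})

test_that("distances and profiles are translation invariant", {
  cfg <- hex_cfg(seed = 21, section_extent_um = c(1600, 1600),
                 tumor_radius_um = 450, zone_edges_um = c(90, 180, 270, 360))
  sec <- simulate_section(cfg)
  adj <- build_adjacency(sec$grid)
  regs <- extract_tumor_regions(sec$compartments, adj, sec$grid)
  fld <- spot_edge_distance(regs[[1]], sec$grid)

  shift <- sec$grid
  shift$x_um <- shift$x_um + 1234.5
  shift$y_um <- shift$y_um - 987.6
  shift <- edgeniche:::new_spot_grid(as.data.frame(shift), "hex", 100, 50)
  adj2 <- build_adjacency(shift)
  regs2 <- extract_tumor_regions(sec$compartments, adj2, shift)
  fld2 <- spot_edge_distance(regs2[[1]], shift)
  expect_equal(fld2$distance_um, fld$distance_um, tolerance = 1e-9)
})

test_that("too-coarse rasters are rejected", {
  cfg <- hex_cfg(seed = 2, section_extent_um = c(1600, 1600),
                 tumor_radius_um = 450, zone_edges_um = c(90, 180, 270, 360))
  grid <- generate_spot_grid(cfg)
  comp <- assign_compartments(grid, cfg)
  adj <- build_adjacency(grid)
  expect_error(extract_tumor_regions(comp, adj, grid, raster_um = 150),
               "coarse")
})
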
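# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (O(n^2) scans, direct enumeration) so they check the
# package implementations without sharing code paths with them.

# -- fixture builders --------------------------------------------------------

square_cfg <- function(extent = c(300, 300), pitch = 100, seed = 1, ...) {
  synthetic_config(seed = seed, lattice = "square", pitch_um = pitch,
                   spot_diameter_um = pitch / 2,
                   section_extent_um = extent,
                   tumor_center_um = extent / 2,
                   tumor_radius_um = min(extent) / 2 - pitch / 10,
                   zone_edges_um = min(extent) / 2 * c(.2, .4, .6, .8) - pitch / 10,
                   ...)
}

hex_cfg <- function(seed = 1, ...) {
  dots <- list(...)
  extent <- dots$section_extent_um %||% c(3000, 3000)
  dots$section_extent_um <- extent
  if (is.null(dots$tumor_center_um)) dots$tumor_center_um <- extent / 2
  do.call(synthetic_config, c(list(seed = seed, lattice = "hex"), dots))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# toy spot grid from explicit coordinates (unexported constructor)
toy_grid <- function(x, y, lattice = "square", pitch = 1) {
  edgeniche:::new_spot_grid(
    data.frame(barcode = sprintf("BC-%03d", seq_along(x)),
               array_row = 0L, array_col = seq_along(x) - 1L,
               x_um = x, y_um = y, stringsAsFactors = FALSE),
    lattice, pitch, pitch / 2)
}

# compartment map with given tumor barcodes on a grid
toy_comp <- function(grid, tumor_bc, zone = NULL) {
  comp <- ifelse(grid$barcode %in% tumor_bc, "tumor", "normal_gland")
  z <- rep(NA_character_, nrow(grid))
  if (!is.null(zone)) z[match(names(zone), grid$barcode)] <- zone
  edgeniche:::new_compartment_map(
    data.frame(barcode = grid$barcode, compartment = comp, zone = z,
               stringsAsFactors = FALSE))
}

toy_cells <- function(x, y, cd44 = TRUE, ptn = TRUE) {
  edgeniche:::new_cell_table(
    data.frame(cell_id = sprintf("C-%04d", seq_along(x)),
               x_um = x, y_um = y,
               CD44_pos = rep_len(cd44, length(x)),
               PTN_pos = rep_len(ptn, length(x)),
               stringsAsFactors = FALSE))
}

# a rectangular strip region mask (length L x width 2W um), raster px um
strip_region <- function(L = 2500, W = 300, px = 10, id = "R01") {
  m <- matrix(TRUE, nrow = ceiling(2 * W / px), ncol = ceiling(L / px))
  region_from_mask(m, px_size_um = px, origin_um = c(0, 0), region_id = id)
}

# random blob of tumor spots grown from a seed spot on a hex grid
random_tumor_blob <- function(grid, adj, n_target, seed) {
  set.seed(seed)
  start <- sample(nrow(grid), 1)
  mem <- start
  frontier <- adj[[start]]
  while (length(mem) < n_target && length(frontier)) {
    nxt <- sample(frontier, 1)
    mem <- union(mem, nxt)
    frontier <- setdiff(union(frontier, adj[[nxt]]), mem)
  }
  grid$barcode[mem]
}

# -- oracles -----------------------------------------------------------------

bf_adjacency <- function(grid, thr) {
  n <- nrow(grid)
  lapply(seq_len(n), function(i) {
    d <- sqrt((grid$x_um - grid$x_um[i])^2 + (grid$y_um - grid$y_um[i])^2)
    setdiff(which(d <= thr), i)
  })
}

bf_boundary <- function(grid, adj, comp, members, interior_deg) {
  members[vapply(members, function(i) {
    js <- adj[[i]]
    length(js) < interior_deg ||
      any(comp$compartment[js] != "tumor")
  }, logical(1))]
}

bf_spot_dist <- function(grid, members, boundary) {
  vapply(members, function(i) {
    min(sqrt((grid$x_um[boundary] - grid$x_um[i])^2 +
             (grid$y_um[boundary] - grid$y_um[i])^2))
  }, numeric(1))
}

# brute-force distance of every mask pixel to the nearest boundary-pixel
# center (boundary = mask pixel with a 4-neighbor outside the mask)
bf_edt <- function(px) {
  ny <- nrow(px); nx <- ncol(px)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- px
  bnd <- which(px & !(pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
                      pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]),
               arr.ind = TRUE)
  out <- matrix(NA_real_, ny, nx)
  inm <- which(px, arr.ind = TRUE)
  for (k in seq_len(nrow(inm))) {
    out[inm[k, 1], inm[k, 2]] <-
      sqrt(min((bnd[, 1] - inm[k, 1])^2 + (bnd[, 2] - inm[k, 2])^2))
  }
  out
}

bf_top_quantile <- function(expr, barcodes, q) {
  ord <- order(-expr, barcodes)
  barcodes[ord][seq_len(ceiling(q * length(barcodes)))]
}

bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(ord)]
}

# exhaustive recovery-curve AUC for one expression vector
bf_auc <- function(expr, genes, signature, top_frac) {
  ord <- order(-expr, genes)
  n_top <- max(1, floor(top_frac * length(genes)))
  hits <- cumsum(genes[ord][seq_len(n_top)] %in% signature)
  m <- min(sum(signature %in% genes), n_top)
  sum(hits) / sum(pmin(seq_len(n_top), m))
}
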
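#' Build the spot adjacency graph
#'
#' Neighbors are spot pairs whose center distance is at most 1.05 * pitch
#' (hex lattice) or exactly the axis-aligned pitch (square lattice, with the
#' same 5% numeric slack). Isolated spots keep an empty neighbor list.
#'
#' @param grid a \code{spot_grid}.
#' @return an \code{adjacency_graph}: named list of integer neighbor index
#'   vectors, one per spot, with the grid's barcodes as names.
#' @export
build_adjacency <- function(grid) {
  p <- grid_pitch(grid)
  thr <- if (grid_lattice(grid) == "hex") 1.05 * p else 1.05 * p
  x <- grid$x_um; y <- grid$y_um; n <- length(x)
  square <- grid_lattice(grid) == "square"
  nbr <- vector("list", n)
  # chunked pairwise scan keeps memory bounded on large sections
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    dx <- outer(x[idx], x, "-"); dy <- outer(y[idx], y, "-")
    if (square) {
      hit <- (abs(dx) <= thr & abs(dy) < p * 0.05) |
             (abs(dy) <= thr & abs(dx) < p * 0.05)
    } else {
      hit <- dx * dx + dy * dy <= thr * thr
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      js <- which(hit[k, ])
      nbr[[i]] <- js[js != i]
    }
  }
  names(nbr) <- grid$barcode
  structure(nbr, class = "adjacency_graph",
            lattice = grid_lattice(grid), pitch_um = p)
}

#' Extract connected tumor regions with boundaries and rasterized masks
#'
#' Tumor-labeled spots are split into connected components under the lattice
#' adjacency; components smaller than \code{min_spots} are dropped (with a
#' message). A region's boundary is the set of its member spots having at
#' least one non-tumor or off-lattice neighbor (lattice degree below the
#' interior degree). The region mask is the union of the members' lattice
#' cells, rasterized by assigning each pixel to its nearest spot center
#' (capped at 0.75 * pitch) and keeping pixels whose nearest spot is a
#' member.
#'
#' @param comp a \code{compartment_map}.
#' @param adj matching \code{adjacency_graph}.
#' @param grid matching \code{spot_grid}.
#' @param min_spots minimum component size retained.
#' @param raster_um mask pixel size in micrometers.
#' @return list of \code{tumor_region} objects.
#' @export
extract_tumor_regions <- function(comp, adj, grid, min_spots = 10L,
                                  raster_um = 10) {
  stopifnot(identical(names(adj), grid$barcode),
            identical(comp$barcode, grid$barcode))
  if (raster_um > grid_pitch(grid))
    abort("mask too coarse: raster pixel size exceeds the lattice pitch")
  tum <- which(comp$compartment == "tumor")
  if (!length(tum)) abort("no tumor region: no tumor-labeled spots")
  sub <- lapply(adj[tum], function(js) match(js[js %in% tum], tum))
  el <- do.call(rbind, lapply(seq_along(sub), function(i) {
    js <- sub[[i]]; js <- js[!is.na(js) & js > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  g <- igraph::graph_from_edgelist(
    if (is.null(el)) matrix(integer(0), ncol = 2) else el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(tum) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  interior_deg <- if (grid_lattice(grid) == "hex") 6L else 4L
  regions <- list()
  dropped <- 0L
  for (cid in sort(unique(memb))) {
    mem <- tum[memb == cid]
    if (length(mem) < min_spots) { dropped <- dropped + 1L; next }
    bnd <- mem[vapply(mem, function(i) {
      js <- adj[[i]]
      length(js) < interior_deg || any(comp$compartment[js] != "tumor")
    }, logical(1))]
    mask <- rasterize_region(grid, mem, raster_um)
    regions[[length(regions) + 1L]] <- structure(list(
      region_id = sprintf("R%02d", length(regions) + 1L),
      barcodes = grid$barcode[mem], boundary = grid$barcode[bnd],
      mask = mask, pitch_um = grid_pitch(grid)), class = "tumor_region")
  }
  if (dropped) message(dropped, " tumor component(s) below min_spots dropped")
  if (!length(regions)) abort("no tumor region left after size filtering")
  regions
}

# Voronoi-style rasterization of the union of member lattice cells.
rasterize_region <- function(grid, members, raster_um) {
  p <- grid_pitch(grid)
  pad <- p  # background margin so boundary pixels always exist
  x0 <- min(grid$x_um[members]) - pad; x1 <- max(grid$x_um[members]) + pad
  y0 <- min(grid$y_um[members]) - pad; y1 <- max(grid$y_um[members]) + pad
  nx <- ceiling((x1 - x0) / raster_um); ny <- ceiling((y1 - y0) / raster_um)
  cx <- x0 + (seq_len(nx) - 0.5) * raster_um
  cy <- y0 + (seq_len(ny) - 0.5) * raster_um
  # restrict candidate spots to the raster window
  cand <- which(grid$x_um >= x0 - p & grid$x_um <= x1 + p &
                grid$y_um >= y0 - p & grid$y_um <= y1 + p)
  is_mem <- cand %in% members
  px <- matrix(FALSE, nrow = ny, ncol = nx)
  cap2 <- (0.75 * p)^2
  for (j in seq_len(nx)) {
    dx2 <- (grid$x_um[cand] - cx[j])^2
    # distances of all candidate spots to each pixel of column j
    d2 <- outer(grid$y_um[cand], cy, function(sy, py) (sy - py)^2) + dx2
    nearest <- max.col(-t(d2), ties.method = "first")
    dmin <- d2[cbind(nearest, seq_len(ny))]
    px[, j] <- is_mem[nearest] & dmin <= cap2
  }
  list(px = px, px_size_um = raster_um, origin_um = c(x0, y0))
}

# column-major linear index of the pixel containing each (x, y); NA outside.
mask_pixel_index <- function(mask, x, y) {
  j <- floor((x - mask$origin_um[1]) / mask$px_size_um) + 1L
  i <- floor((y - mask$origin_um[2]) / mask$px_size_um) + 1L
  ok <- i >= 1L & i <= nrow(mask$px) & j >= 1L & j <= ncol(mask$px)
  out <- rep(NA_integer_, length(x))
  out[ok] <- (j[ok] - 1L) * nrow(mask$px) + i[ok]
  out
}

#' Construct a tumor region directly from a logical mask
#'
#' Escape hatch for tests and for cell tables without a spot lattice: wraps
#' a logical pixel matrix (rows = y, cols = x, image convention) as a
#' \code{tumor_region} with an empty spot membership.
#'
#' @param px logical matrix; TRUE pixels belong to the region.
#' @param px_size_um pixel edge length in micrometers.
#' @param origin_um coordinates of the raster's top-left corner.
#' @param region_id identifier string.
#' @return a \code{tumor_region}.
#' @export
region_from_mask <- function(px, px_size_um, origin_um = c(0, 0),
                             region_id = "R01") {
  stopifnot(is.matrix(px), is.logical(px))
  if (!any(px)) abort("mask area must be > 0")
  structure(list(region_id = region_id, barcodes = character(),
                 boundary = character(),
                 mask = list(px = px, px_size_um = px_size_um,
                             origin_um = as.numeric(origin_um)),
                 pitch_um = NA_real_), class = "tumor_region")
}

# Euclidean distance (pixels) of every pixel to the nearest boundary pixel
# of the mask. Boundary pixels are mask pixels with a 4-neighbor outside the
# mask (raster border counts as outside). Cached on the region's environment
# would complicate the value semantics, so it is recomputed on demand.
region_edt <- function(region) {
  m <- region$mask$px
  ny <- nrow(m); nx <- ncol(m)
  up <- rbind(FALSE, m[-ny, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -nx, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  boundary <- m & !(up & dn & lf & rt)
  img <- matrix(1L, ny, nx)
  img[boundary] <- 0L
  EBImage::distmap(img, metric = "euclidean")
}

#' Spot distance-to-edge field
#'
#' Distance of every member spot of a region to the tumor boundary, defined
#' as the Euclidean distance from the spot center to the nearest
#' boundary-spot center. Boundary spots are exactly 0.
#'
#' @param region a \code{tumor_region} from \code{\link{extract_tumor_regions}}.
#' @param grid the matching \code{spot_grid}.
#' @return an \code{edge_distance_field} data.frame (subject_id, region_id,
#'   distance_um) with attribute \code{subject = "spots"}.
#' @export
spot_edge_distance <- function(region, grid) {
  mi <- match(region$barcodes, grid$barcode)
  bi <- match(region$boundary, grid$barcode)
  if (anyNA(mi) || anyNA(bi)) abort("region barcodes missing from grid")
  dx <- outer(grid$x_um[mi], grid$x_um[bi], "-")
  dy <- outer(grid$y_um[mi], grid$y_um[bi], "-")
  d <- sqrt(apply(dx * dx + dy * dy, 1, min))
  new_edge_field(data.frame(subject_id = region$barcodes,
                            region_id = region$region_id,
                            distance_um = d, stringsAsFactors = FALSE),
                 "spots")
}

new_edge_field <- function(df, subject) {
  if (any(df$distance_um < 0)) abort("negative distance")
  structure(df, class = c("edge_distance_field", "data.frame"),
            subject = subject)
}

#' Cell distance-to-edge field
#'
#' Maps each cell to its raster pixel in the region mask and reads off the
#' Euclidean distance transform to the mask's outer boundary (boundary-pixel
#' centers), in micrometers. Cells falling outside the mask are excluded
#' and their count reported via a message.
#'
#' @param region a \code{tumor_region}.
#' @param cells a \code{cell_table}.
#' @return an \code{edge_distance_field} with attribute
#'   \code{subject = "cells"}.
#' @export
cell_edge_distance <- function(region, cells) {
  if (!is.na(region$pitch_um) &&
      region$mask$px_size_um > region$pitch_um)
    abort("mask too coarse: pixel size exceeds the lattice pitch")
  edt <- region_edt(region)
  px <- mask_pixel_index(region$mask, cells$x_um, cells$y_um)
  inside <- !is.na(px) & region$mask$px[ifelse(is.na(px), 1L, px)]
  n_out <- sum(!inside)
  if (n_out) message(n_out, " cell(s) outside region mask excluded")
  d <- edt[px[inside]] * region$mask$px_size_um
  new_edge_field(data.frame(subject_id = cells$cell_id[inside],
                            region_id = rep(region$region_id, sum(inside)),
                            distance_um = d, stringsAsFactors = FALSE),
                 "cells")
}

#' Shell-binned density profile of marker-positive cells
#'
#' Bins in-region cells by distance to the tumor edge into half-open shells
#' \code{[0, w), [w, 2w), ...} and divides counts by the shell areas read
#' off the mask raster (pixels whose distance transform falls in the bin).
#' By default the classes are mutually exclusive as plotted in stainings:
#' CD44+ means CD44-positive and PTN-negative, PTN+ the reverse, and
#' CD44+PTN+ double positive; with \code{superset = TRUE} the single-marker
#' classes include double positives.
#'
#' @param field a cell \code{edge_distance_field}.
#' @param region the matching \code{tumor_region}.
#' @param cells the \code{cell_table} carrying the marker flags.
#' @param bin_width_um shell width, micrometers.
#' @param superset if TRUE, CD44+ / PTN+ are supersets of the double
#'   positives.
#' @return a \code{density_profile} data.frame (class, bin_lo, bin_hi,
#'   bin_mid, count, area_mm2, density_per_mm2).
#' @export
shell_profile <- function(field, region, cells, bin_width_um = 50,
                          superset = FALSE) {
  if (!identical(attr(field, "subject"), "cells"))
    abort("shell_profile needs a cell distance field")
  if (!any(region$mask$px)) abort("empty region")
  edt_um <- region_edt(region)[region$mask$px] * region$mask$px_size_um
  edges <- seq(0, max(edt_um, field$distance_um, bin_width_um) + bin_width_um,
               by = bin_width_um)
  px_area_mm2 <- (region$mask$px_size_um / 1000)^2
  area <- as.numeric(table(factor(findInterval(edt_um, edges,
                                               left.open = FALSE),
                                  levels = seq_len(length(edges) - 1L)))) *
    px_area_mm2
  keep <- area > 0
  idx <- match(field$subject_id, cells$cell_id)
  cls <- cell_class_labels(cells[idx, , drop = FALSE], superset)
  out <- list()
  for (cl in CELL_CLASSES) {
    d <- field$distance_um[cls[[cl]]]
    cnt <- as.numeric(table(factor(findInterval(d, edges, left.open = FALSE),
                                   levels = seq_len(length(edges) - 1L))))
    out[[cl]] <- data.frame(
      class = cl, bin_lo = edges[-length(edges)][keep],
      bin_hi = edges[-1][keep],
      bin_mid = (edges[-1] - bin_width_um / 2)[keep],
      count = cnt[keep], area_mm2 = area[keep],
      density_per_mm2 = cnt[keep] / area[keep],
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("density_profile", "data.frame"),
            bin_width_um = bin_width_um, region_id = region$region_id)
}

cell_class_labels <- function(cells, superset) {
  if (superset) {
    list(`CD44+` = cells$CD44_pos,
         `PTN+` = cells$PTN_pos,
         `CD44+PTN+` = cells$CD44_pos & cells$PTN_pos)
  } else {
    list(`CD44+` = cells$CD44_pos & !cells$PTN_pos,
         `PTN+` = cells$PTN_pos & !cells$CD44_pos,
         `CD44+PTN+` = cells$CD44_pos & cells$PTN_pos)
  }
}

#' Pool density profiles across tumor regions
#'
#' Sums per-bin counts and shell areas over regions (matching bins by their
#' edges) and recomputes densities, i.e. an area-weighted pooled profile.
#'
#' @param profiles list of \code{density_profile} objects with identical bin
#'   width.
#' @return a pooled \code{density_profile}.
#' @export
pool_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  bw <- unique(vapply(profiles, attr, numeric(1), "bin_width_um"))
  if (length(bw) != 1L) abort("profiles must share a bin width")
  all <- do.call(rbind, lapply(profiles, as.data.frame))
  agg <- stats::aggregate(cbind(count, area_mm2) ~ class + bin_lo + bin_hi +
                            bin_mid, data = all, FUN = sum)
  agg <- agg[order(agg$class, agg$bin_lo), ]
  agg$density_per_mm2 <- agg$count / agg$area_mm2
  agg <- agg[, c("class", "bin_lo", "bin_hi", "bin_mid", "count",
                 "area_mm2", "density_per_mm2")]
  structure(agg, class = c("density_profile", "data.frame"),
            bin_width_um = bw, region_id = "pooled",
            row.names = seq_len(nrow(agg)))
}
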
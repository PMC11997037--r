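#' Configuration for a synthetic tumor section
#'
#' Builds the parameter set for the synthetic-section generator. The defaults
#' emulate the layered ring-like architecture of chemically induced mouse
#' colorectal tumors on a Visium-style lattice: a hexagonal spot grid (100 um
#' pitch, 50 um spot diameter), a central tumor disc split into five
#' concentric zones T1 (innermost) to T5 (outer rim), surrounding bands of
#' submucosa, muscularis and lymphoid follicle with normal gland elsewhere,
#' CD44 expression rising toward the tumor edge, Lgr5 rising toward the
#' center, edge-weighted CAF/TAN marker genes, and cell point clouds whose
#' CD44+ and CD44+PTN+ densities increase toward the tumor boundary while
#' PTN+ single-positive cells stay spatially flat.
#'
#' @param seed master integer seed; each generated artifact (counts, cells)
#'   uses its own substream derived from it by a fixed offset.
#' @param lattice "hex" (offset rows, interior degree 6) or "square".
#' @param pitch_um center-to-center spot spacing, micrometers.
#' @param spot_diameter_um capture-spot diameter; must not exceed the pitch.
#' @param section_extent_um width and height of the section in micrometers.
#' @param tumor_center_um,tumor_radius_um geometry of the tumor disc.
#' @param zone_edges_um four ascending radii (< tumor_radius_um) splitting
#'   the disc into zones T1..T5.
#' @param compartment_band_widths_um named vector of band widths laid
#'   concentrically outside the tumor disc, in order; spots beyond the last
#'   band are labeled normal_gland.
#' @param nb_mean named list: compartment -> named numeric vector of
#'   per-gene negative-binomial base means. All compartments must cover the
#'   same gene set with strictly positive means.
#' @param nb_dispersion negative-binomial size parameter k
#'   (variance = mu + mu^2/k); one global value.
#' @param gradient_genes named list: gene -> list(direction = "edge_high",
#'   "center_high" or "flat", amplitude >= 0, decay_tau_um > 0). Inside the
#'   tumor the base mean is multiplied by 1 + amplitude*exp(-d/tau)
#'   (edge_high) or 1 + amplitude*exp(-(R-d)/tau) (center_high) where d is
#'   the spot's distance to the tumor boundary and R the maximum in-tumor
#'   distance.
#' @param cell_classes named list: class ("CD44+", "PTN+", "CD44+PTN+") ->
#'   list(lambda0_per_mm2, lambda1_per_mm2, decay_tau_um); cells are drawn
#'   from an inhomogeneous Poisson process with intensity
#'   lambda0 + lambda1*exp(-d/tau) inside the tumor mask.
#' @param raster_um pixel size of the rasterized tumor mask shared with the
#'   geometry stage.
#' @return an object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             lattice = c("hex", "square"),
                             pitch_um = 100,
                             spot_diameter_um = 50,
                             section_extent_um = c(3000, 3000),
                             tumor_center_um = c(1500, 1500),
                             tumor_radius_um = 800,
                             zone_edges_um = c(160, 320, 480, 640),
                             compartment_band_widths_um = c(
                               submucosa = 300,
                               muscularis = 300,
                               lymphoid_follicle = 200),
                             nb_mean = NULL,
                             nb_dispersion = 2,
                             gradient_genes = NULL,
                             cell_classes = NULL,
                             raster_um = 10) {
  lattice <- match.arg(lattice)
  check_scalar_num(pitch_um, "pitch_um", positive = TRUE)
  check_scalar_num(spot_diameter_um, "spot_diameter_um", positive = TRUE)
  if (spot_diameter_um > pitch_um)
    abort("spot_diameter_um must not exceed pitch_um")
  if (length(section_extent_um) != 2L || any(section_extent_um <= 0))
    abort("section_extent_um must be two positive numbers")
  check_scalar_num(tumor_radius_um, "tumor_radius_um", positive = TRUE)
  if (length(zone_edges_um) != 4L || any(diff(zone_edges_um) <= 0) ||
      any(zone_edges_um <= 0) || any(zone_edges_um >= tumor_radius_um))
    abort("zone_edges_um must be 4 strictly ascending radii < tumor_radius_um")
  if (length(compartment_band_widths_um)) {
    bad <- setdiff(names(compartment_band_widths_um), COMPARTMENTS)
    if (length(bad))
      abort("unknown band compartment(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(names(compartment_band_widths_um)))
      abort("overlapping band specification: duplicated compartment names")
    if (any(compartment_band_widths_um <= 0))
      abort("band widths must be positive")
  }
  check_scalar_num(nb_dispersion, "nb_dispersion", positive = TRUE)
  check_scalar_num(raster_um, "raster_um", positive = TRUE)

  if (is.null(nb_mean)) nb_mean <- default_nb_mean()
  genes <- names(nb_mean[[1]])
  for (cmp in names(nb_mean)) {
    if (!setequal(names(nb_mean[[cmp]]), genes))
      abort("nb_mean compartments must cover identical gene sets")
    if (any(nb_mean[[cmp]] <= 0))
      abort("nonpositive mean: all nb_mean entries must be > 0")
  }
  if (!setequal(names(nb_mean), COMPARTMENTS))
    abort("nb_mean must map all five compartments")

  if (is.null(gradient_genes)) gradient_genes <- default_gradient_genes()
  for (g in names(gradient_genes)) {
    if (!g %in% genes)
      abort("gradient gene '", g, "' missing from nb_mean")
    gg <- gradient_genes[[g]]
    if (!gg$direction %in% c("edge_high", "center_high", "flat"))
      abort("gradient direction must be edge_high, center_high or flat")
    if (gg$amplitude < 0) abort("gradient amplitude must be >= 0")
    if (gg$decay_tau_um <= 0) abort("gradient decay_tau_um must be > 0")
  }

  if (is.null(cell_classes)) cell_classes <- default_cell_classes()
  bad <- setdiff(names(cell_classes), CELL_CLASSES)
  if (length(bad)) abort("unknown cell class(es): ", paste(bad, collapse = ", "))
  for (cl in names(cell_classes)) {
    cc <- cell_classes[[cl]]
    if (cc$lambda0_per_mm2 < 0 || cc$lambda1_per_mm2 < 0)
      abort("cell intensities must be >= 0")
    if (cc$decay_tau_um <= 0) abort("cell decay_tau_um must be > 0")
  }

  structure(list(
    seed = as.integer(seed), lattice = lattice, pitch_um = pitch_um,
    spot_diameter_um = spot_diameter_um,
    section_extent_um = as.numeric(section_extent_um),
    tumor_center_um = as.numeric(tumor_center_um),
    tumor_radius_um = tumor_radius_um, zone_edges_um = as.numeric(zone_edges_um),
    compartment_band_widths_um = compartment_band_widths_um,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    gradient_genes = gradient_genes, cell_classes = cell_classes,
    raster_um = raster_um), class = "synthetic_config")
}

# Default gene panel: the five classical CSC markers, Ptn, CAF/TAN markers
# and a few flat "housekeeping" genes. Tumor base means are higher for
# tumor-associated genes; stromal compartments carry low background.
default_nb_mean <- function() {
  genes <- c("CD44", "Lgr5", "Alcam", "Aldh2", "Prom1", "Ptn",
             "Col1a1", "Il11", "Pdgfrb", "Acta2", "Ly6g", "Cd101",
             "Krt20", "Hes1", "Tpm2", "Myl9", "Fabp4", "Ccl21a",
             "Actb", "Gapdh")
  base <- setNames(rep(1, length(genes)), genes)
  tumor <- base
  tumor[c("CD44", "Lgr5", "Alcam", "Aldh2", "Prom1", "Ptn")] <- 5
  tumor[c("Col1a1", "Il11", "Pdgfrb", "Acta2", "Ly6g", "Cd101")] <- 3
  tumor[c("Actb", "Gapdh")] <- 20
  normal <- base
  normal[c("Krt20", "Hes1")] <- 10
  normal[c("Actb", "Gapdh")] <- 20
  musc <- base; musc[c("Tpm2", "Myl9")] <- 10; musc[c("Actb", "Gapdh")] <- 20
  subm <- base; subm["Fabp4"] <- 10; subm[c("Actb", "Gapdh")] <- 20
  lymph <- base; lymph["Ccl21a"] <- 10; lymph[c("Actb", "Gapdh")] <- 20
  list(normal_gland = normal, tumor = tumor, muscularis = musc,
       submucosa = subm, lymphoid_follicle = lymph)
}

default_gradient_genes <- function() {
  edge <- function(a = 4, tau = 150)
    list(direction = "edge_high", amplitude = a, decay_tau_um = tau)
  list(
    CD44 = edge(), Ptn = edge(),
    Lgr5 = list(direction = "center_high", amplitude = 4, decay_tau_um = 150),
    Alcam = list(direction = "flat", amplitude = 0, decay_tau_um = 150),
    Aldh2 = list(direction = "flat", amplitude = 0, decay_tau_um = 150),
    Prom1 = list(direction = "flat", amplitude = 0, decay_tau_um = 150),
    Col1a1 = edge(), Il11 = edge(), Pdgfrb = edge(), Acta2 = edge(),
    Ly6g = edge(), Cd101 = edge())
}

default_cell_classes <- function() {
  list(
    `CD44+PTN+` = list(lambda0_per_mm2 = 20, lambda1_per_mm2 = 180,
                       decay_tau_um = 100),
    `CD44+` = list(lambda0_per_mm2 = 20, lambda1_per_mm2 = 180,
                   decay_tau_um = 100),
    `PTN+` = list(lambda0_per_mm2 = 100, lambda1_per_mm2 = 0,
                  decay_tau_um = 100))
}

#' Generate a spot lattice
#'
#' Lays a hexagonal (offset-row) or square lattice over the section extent.
#' Spot centers start half a pitch from the origin; hex rows are spaced
#' pitch*sqrt(3)/2 apart with odd rows shifted half a pitch so that every
#' interior spot has six neighbors at exactly one pitch. Deterministic:
#' involves no random draws.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a \code{spot_grid}: data.frame (barcode, array_row, array_col,
#'   x_um, y_um) with lattice, pitch_um and spot_diameter_um attributes.
#' @export
generate_spot_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$section_extent_um[1]; h <- config$section_extent_um[2]
  p <- config$pitch_um
  if (w < p || h < p) abort("degenerate section: extent smaller than one pitch")
  if (config$lattice == "square") {
    xs <- seq(p / 2, w, by = p); ys <- seq(p / 2, h, by = p)
    grid <- expand.grid(col = seq_along(xs) - 1L, row = seq_along(ys) - 1L)
    x <- xs[grid$col + 1L]; y <- ys[grid$row + 1L]
  } else {
    dy <- p * sqrt(3) / 2
    ys <- seq(p / 2, h, by = dy)
    rows <- lapply(seq_along(ys), function(i) {
      off <- if ((i - 1L) %% 2L == 1L) p / 2 else 0
      xs <- seq(p / 2 + off, w, by = p)
      if (!length(xs)) return(NULL)
      data.frame(col = seq_along(xs) - 1L, row = i - 1L, x = xs, y = ys[i])
    })
    rows <- do.call(rbind, rows)
    grid <- rows[, c("col", "row")]; x <- rows$x; y <- rows$y
  }
  n <- nrow(grid)
  if (n < 1L) abort("degenerate section: no spots fit the extent")
  out <- data.frame(
    barcode = sprintf("SYN-%05d", seq_len(n)),
    array_row = grid$row, array_col = grid$col,
    x_um = x, y_um = y, stringsAsFactors = FALSE)
  new_spot_grid(out, config$lattice, config$pitch_um, config$spot_diameter_um)
}

new_spot_grid <- function(df, lattice, pitch_um, spot_diameter_um) {
  if (anyDuplicated(df$barcode)) abort("duplicate barcodes in spot grid")
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    abort("non-finite spot coordinates")
  if (spot_diameter_um > pitch_um) abort("spot diameter exceeds pitch")
  structure(df, class = c("spot_grid", "data.frame"),
            lattice = lattice, pitch_um = pitch_um,
            spot_diameter_um = spot_diameter_um)
}

grid_pitch <- function(grid) attr(grid, "pitch_um")
grid_lattice <- function(grid) attr(grid, "lattice")

#' Assign tissue compartments and tumor zones
#'
#' Labels spots within the tumor radius as tumor, with concentric zones T1
#' (innermost) to T5 (outer rim) cut at \code{zone_edges_um}; lays the
#' configured compartment bands concentrically outside the disc and labels
#' everything beyond them normal_gland. Every spot receives exactly one of
#' the five compartments; tumor spots additionally one zone.
#'
#' @param grid a \code{spot_grid}.
#' @param config a \code{\link{synthetic_config}}.
#' @return a \code{compartment_map} data.frame (barcode, compartment, zone).
#' @export
assign_compartments <- function(grid, config) {
  ctr <- config$tumor_center_um; R <- config$tumor_radius_um
  ext <- config$section_extent_um
  if (ctr[1] - R < 0 || ctr[1] + R > ext[1] ||
      ctr[2] - R < 0 || ctr[2] + R > ext[2])
    abort("tumor disc does not fit inside the section extent")
  r <- sqrt((grid$x_um - ctr[1])^2 + (grid$y_um - ctr[2])^2)
  comp <- rep("normal_gland", nrow(grid))
  zone <- rep(NA_character_, nrow(grid))
  in_tumor <- r <= R
  comp[in_tumor] <- "tumor"
  zone[in_tumor] <- TUMOR_ZONES[
    findInterval(r[in_tumor], config$zone_edges_um, left.open = FALSE) + 1L]
  lo <- R
  for (nm in names(config$compartment_band_widths_um)) {
    hi <- lo + config$compartment_band_widths_um[[nm]]
    comp[r > lo & r <= hi] <- nm
    lo <- hi
  }
  new_compartment_map(data.frame(barcode = grid$barcode, compartment = comp,
                                 zone = zone, stringsAsFactors = FALSE))
}

new_compartment_map <- function(df) {
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad))
    abort("unknown compartment label(s) ", paste(bad, collapse = ", "),
          "; allowed: ", paste(COMPARTMENTS, collapse = ", "))
  zn <- df$zone[!is.na(df$zone)]
  badz <- setdiff(unique(zn), c(TUMOR_ZONES, GLAND_ZONES))
  if (length(badz)) abort("unknown zone label(s): ", paste(badz, collapse = ", "))
  tz <- !is.na(df$zone) & df$zone %in% TUMOR_ZONES & df$compartment != "tumor"
  gz <- !is.na(df$zone) & df$zone %in% GLAND_ZONES & df$compartment != "normal_gland"
  if (any(tz) || any(gz)) abort("zone labels on incompatible compartments")
  structure(df, class = c("compartment_map", "data.frame"))
}

#' Simulate spot-level counts with planted spatial gradients
#'
#' Draws negative-binomial counts per gene and spot with mean
#' \code{base_mean(compartment, gene) * f(d)}, where d is the spot's
#' Euclidean distance to the tumor boundary (shared definition with
#' \code{\link{spot_edge_distance}}) and f encodes the configured gradient:
#' \code{1 + A*exp(-d/tau)} for edge_high genes, \code{1 + A*exp(-(R-d)/tau)}
#' for center_high (R = maximum in-tumor distance), and 1 for flat genes and
#' all non-tumor spots. Uses the counts substream of the master seed.
#'
#' @param grid a \code{spot_grid}.
#' @param comp matching \code{compartment_map}.
#' @param config a \code{\link{synthetic_config}}.
#' @return sparse genes x spots integer \code{dgCMatrix} with dimnames.
#' @export
simulate_counts <- function(grid, comp, config) {
  stopifnot(identical(grid$barcode, comp$barcode))
  genes <- names(config$nb_mean[[1]])
  mu <- matrix(0, nrow = length(genes), ncol = nrow(grid),
               dimnames = list(genes, grid$barcode))
  for (cmp in COMPARTMENTS) {
    idx <- which(comp$compartment == cmp)
    if (length(idx)) mu[, idx] <- config$nb_mean[[cmp]][genes]
  }
  if (any(mu <= 0)) abort("nonpositive mean in count model")
  tum <- which(comp$compartment == "tumor")
  if (length(tum)) {
    adj <- build_adjacency(grid)
    regions <- extract_tumor_regions(comp, adj, grid, min_spots = 1L,
                                     raster_um = config$raster_um)
    d <- rep(NA_real_, nrow(grid)); names(d) <- grid$barcode
    for (rg in regions) {
      fld <- spot_edge_distance(rg, grid)
      d[fld$subject_id] <- fld$distance_um
    }
    Rmax <- max(d[tum], na.rm = TRUE)
    for (g in names(config$gradient_genes)) {
      gg <- config$gradient_genes[[g]]
      f <- switch(gg$direction,
        edge_high = 1 + gg$amplitude * exp(-d[tum] / gg$decay_tau_um),
        center_high = 1 + gg$amplitude * exp(-(Rmax - d[tum]) / gg$decay_tau_um),
        flat = rep(1, length(tum)))
      mu[g, tum] <- mu[g, tum] * f
    }
  }
  set.seed(child_seed(config$seed, 1L))
  cnt <- matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
                nrow = nrow(mu), dimnames = dimnames(mu))
  methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Simulate marker-positive cell point clouds
#'
#' For each configured cell class, draws an inhomogeneous Poisson point
#' process inside the rasterized tumor mask with intensity
#' \code{lambda(d) = lambda0 + lambda1*exp(-d/tau)} (cells/mm^2), where d is
#' the pixel's Euclidean distance to the mask boundary, via thinning of a
#' homogeneous process at rate lambda0 + lambda1. Uses the cells substream
#' of the master seed.
#'
#' @inheritParams simulate_counts
#' @return a \code{cell_table} data.frame (cell_id, x_um, y_um, CD44_pos,
#'   PTN_pos).
#' @export
simulate_cells <- function(comp, grid, config) {
  if (!any(comp$compartment == "tumor")) abort("empty tumor mask")
  adj <- build_adjacency(grid)
  regions <- extract_tumor_regions(comp, adj, grid, min_spots = 1L,
                                   raster_um = config$raster_um)
  set.seed(child_seed(config$seed, 2L))
  out <- list()
  for (rg in regions) {
    for (cl in names(config$cell_classes)) {
      cc <- config$cell_classes[[cl]]
      pts <- rpoispp_mask(rg, cc$lambda0_per_mm2, cc$lambda1_per_mm2,
                          cc$decay_tau_um)
      if (nrow(pts)) {
        pts$class <- cl
        pts$region_id <- rg$region_id
        out[[length(out) + 1L]] <- pts
      }
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(x_um = numeric(), y_um = numeric(), class = character(),
               region_id = character())
  flags <- class_to_flags(out$class)
  new_cell_table(data.frame(
    cell_id = sprintf("CELL-%06d", seq_len(nrow(out))),
    x_um = out$x_um, y_um = out$y_um,
    CD44_pos = flags$CD44_pos, PTN_pos = flags$PTN_pos,
    stringsAsFactors = FALSE))
}

#' Simulate cells of one class on a single region mask
#'
#' Draws an inhomogeneous Poisson point process with intensity
#' \code{lambda0 + lambda1*exp(-d/tau)} cells/mm^2 (d = distance to the
#' mask boundary, micrometers) inside one rasterized tumor region — the
#' per-region building block behind \code{\link{simulate_cells}}, exposed
#' so cell clouds can be planted on arbitrary region geometries.
#'
#' @param region a \code{tumor_region} (e.g. \code{\link{region_from_mask}}).
#' @param lambda0_per_mm2,lambda1_per_mm2,decay_tau_um intensity parameters.
#' @param class cell class label ("CD44+", "PTN+" or "CD44+PTN+").
#' @param seed RNG seed.
#' @return a \code{cell_table}.
#' @export
simulate_region_cells <- function(region, lambda0_per_mm2, lambda1_per_mm2,
                                  decay_tau_um, class = "CD44+PTN+",
                                  seed = 1L) {
  set.seed(seed)
  pts <- rpoispp_mask(region, lambda0_per_mm2, lambda1_per_mm2,
                      decay_tau_um)
  flags <- class_to_flags(rep(class, nrow(pts)))
  new_cell_table(data.frame(
    cell_id = sprintf("CELL-%06d", seq_len(nrow(pts))),
    x_um = pts$x_um, y_um = pts$y_um,
    CD44_pos = flags$CD44_pos, PTN_pos = flags$PTN_pos,
    stringsAsFactors = FALSE))
}

# Poisson thinning on a rasterized region mask; lambda in cells/mm^2.
rpoispp_mask <- function(region, lambda0, lambda1, tau) {
  lam_max <- lambda0 + lambda1
  empty <- data.frame(x_um = numeric(), y_um = numeric())
  if (lam_max <= 0) return(empty)
  m <- region$mask
  area_mm2 <- sum(m$px) * (m$px_size_um / 1000)^2
  n0 <- rpois(1L, lam_max * area_mm2)
  if (n0 == 0L) return(empty)
  edt <- region_edt(region)
  nx <- ncol(m$px); ny <- nrow(m$px)
  # uniform points inside the mask by rejection over the raster bounding box
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n0) {
    k <- max(2L * (n0 - nrow(pts)), 32L)
    x <- runif(k, 0, nx * m$px_size_um) + m$origin_um[1]
    y <- runif(k, 0, ny * m$px_size_um) + m$origin_um[2]
    px <- mask_pixel_index(m, x, y)
    keep <- !is.na(px) & m$px[px]
    pts <- rbind(pts, cbind(x[keep], y[keep]))
  }
  pts <- pts[seq_len(n0), , drop = FALSE]
  d <- edt[mask_pixel_index(m, pts[, 1], pts[, 2])] * m$px_size_um
  p_keep <- (lambda0 + lambda1 * exp(-d / tau)) / lam_max
  keep <- runif(n0) < p_keep
  data.frame(x_um = pts[keep, 1], y_um = pts[keep, 2])
}

new_cell_table <- function(df) {
  if (anyDuplicated(df$cell_id)) abort("duplicate cell ids")
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    abort("non-finite cell coordinates")
  structure(df, class = c("cell_table", "data.frame"))
}

#' Simulate a complete synthetic section
#'
#' Convenience wrapper running \code{\link{generate_spot_grid}},
#' \code{\link{assign_compartments}}, \code{\link{simulate_counts}} and
#' \code{\link{simulate_cells}} on one config.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param cells if FALSE the (slower) cell point process is skipped.
#' @return list with grid, compartments, counts, cells and the config.
#' @export
simulate_section <- function(config, cells = TRUE) {
  grid <- generate_spot_grid(config)
  comp <- assign_compartments(grid, config)
  counts <- simulate_counts(grid, comp, config)
  cell_tab <- if (cells) simulate_cells(comp, grid, config) else NULL
  list(grid = grid, compartments = comp, counts = counts, cells = cell_tab,
       config = config)
}
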
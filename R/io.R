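#' Write a section in Visium-like layout
#'
#' Writes tissue_positions.csv (barcode, in_tissue, array_row, array_col,
#' pxl_x, pxl_y), matrix.mtx (Matrix Market, 1-based), features.tsv,
#' barcodes.tsv and a scalefactors.json sidecar holding the micrometer
#' scale, lattice type, pitch and spot diameter. Pixel columns mirror the
#' micrometer coordinates through the stored scale factor; the micrometer
#' values are authoritative on read.
#'
#' @param dir output directory (created if missing).
#' @param grid a \code{spot_grid}.
#' @param counts genes x spots sparse count matrix aligned to the grid.
#' @param um_per_px micrometers per pixel used for the pixel columns.
#' @return \code{dir}, invisibly.
#' @export
write_visium_like <- function(dir, grid, counts, um_per_px = 1) {
  stopifnot(identical(colnames(counts), grid$barcode))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- data.frame(barcode = grid$barcode, in_tissue = 1L,
                    array_row = grid$array_row, array_col = grid$array_col,
                    pxl_x = grid$x_um / um_per_px,
                    pxl_y = grid$y_um / um_per_px)
  write.csv(pos, file.path(dir, "tissue_positions.csv"), row.names = FALSE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  jsonlite::write_json(list(um_per_px = um_per_px,
                            lattice = grid_lattice(grid),
                            pitch_um = grid_pitch(grid),
                            spot_diameter_um = attr(grid, "spot_diameter_um")),
                       file.path(dir, "scalefactors.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a Visium-like section directory
#'
#' Expects tissue_positions.csv, matrix.mtx, features.tsv, barcodes.tsv and
#' scalefactors.json as written by \code{\link{write_visium_like}}. Spots
#' with in_tissue == 0 are dropped (count reported via a message). Barcodes
#' must align between the positions table and the matrix columns; the
#' matrix must be nonnegative with in-range 1-based indices.
#'
#' @param dir directory path.
#' @return list(grid = \code{spot_grid}, counts = sparse genes x spots
#'   matrix).
#' @export
read_visium_like <- function(dir) {
  need <- c("tissue_positions.csv", "matrix.mtx", "features.tsv",
            "barcodes.tsv", "scalefactors.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) abort("missing input file(s): ", paste(miss, collapse = ", "))
  pos <- read.csv(file.path(dir, "tissue_positions.csv"),
                  stringsAsFactors = FALSE)
  sf <- jsonlite::read_json(file.path(dir, "scalefactors.json"),
                            simplifyVector = TRUE)
  mtx <- tryCatch(Matrix::readMM(file.path(dir, "matrix.mtx")),
                  error = function(e)
                    abort("malformed Matrix Market file: ",
                          conditionMessage(e)))
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(mtx) != length(feats) || ncol(mtx) != length(bcs))
    abort("matrix dimensions disagree with features/barcodes files")
  vals <- if (methods::.hasSlot(mtx, "x")) mtx@x else numeric(0)
  if (any(vals < 0)) abort("count matrix contains negative entries")
  if (anyDuplicated(feats)) abort("duplicate gene ids in features.tsv")
  bad <- setdiff(pos$barcode, bcs)
  if (length(bad))
    abort("barcode mismatch between positions and matrix; first offender: ",
          bad[1])
  bad <- setdiff(bcs, pos$barcode)
  if (length(bad))
    abort("barcode mismatch between matrix and positions; first offender: ",
          bad[1])
  dimnames(mtx) <- list(feats, bcs)
  drop <- pos$barcode[pos$in_tissue == 0]
  if (length(drop))
    message(length(drop), " spot(s) with in_tissue == 0 dropped")
  pos <- pos[pos$in_tissue != 0, , drop = FALSE]
  mtx <- mtx[, pos$barcode, drop = FALSE]
  grid <- new_spot_grid(
    data.frame(barcode = pos$barcode, array_row = pos$array_row,
               array_col = pos$array_col,
               x_um = pos$pxl_x * sf$um_per_px,
               y_um = pos$pxl_y * sf$um_per_px, stringsAsFactors = FALSE),
    sf$lattice, sf$pitch_um, sf$spot_diameter_um)
  mtx <- methods::as(methods::as(mtx, "generalMatrix"), "CsparseMatrix")
  list(grid = grid, counts = mtx)
}

#' Read per-spot compartment annotations
#'
#' Tab-separated file with columns barcode, compartment and optionally
#' zone. Every barcode of the grid must be annotated exactly once, the
#' compartment must be one of the five tissue labels and zones must match
#' their compartment (T* on tumor, G* on normal_gland).
#'
#' @param path TSV path.
#' @param grid the section's \code{spot_grid}.
#' @return a \code{compartment_map} ordered like the grid.
#' @export
read_annotations <- function(path, grid) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "compartment") %in% names(df)))
    abort("annotation file needs columns barcode and compartment")
  if (!"zone" %in% names(df)) df$zone <- NA_character_
  df$zone[df$zone %in% c("", "NA")] <- NA_character_
  miss <- setdiff(grid$barcode, df$barcode)
  if (length(miss))
    abort("annotation missing for barcode(s), first: ", miss[1])
  if (anyDuplicated(df$barcode)) abort("duplicated barcode in annotations")
  df <- df[match(grid$barcode, df$barcode),
           c("barcode", "compartment", "zone")]
  new_compartment_map(df)
}

#' Write compartment annotations
#' @param comp a \code{compartment_map}.
#' @param path output TSV path.
#' @export
write_annotations <- function(comp, path) {
  write.table(as.data.frame(comp), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cell-centroid table
#'
#' CSV with columns cell_id, x_um, y_um, class where class is one of
#' "CD44+", "PTN+", "CD44+PTN+". Marker flags are derived from the class.
#'
#' @param path CSV path.
#' @return a \code{cell_table}.
#' @export
read_cells <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "x_um", "y_um", "class")
  if (!all(need %in% names(df)))
    abort("cells file needs columns ", paste(need, collapse = ", "))
  flags <- class_to_flags(df$class)
  new_cell_table(data.frame(cell_id = df$cell_id, x_um = df$x_um,
                            y_um = df$y_um, CD44_pos = flags$CD44_pos,
                            PTN_pos = flags$PTN_pos,
                            stringsAsFactors = FALSE))
}

#' Write a cell-centroid table
#' @param cells a \code{cell_table}.
#' @param path output CSV path; coordinates printed with 6 decimals.
#' @export
write_cells <- function(cells, path) {
  out <- data.frame(cell_id = cells$cell_id,
                    x_um = round(cells$x_um, 6),
                    y_um = round(cells$y_um, 6),
                    class = flags_to_class(cells$CD44_pos, cells$PTN_pos))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-signature library
#'
#' Two-column TSV (name, gene), one gene per row; a signature with no genes
#' is rejected. Matching against a count matrix is case-sensitive unless
#' \code{ignore_case} is set at scoring time by the caller.
#'
#' @param path TSV path.
#' @return named list of character vectors.
#' @export
read_signatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "gene") %in% names(df)))
    abort("signature file needs columns name and gene")
  df <- df[df$gene != "" & !is.na(df$gene), , drop = FALSE]
  sets <- split(df$gene, df$name)
  if (!length(sets) || any(!lengths(sets)))
    abort("signature file contains an empty gene set")
  lapply(sets, unique)
}

#' Write a gene-signature library
#' @param library named list of gene id vectors.
#' @param path output TSV path.
#' @export
write_signatures <- function(library, path) {
  df <- data.frame(name = rep(names(library), lengths(library)),
                   gene = unlist(library, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an edge-distance field
#' @param field an \code{edge_distance_field}.
#' @param path output TSV path (subject_id, region_id, distance_um).
#' @export
write_distances <- function(field, path) {
  write.table(as.data.frame(field), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an edge-distance field written by \code{\link{write_distances}}
#' @param path TSV path.
#' @param subject "spots" or "cells".
#' @return an \code{edge_distance_field}.
#' @export
read_distances <- function(path, subject = c("spots", "cells")) {
  subject <- match.arg(subject)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "region_id", "distance_um")
  if (!all(need %in% names(df)))
    abort("distances file needs columns ", paste(need, collapse = ", "))
  new_edge_field(df[, need], subject)
}

#' Write a density profile
#' @param profile a \code{density_profile}.
#' @param path output CSV path.
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a density profile written by \code{\link{write_profile}}
#' @param path CSV path.
#' @return a \code{density_profile}.
#' @export
read_profile <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  bw <- unique(df$bin_hi - df$bin_lo)
  structure(df, class = c("density_profile", "data.frame"),
            bin_width_um = bw[1], region_id = "file")
}

#' Write niche calls as a long TSV
#' @param calls list of \code{niche_call}s.
#' @param path output TSV (section, marker, barcode).
#' @export
write_niches <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(cl)
    data.frame(section = cl$section_id, marker = cl$marker,
               barcode = cl$members, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
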
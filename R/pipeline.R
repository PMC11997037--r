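#' Load and validate a pipeline run configuration
#'
#' YAML file with the blocks: \code{out_dir} (run directory), \code{seed}
#' (master seed), \code{synthetic} (overrides passed to
#' \code{\link{synthetic_config}}), \code{niche} (markers, q, scope),
#' \code{populations} (signatures file path or "builtin"), \code{profile}
#' (bin_width_um, superset) and \code{enrich} (n_perm). Unknown keys are
#' rejected; after resolution every stochastic stage has an explicit seed.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated config list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    out_dir = "edgeniche_run", seed = 1L,
    synthetic = list(),
    niche = list(markers = c("CD44", "Lgr5", "Alcam", "Aldh2", "Prom1"),
                 q = 0.10, scope = "all_spots"),
    populations = list(signatures = "builtin", q = 0.10, top_frac = 0.05),
    profile = list(bin_width_um = 50, superset = FALSE),
    enrich = list(n_perm = 1000))
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) abort("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in c("niche", "populations", "profile", "enrich")) {
    bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(bad))
      abort("unknown config key(s) in '", blk, "': ",
            paste(bad, collapse = ", "))
    defaults[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  }
  for (k in c("out_dir", "seed", "synthetic"))
    if (!is.null(cfg[[k]])) defaults[[k]] <- cfg[[k]]
  defaults$seed <- as.integer(defaults$seed)
  defaults
}

builtin_population_signatures <- function() {
  list(Fib_C8_iCAF = c("Col1a1", "Il11"),
       Fib_C11_myCAF = c("Pdgfrb", "Acta2"),
       Neu_C12_TAN = c("Ly6g", "Cd101"))
}

manifest_add <- function(out_dir, stage, info) {
  path <- file.path(out_dir, "run_manifest.json")
  man <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  man[[length(man) + 1L]] <- c(list(stage = stage,
                                    package_version =
                                      as.character(utils::packageVersion("edgeniche"))),
                               info)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

need_upstream <- function(out_dir, files, stage) {
  miss <- files[!file.exists(file.path(out_dir, files))]
  if (length(miss))
    abort("stage '", stage, "' is missing upstream file(s): ",
          paste(miss, collapse = ", "))
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic section to disk), \code{call-niches},
#' \code{map-populations}, \code{edge-distance}, \code{profile},
#' \code{enrich} and \code{report}; \code{all} chains them in order. Each
#' stage reads only the files its upstream stages wrote under the run
#' directory, writes its documented outputs and appends to the run
#' manifest.
#'
#' @param stage stage name (see above).
#' @param cfg config from \code{\link{run_config}} (or a path to one).
#' @return invisibly, the run directory.
#' @export
run_stage <- function(stage, cfg) {
  if (is.character(cfg)) cfg <- run_config(cfg)
  stages <- c("simulate", "call-niches", "map-populations", "edge-distance",
              "profile", "enrich", "report")
  if (identical(stage, "all")) {
    for (s in stages) run_stage(s, cfg)
    return(invisible(cfg$out_dir))
  }
  if (!stage %in% stages) abort("unknown stage '", stage, "'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         "simulate" = stage_simulate(cfg),
         "call-niches" = stage_call_niches(cfg),
         "map-populations" = stage_map_populations(cfg),
         "edge-distance" = stage_edge_distance(cfg),
         "profile" = stage_profile(cfg),
         "enrich" = stage_enrich(cfg),
         "report" = stage_report(cfg))
  invisible(cfg$out_dir)
}

stage_simulate <- function(cfg) {
  sc <- do.call(synthetic_config, c(list(seed = cfg$seed), cfg$synthetic))
  sec <- simulate_section(sc)
  write_visium_like(file.path(cfg$out_dir, "section"), sec$grid, sec$counts)
  write_annotations(sec$compartments,
                    file.path(cfg$out_dir, "annotations.tsv"))
  write_cells(sec$cells, file.path(cfg$out_dir, "cells.csv"))
  truth <- sc[c("seed", "lattice", "pitch_um", "spot_diameter_um",
                "tumor_radius_um", "zone_edges_um", "nb_dispersion")]
  truth$gradient_genes <- sc$gradient_genes
  truth$cell_classes <- sc$cell_classes
  jsonlite::write_json(truth, file.path(cfg$out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest_add(cfg$out_dir, "simulate", list(seed = cfg$seed))
}

load_section <- function(cfg, stage) {
  need_upstream(cfg$out_dir, c("section/matrix.mtx", "annotations.tsv"),
                stage)
  sec <- read_visium_like(file.path(cfg$out_dir, "section"))
  sec$compartments <- read_annotations(file.path(cfg$out_dir,
                                                 "annotations.tsv"),
                                       sec$grid)
  sec
}

stage_call_niches <- function(cfg) {
  sec <- load_section(cfg, "call-niches")
  calls <- lapply(cfg$niche$markers, function(m)
    call_marker_niches(sec$counts, sec$compartments, m, q = cfg$niche$q,
                       scope = cfg$niche$scope, section_id = "section"))
  write_niches(calls, file.path(cfg$out_dir, "niches.tsv"))
  ov <- overlap_summary(calls)
  jsonlite::write_json(list(exact_regions = as.list(ov$exact_regions)),
                       file.path(cfg$out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  comp_tab <- lapply(calls, niche_composition, comp = sec$compartments)
  names(comp_tab) <- cfg$niche$markers
  jsonlite::write_json(comp_tab, file.path(cfg$out_dir, "composition.json"),
                       digits = NA, pretty = TRUE)
  manifest_add(cfg$out_dir, "call-niches",
               list(markers = cfg$niche$markers, q = cfg$niche$q,
                    scope = cfg$niche$scope))
}

stage_map_populations <- function(cfg) {
  sec <- load_section(cfg, "map-populations")
  lib <- if (identical(cfg$populations$signatures, "builtin"))
    builtin_population_signatures()
  else read_signatures(cfg$populations$signatures)
  maps <- population_signature_map(sec$counts, sec$compartments, lib,
                                   q = cfg$populations$q,
                                   top_frac = cfg$populations$top_frac)
  df <- do.call(rbind, lapply(names(maps), function(p)
    data.frame(population = p, barcode = maps[[p]]$members,
               stringsAsFactors = FALSE)))
  write.table(df, file.path(cfg$out_dir, "populations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest_add(cfg$out_dir, "map-populations",
               list(populations = names(maps), q = cfg$populations$q))
}

pipeline_regions <- function(sec) {
  adj <- build_adjacency(sec$grid)
  extract_tumor_regions(sec$compartments, adj, sec$grid)
}

stage_edge_distance <- function(cfg) {
  sec <- load_section(cfg, "edge-distance")
  need_upstream(cfg$out_dir, "cells.csv", "edge-distance")
  cells <- read_cells(file.path(cfg$out_dir, "cells.csv"))
  regions <- pipeline_regions(sec)
  spot_f <- do.call(rbind, lapply(regions, spot_edge_distance,
                                  grid = sec$grid))
  cell_f <- do.call(rbind, lapply(regions, cell_edge_distance,
                                  cells = cells))
  write_distances(new_edge_field(spot_f, "spots"),
                  file.path(cfg$out_dir, "distances_spots.tsv"))
  write_distances(new_edge_field(cell_f, "cells"),
                  file.path(cfg$out_dir, "distances_cells.tsv"))
  manifest_add(cfg$out_dir, "edge-distance",
               list(n_regions = length(regions)))
}

stage_profile <- function(cfg) {
  sec <- load_section(cfg, "profile")
  need_upstream(cfg$out_dir, c("cells.csv", "distances_cells.tsv"),
                "profile")
  cells <- read_cells(file.path(cfg$out_dir, "cells.csv"))
  field <- read_distances(file.path(cfg$out_dir, "distances_cells.tsv"),
                          "cells")
  regions <- pipeline_regions(sec)
  profs <- lapply(regions, function(rg) {
    f <- field[field$region_id == rg$region_id, , drop = FALSE]
    shell_profile(new_edge_field(f, "cells"), rg, cells,
                  bin_width_um = cfg$profile$bin_width_um,
                  superset = cfg$profile$superset)
  })
  pooled <- pool_profiles(profs)
  write_profile(pooled, file.path(cfg$out_dir, "profile.csv"))
  manifest_add(cfg$out_dir, "profile",
               list(bin_width_um = cfg$profile$bin_width_um))
}

stage_enrich <- function(cfg) {
  need_upstream(cfg$out_dir,
                c("niches.tsv", "distances_spots.tsv", "profile.csv"),
                "enrich")
  niches <- read.delim(file.path(cfg$out_dir, "niches.tsv"),
                       stringsAsFactors = FALSE)
  field <- read_distances(file.path(cfg$out_dir, "distances_spots.tsv"),
                          "spots")
  profile <- read_profile(file.path(cfg$out_dir, "profile.csv"))
  n_perm <- cfg$enrich$n_perm
  edge <- list()
  for (m in unique(niches$marker)) {
    S <- intersect(niches$barcode[niches$marker == m], field$subject_id)
    if (length(S) < 2L) next
    r <- edge_enrichment_test(S, field, n_perm = n_perm,
                              seed = child_seed(cfg$seed, 10L))
    edge[[m]] <- list(n_spots = length(S), observed_mean_um = r$observed_stat,
                      null_mean_um = r$null_mean, p_value = r$p_value)
  }
  ps <- vapply(edge, `[[`, numeric(1), "p_value")
  qs <- bh_adjust(ps)
  for (i in seq_along(edge)) edge[[i]]$q_bh <- qs[[i]]
  trend <- list()
  for (cl in unique(profile$class)) {
    nonzero <- sum(profile$count[profile$class == cl]) > 0
    if (!nonzero || sum(profile$class == cl) < 4L) next
    r <- density_trend_test(profile, class = cl, n_perm = n_perm,
                            seed = child_seed(cfg$seed, 11L))
    trend[[cl]] <- list(spearman_rho = r$spearman_rho,
                        p_value = r$test$p_value)
  }
  jsonlite::write_json(
    list(seed = cfg$seed, n_perm = n_perm,
         edge_enrichment = edge, density_trend = trend),
    file.path(cfg$out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest_add(cfg$out_dir, "enrich", list(n_perm = n_perm,
                                           seed = cfg$seed))
}

stage_report <- function(cfg) {
  need_upstream(cfg$out_dir, "stats.json", "report")
  st <- jsonlite::read_json(file.path(cfg$out_dir, "stats.json"),
                            simplifyVector = TRUE)
  lines <- c("edgeniche run summary", "=====================", "",
             sprintf("seed: %d   permutations: %d", st$seed, st$n_perm), "",
             "Edge enrichment of marker niches (mean distance to edge):")
  for (m in names(st$edge_enrichment)) {
    e <- st$edge_enrichment[[m]]
    lines <- c(lines, sprintf(
      "  %-6s n=%3d  observed %7.1f um  null %7.1f um  p=%.4g  q=%.4g",
      m, e$n_spots, e$observed_mean_um, e$null_mean_um, e$p_value, e$q_bh))
  }
  lines <- c(lines, "", "Center-to-edge density trend (Spearman rho):")
  for (cl in names(st$density_trend)) {
    t <- st$density_trend[[cl]]
    lines <- c(lines, sprintf("  %-10s rho=%6.3f  p=%.4g", cl,
                              t$spearman_rho, t$p_value))
  }
  writeLines(lines, file.path(cfg$out_dir, "report.txt"))
  manifest_add(cfg$out_dir, "report", list())
}

#' Command-line entry point
#'
#' Dispatches \code{edgeniche <stage> --config <file.yaml>}; used by the
#' thin Rscript shipped in \code{inst/cli}. Returns 0 on success and
#' signals a condition otherwise.
#'
#' @param args character vector, typically \code{commandArgs(TRUE)}.
#' @return exit status, invisibly.
#' @export
en_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    abort("usage: edgeniche <simulate|call-niches|map-populations|",
          "edge-distance|profile|enrich|report|all> --config <file>")
  stage <- args[[1]]
  ci <- which(args == "--config")
  if (!length(ci) || ci + 1L > length(args))
    abort("--config <file> is required")
  cfg <- run_config(args[[ci + 1L]])
  run_stage(stage, cfg)
  invisible(0L)
}
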
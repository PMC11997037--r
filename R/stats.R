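#' Odds ratio of a 2x2 contingency table
#'
#' OR = (a*d)/(b*c) with a Woolf (log-scale normal) 95% confidence interval.
#' When any cell is zero and \code{haldane = TRUE}, 0.5 is added to every
#' cell (Haldane-Anscombe correction) and the result is flagged. A Fisher
#' exact p-value on the uncorrected table accompanies the estimate.
#'
#' @param a,b,c,d cell counts: a = in-cluster & tumor, b = in-cluster &
#'   normal, c = out-cluster & tumor, d = out-cluster & normal.
#' @param haldane apply the 0.5 correction when a zero cell is present.
#' @return list(or, log_or, se_log_or, ci95_lo, ci95_hi, p_fisher,
#'   correction_applied).
#' @export
odds_ratio <- function(a, b, c, d, haldane = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    abort("contingency cells must be nonnegative integers")
  if (sum(cells) == 0) abort("all-zero contingency table")
  p_fisher <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane) abort("zero cell without Haldane correction")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = or, log_or = log(or), se_log_or = se,
       ci95_lo = exp(log(or) - 1.96 * se),
       ci95_hi = exp(log(or) + 1.96 * se),
       p_fisher = p_fisher, correction_applied = corrected)
}

#' Per-cluster odds ratios of occurrence in tumor vs normal
#'
#' For each cluster, builds the 2x2 table of that cluster vs all others
#' against the tumor/normal condition, computes the odds ratio (with
#' Haldane-Anscombe correction where needed) and Fisher p-value, and adjusts
#' p-values across clusters by Benjamini-Hochberg.
#'
#' @param cluster factor/character vector of per-cell cluster labels.
#' @param condition per-cell condition, values "tumor" and "normal".
#' @param haldane passed to \code{\link{odds_ratio}}.
#' @return data.frame (cluster, a, b, c, d, or, ci95_lo, ci95_hi, p_fisher,
#'   q_bh, correction_applied) ordered by cluster.
#' @export
population_or_table <- function(cluster, condition, haldane = TRUE) {
  stopifnot(length(cluster) == length(condition))
  if (!all(condition %in% c("tumor", "normal")))
    abort("condition values must be 'tumor' or 'normal'")
  if (length(unique(condition)) < 2L)
    abort("both conditions must be present")
  cl <- sort(unique(as.character(cluster)))
  if (length(cl) < 2L) abort("need at least two clusters")
  rows <- lapply(cl, function(k) {
    a <- sum(cluster == k & condition == "tumor")
    b <- sum(cluster == k & condition == "normal")
    cc <- sum(cluster != k & condition == "tumor")
    d <- sum(cluster != k & condition == "normal")
    res <- odds_ratio(a, b, cc, d, haldane = haldane)
    data.frame(cluster = k, a = a, b = b, c = cc, d = d, or = res$or,
               ci95_lo = res$ci95_lo, ci95_hi = res$ci95_hi,
               p_fisher = res$p_fisher,
               correction_applied = res$correction_applied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_fisher)
  out
}

new_perm_result <- function(observed, null, n_perm, p, direction, seed) {
  structure(list(observed_stat = observed, n_perm = n_perm,
                 null_mean = mean(null), null_sd = sd(null),
                 p_value = p, direction = direction, seed = seed),
            class = "permutation_test")
}

#' Permutation test for edge enrichment of a spot set
#'
#' Tests whether a spot set sits closer to the tumor boundary than a random
#' set of the same size: the statistic is the mean distance-to-edge of the
#' set, and the null draws size-|S| subsets of the field's subjects without
#' replacement. The one-sided p-value (direction "closer") is
#' \code{(1 + #(null <= observed)) / (1 + n_perm)}.
#'
#' @param spots character vector of member barcodes (subset of the field).
#' @param field a spot \code{edge_distance_field}.
#' @param n_perm number of permutations.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param direction "closer" (default) or "farther" from the edge.
#' @return a \code{permutation_test} result.
#' @export
edge_enrichment_test <- function(spots, field, n_perm = 1000, seed = 1L,
                                 direction = c("closer", "farther")) {
  direction <- match.arg(direction)
  idx <- match(spots, field$subject_id)
  if (anyNA(idx)) abort("spot set contains barcodes outside the field")
  if (length(idx) < 2L) abort("spot set must contain at least 2 spots")
  d <- field$distance_um
  obs <- mean(d[idx])
  if (length(idx) == length(d)) {
    warning("spot set covers the whole field; test is degenerate",
            call. = FALSE)
    return(new_perm_result(obs, rep(obs, n_perm), n_perm, 1, direction, seed))
  }
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    mean(d[sample.int(length(d), length(idx))]), numeric(1))
  extreme <- if (direction == "closer") sum(null <= obs) else sum(null >= obs)
  p <- (1 + extreme) / (1 + n_perm)
  new_perm_result(obs, null, n_perm, p, direction, seed)
}

#' Monotone trend test on a shell density profile
#'
#' Computes the Spearman correlation between shell midpoint distance and
#' density for one cell class, and a permutation p-value under complete
#' spatial randomness: the class's cells are redistributed over the shells
#' with probabilities proportional to shell area (a multinomial draw),
#' densities recomputed and the correlation re-evaluated. The default
#' one-sided direction "decreasing" asks whether density falls with distance
#' from the edge, i.e. rises toward the tumor boundary.
#'
#' @param profile a \code{density_profile}.
#' @param class one of "CD44+", "PTN+", "CD44+PTN+".
#' @param n_perm,seed permutation parameters.
#' @param direction "decreasing" (default) or "increasing" density with
#'   distance from the edge.
#' @return list(spearman_rho, test = \code{permutation_test}).
#' @export
density_trend_test <- function(profile, class = "CD44+PTN+", n_perm = 1000,
                               seed = 1L,
                               direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  pr <- profile[profile$class == class, , drop = FALSE]
  if (nrow(pr) < 4L) abort("insufficient shells: need at least 4 bins")
  rho <- suppressWarnings(
    cor(pr$bin_mid, pr$density_per_mm2, method = "spearman"))
  n_cells <- sum(pr$count)
  set.seed(seed)
  prob <- pr$area_mm2 / sum(pr$area_mm2)
  draws <- rmultinom(n_perm, n_cells, prob)
  null <- apply(draws, 2, function(cnt)
    suppressWarnings(cor(pr$bin_mid, cnt / pr$area_mm2,
                         method = "spearman")))
  null[is.na(null)] <- 0
  obs <- if (is.na(rho)) 0 else rho
  extreme <- if (direction == "decreasing") sum(null <= obs)
             else sum(null >= obs)
  p <- (1 + extreme) / (1 + n_perm)
  list(spearman_rho = rho,
       test = new_perm_result(obs, null, n_perm, p, direction, seed))
}

#' Permutation test of spatial proximity between two spot sets
#'
#' The statistic is the mean, over spots of set A, of the Euclidean distance
#' to the nearest spot of set B. The null resamples A-sized sets from a
#' scope of candidate spots (default: all spots of the grid) and the
#' one-sided p asks whether A lies closer to B than chance.
#'
#' @param A,B character barcode vectors; B must be nonempty.
#' @param grid a \code{spot_grid}.
#' @param scope candidate barcodes resampled under the null; defaults to
#'   all grid barcodes.
#' @param n_perm,seed permutation parameters.
#' @return a \code{permutation_test} result.
#' @export
proximity_test <- function(A, B, grid, scope = NULL, n_perm = 1000,
                           seed = 1L) {
  if (!length(B)) abort("set B is empty")
  if (!length(A)) abort("set A is empty")
  scope <- scope %||% grid$barcode
  ia <- match(A, grid$barcode); ib <- match(B, grid$barcode)
  is <- match(scope, grid$barcode)
  if (anyNA(ia) || anyNA(ib) || anyNA(is))
    abort("barcodes missing from the grid")
  nn_mean <- function(idx) {
    dx <- outer(grid$x_um[idx], grid$x_um[ib], "-")
    dy <- outer(grid$y_um[idx], grid$y_um[ib], "-")
    mean(sqrt(apply(dx * dx + dy * dy, 1, min)))
  }
  obs <- nn_mean(ia)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    nn_mean(sample(is, length(ia))), numeric(1))
  p <- (1 + sum(null <= obs)) / (1 + n_perm)
  new_perm_result(obs, null, n_perm, p, "closer", seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, named wrapper around
#' \code{p.adjust(method = "BH")} so the pipeline's multiple-testing policy
#' has a single entry point.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1 | is.na(p))) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}
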
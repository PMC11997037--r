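#' Call top-quantile marker niches
#'
#' Ranks spots by the expression of one marker gene (descending, ties broken
#' by barcode ascending so the call is deterministic) and returns the top
#' \code{ceiling(q * N)} spots — the "top 10 percent" niche definition used
#' for cancer-stem-cell markers. The ranked scope is either every spot of
#' the section or only tumor-annotated spots.
#'
#' @param counts genes x spots matrix (raw counts or any monotone transform;
#'   the call is rank-based and therefore scale-invariant).
#' @param comp \code{compartment_map}; required for \code{scope = "tumor_only"}.
#' @param marker gene id present in \code{counts}.
#' @param q quantile in (0, 1); default 0.10.
#' @param scope "all_spots" or "tumor_only".
#' @param section_id identifier carried into the result.
#' @return a \code{niche_call}: list(section_id, marker, q, scope, members).
#' @export
call_marker_niches <- function(counts, comp = NULL, marker, q = 0.10,
                               scope = c("all_spots", "tumor_only"),
                               section_id = "section") {
  scope <- match.arg(scope)
  if (!marker %in% rownames(counts))
    abort("marker '", marker, "' absent from the count matrix")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    abort("q must lie in (0, 1)")
  bc <- colnames(counts)
  if (scope == "tumor_only") {
    if (is.null(comp)) abort("tumor_only scope requires a compartment map")
    bc <- intersect(bc, comp$barcode[comp$compartment == "tumor"])
  }
  expr <- counts[marker, bc]
  ord <- order(-as.numeric(expr), bc)
  n_top <- ceiling(q * length(bc))
  structure(list(section_id = section_id, marker = marker, q = q,
                 scope = scope, members = bc[ord[seq_len(n_top)]]),
            class = "niche_call")
}

#' Overlap summary of marker niches
#'
#' Exact inclusion-exclusion region counts (number of spots in exactly each
#' nonempty marker subset) and the pairwise Jaccard matrix, as shown in Venn
#' diagrams of CSC-marker niches.
#'
#' @param calls list of \code{niche_call}s from the same section.
#' @return list(exact_regions = named counts keyed by "A&B"-style subset
#'   labels, jaccard = symmetric matrix).
#' @export
overlap_summary <- function(calls) {
  stopifnot(length(calls) >= 1L)
  secs <- unique(vapply(calls, `[[`, character(1), "section_id"))
  if (length(secs) != 1L) abort("niche calls come from mixed sections")
  markers <- vapply(calls, `[[`, character(1), "marker")
  sets <- lapply(calls, `[[`, "members")
  names(sets) <- markers
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L,
                                         dimnames = list(NULL, markers))
  pat <- apply(memb, 1, function(r) paste(markers[r], collapse = "&"))
  exact <- table(pat)
  jac <- matrix(1, length(sets), length(sets),
                dimnames = list(markers, markers))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) {
      v <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- jac[j, i] <- v
    }
  }
  list(exact_regions = setNames(as.integer(exact), names(exact)),
       jaccard = jac)
}

#' Zonal composition of a niche
#'
#' Fraction of niche member spots falling in each tumor zone T1..T5, with a
#' non_tumor bucket for members outside the tumor compartment. Fractions
#' sum to one.
#'
#' @param call a \code{niche_call}.
#' @param comp a \code{compartment_map} with tumor zones annotated.
#' @return named numeric vector over T1..T5 and non_tumor.
#' @export
niche_composition <- function(call, comp) {
  idx <- match(call$members, comp$barcode)
  if (anyNA(idx)) abort("niche members missing from the compartment map")
  zone <- comp$zone[idx]
  zone[comp$compartment[idx] != "tumor" | is.na(zone)] <- "non_tumor"
  tab <- table(factor(zone, levels = c(TUMOR_ZONES, "non_tumor")))
  setNames(as.numeric(tab) / length(call$members), names(tab))
}

#' Rank-recovery (AUC) gene-set score per spot
#'
#' For each spot, genes are ranked by expression (descending, ties broken by
#' gene id ascending) and the recovery curve counts cumulative signature
#' hits over the top \code{floor(top_frac * G)} ranks. The score is the area
#' under that step curve normalized by the maximal achievable area (all
#' recoverable signature genes at the very top), so it lies in [0, 1] and is
#' invariant under any strictly monotone transform of a spot's profile.
#'
#' @param counts genes x spots matrix.
#' @param signature character vector of gene ids; genes absent from the
#'   matrix are dropped with a warning, an entirely absent set is an error.
#' @param top_frac fraction of the ranking examined (default 0.05).
#' @param signature_name label carried into the score table.
#' @return a \code{score_table} data.frame (barcode, signature, score,
#'   method) with the parameters as attributes.
#' @export
auc_score <- function(counts, signature, top_frac = 0.05,
                      signature_name = "signature") {
  present <- intersect(signature, rownames(counts))
  if (!length(present))
    abort("signature '", signature_name, "' shares no genes with the matrix")
  if (length(present) < length(signature))
    warning(length(signature) - length(present),
            " signature gene(s) absent from the matrix", call. = FALSE)
  G <- nrow(counts)
  n_top <- max(1L, floor(top_frac * G))
  gene_ord_key <- rownames(counts)
  m <- min(length(present), n_top)
  max_area <- sum(pmin(seq_len(n_top), m))
  scores <- vapply(seq_len(ncol(counts)), function(j) {
    expr <- as.numeric(counts[, j])
    ord <- order(-expr, gene_ord_key)
    hit <- gene_ord_key[ord[seq_len(n_top)]] %in% present
    sum(cumsum(hit)) / max_area
  }, numeric(1))
  new_score_table(colnames(counts), signature_name, scores, "auc",
                  list(top_frac = top_frac))
}

new_score_table <- function(barcodes, signature, score, method, params) {
  structure(data.frame(barcode = barcodes, signature = signature,
                       score = score, method = method,
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"), params = params)
}

#' Background-corrected module (stemness) score per spot
#'
#' Expression-bin-matched control scoring: genes are binned into
#' \code{n_bins} by mean log1p counts-per-10k expression across spots; for
#' every signature gene, \code{n_ctrl} control genes are drawn from its bin
#' without replacement (with replacement, with a warning, when the bin is
#' too small — a bin of size one makes a gene its own control and the score
#' collapses to zero, which is the intended degenerate behavior). The score
#' is mean signature expression minus mean control expression.
#'
#' @param counts genes x spots raw count matrix (normalized internally), or
#'   a pre-normalized matrix with \code{normalize = FALSE}.
#' @param signature character vector of gene ids.
#' @param n_bins,n_ctrl binning and control-set parameters.
#' @param seed RNG seed for the control draw.
#' @param normalize apply \code{\link{normalize_log1p_cp10k}} first.
#' @param signature_name label carried into the score table.
#' @return a \code{score_table} with method "module".
#' @export
module_score <- function(counts, signature, n_bins = 25, n_ctrl = 50,
                         seed = 1L, normalize = TRUE,
                         signature_name = "signature") {
  present <- intersect(signature, rownames(counts))
  if (!length(present))
    abort("signature '", signature_name, "' shares no genes with the matrix")
  if (length(present) < length(signature))
    warning(length(signature) - length(present),
            " signature gene(s) absent from the matrix", call. = FALSE)
  x <- if (normalize) normalize_log1p_cp10k(counts) else counts
  gene_mean <- Matrix::rowMeans(x)
  br <- unique(quantile(gene_mean, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(gene_mean, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(x)
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    pool <- names(bin)[bin == bin[g]]
    if (length(pool) < n_ctrl) {
      warning("bin of gene '", g, "' has fewer than n_ctrl genes; ",
              "sampling with replacement", call. = FALSE)
      ctrl <- c(ctrl, sample(pool, n_ctrl, replace = TRUE))
    } else {
      ctrl <- c(ctrl, sample(pool, n_ctrl, replace = FALSE))
    }
  }
  sig_mean <- Matrix::colMeans(x[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(x[ctrl, , drop = FALSE])
  new_score_table(colnames(x), signature_name,
                  as.numeric(sig_mean - ctrl_mean), "module",
                  list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed))
}

#' Map cell-population signatures onto spots
#'
#' Scores each population signature per spot with \code{\link{auc_score}}
#' and calls the top-quantile spots of each score (ties broken by barcode),
#' yielding one high-spot set per population — the signature-based analogue
#' of projecting single-cell clusters onto the spot lattice.
#'
#' @param counts genes x spots matrix.
#' @param comp optional \code{compartment_map} for \code{scope = "tumor_only"}.
#' @param library named list of signatures (\code{\link{read_signatures}}).
#' @param q top quantile called per population.
#' @param top_frac passed to \code{\link{auc_score}}.
#' @param scope ranked scope as in \code{\link{call_marker_niches}}.
#' @return named list: population -> list(members, scores = score_table).
#' @export
population_signature_map <- function(counts, comp = NULL, library, q = 0.10,
                                     top_frac = 0.05,
                                     scope = c("all_spots", "tumor_only")) {
  scope <- match.arg(scope)
  if (!length(library)) abort("signature library is empty")
  out <- list()
  for (pop in names(library)) {
    st <- auc_score(counts, library[[pop]], top_frac = top_frac,
                    signature_name = pop)
    bc <- st$barcode
    if (scope == "tumor_only") {
      if (is.null(comp)) abort("tumor_only scope requires a compartment map")
      keep <- bc %in% comp$barcode[comp$compartment == "tumor"]
      st <- st[keep, , drop = FALSE]; bc <- bc[keep]
    }
    ord <- order(-st$score, bc)
    n_top <- ceiling(q * length(bc))
    out[[pop]] <- list(members = bc[ord[seq_len(n_top)]], scores = st)
  }
  out
}
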
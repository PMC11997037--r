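#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

COMPARTMENTS <- c("normal_gland", "tumor", "muscularis", "submucosa",
                  "lymphoid_follicle")
TUMOR_ZONES <- paste0("T", 1:5)
GLAND_ZONES <- paste0("G", 1:4)

abort <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    abort(sprintf("'%s' must be positive", name))
  invisible(x)
}

#' Library-size normalize counts to log1p counts-per-10k
#'
#' Divides each spot column by its total count, scales to 10,000 and applies
#' \code{log1p}. Spots with zero total counts are left at zero.
#'
#' @param counts genes x spots matrix (dense or \code{Matrix} sparse).
#' @return matrix of the same class and dimnames with normalized values.
#' @export
normalize_log1p_cp10k <- function(counts) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = 1e4 / tot)
  dimnames(out) <- dimnames(counts)
  log1p(out)
}

#' Derive a child RNG seed from a master seed
#'
#' Fixed-offset substreams so that enabling one stochastic artifact never
#' shifts another. Kept below 2^31 - 1.
#' @keywords internal
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

# cell class labels used in tables on disk
CELL_CLASSES <- c("CD44+", "PTN+", "CD44+PTN+")

class_to_flags <- function(class) {
  if (!all(class %in% CELL_CLASSES))
    abort("unknown cell class; allowed: ", paste(CELL_CLASSES, collapse = ", "))
  data.frame(CD44_pos = class %in% c("CD44+", "CD44+PTN+"),
             PTN_pos  = class %in% c("PTN+", "CD44+PTN+"))
}

flags_to_class <- function(cd44, ptn) {
  ifelse(cd44 & ptn, "CD44+PTN+", ifelse(cd44, "CD44+", ifelse(ptn, "PTN+", "neg")))
}
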
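# small deterministic count fixture: genes x spots with controllable values
toy_counts <- function(values, genes = NULL, barcodes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- barcodes %||% sprintf("S%03d", seq_len(ncol(m)))
  m
}

test_that("top-quantile calls select exactly ceil(q*N) top spots", {
  set.seed(1)
  n <- 1000
  expr <- sample(seq_len(5 * n), n)  # distinct values
  counts <- toy_counts(matrix(expr, nrow = 1), genes = "CD44")
  call <- call_marker_niches(counts, marker = "CD44", q = 0.10)
  expect_length(call$members, 100L)
  inside <- expr[match(call$members, colnames(counts))]
  outside <- expr[!colnames(counts) %in% call$members]
  expect_true(min(inside) > max(outside))
})

test_that("ties resolve to lexicographically first barcodes", {
  counts <- toy_counts(matrix(5, nrow = 1, ncol = 10), genes = "CD44")
  call <- call_marker_niches(counts, marker = "CD44", q = 0.25)
  expect_equal(call$members, sort(colnames(counts))[1:3])  # ceil(2.5) = 3
})

test_that("niche calls agree with the sort-and-slice oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(50:300, 1)
    expr <- rpois(n, 5)  # plenty of ties
    counts <- toy_counts(matrix(expr, nrow = 1), genes = "M")
    q <- runif(1, 0.05, 0.5)
    call <- call_marker_niches(counts, marker = "M", q = q)
    expect_equal(sort(call$members),
                 sort(bf_top_quantile(expr, colnames(counts), q)))
  }
})

test_that("niche calls are invariant under monotone transforms", {
  set.seed(7)
  expr <- rnbinom(200, mu = 4, size = 2)
  counts <- toy_counts(matrix(expr, nrow = 1), genes = "M")
  counts2 <- toy_counts(matrix(log1p(expr) * 3 + 1, nrow = 1), genes = "M")
  a <- call_marker_niches(counts, marker = "M", q = 0.1)
  b <- call_marker_niches(counts2, marker = "M", q = 0.1)
  expect_identical(a$members, b$members)
})

test_that("tumor_only scope restricts the ranked population", {
  set.seed(2)
  counts <- toy_counts(matrix(rpois(40, 5), nrow = 1), genes = "M")
  grid <- toy_grid(seq_len(40), rep(1, 40))
  comp <- toy_comp(grid, grid$barcode[1:10])
  comp$barcode <- colnames(counts)  # align names with the matrix
  call <- call_marker_niches(counts, comp, "M", q = 0.2,
                             scope = "tumor_only")
  expect_length(call$members, 2L)  # ceil(0.2 * 10)
  expect_true(all(call$members %in% comp$barcode[1:10]))
  expect_error(call_marker_niches(counts, marker = "Absent"), "absent")
  expect_error(call_marker_niches(counts, marker = "M", q = 1.2), "q must")
})

test_that("overlap summaries satisfy inclusion-exclusion exactly", {
  mk_call <- function(m, members)
    structure(list(section_id = "s", marker = m, q = .1,
                   scope = "all_spots", members = members),
              class = "niche_call")
  # identical sets
  ov <- overlap_summary(list(mk_call("A", c("a", "b")),
                             mk_call("B", c("a", "b"))))
  expect_equal(ov$exact_regions, c(`A&B` = 2L))
  expect_equal(ov$jaccard["A", "B"], 1)
  # disjoint sets
  ov2 <- overlap_summary(list(mk_call("A", c("a", "b")),
                              mk_call("B", c("c"))))
  expect_equal(ov2$jaccard["A", "B"], 0)
  # random families vs brute-force membership tabulation
  for (s in 1:20) {
    set.seed(s)
    universe <- sprintf("S%03d", 1:40)
    k <- sample(2:5, 1)
    sets <- lapply(1:k, function(i) sample(universe, sample(3:20, 1)))
    calls <- Map(mk_call, LETTERS[1:k], sets)
    ov <- overlap_summary(calls)
    # counts over exact regions sum to |union|
    expect_equal(sum(ov$exact_regions), length(unique(unlist(sets))))
    # each pairwise intersection recoverable by inclusion of regions
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      want <- length(intersect(sets[[i]], sets[[j]]))
      pats <- names(ov$exact_regions)
      has_both <- vapply(strsplit(pats, "&"), function(p)
        all(LETTERS[c(i, j)] %in% p), logical(1))
      expect_equal(sum(ov$exact_regions[has_both]), want)
    }
  }
  expect_error(overlap_summary(list(mk_call("A", "a"), {
    cl <- mk_call("B", "b"); cl$section_id <- "other"; cl
  })), "mixed")
})

test_that("zonal composition fractions cross-tabulate and sum to one", {
  grid <- toy_grid(1:20, rep(1, 20))
  zones <- setNames(rep(paste0("T", 1:5), each = 2), grid$barcode[1:10])
  comp <- toy_comp(grid, grid$barcode[1:10], zone = zones)
  call <- structure(list(section_id = "s", marker = "M", q = .5,
                         scope = "all_spots",
                         members = grid$barcode[c(1, 2, 9, 10, 15)]),
                    class = "niche_call")
  fr <- niche_composition(call, comp)
  expect_equal(sum(fr), 1)
  expect_equal(fr[["T1"]], 0.4)
  expect_equal(fr[["T5"]], 0.4)
  expect_equal(fr[["non_tumor"]], 0.2)
  # entirely inside one zone
  call$members <- grid$barcode[9:10]
  expect_equal(niche_composition(call, comp)[["T5"]], 1)
})

test_that("auc scores hit the closed-form extremes", {
  # 100 genes, signature in the very top ranks of spot 1, bottom of spot 2
  g <- sprintf("G%03d", 1:100)
  m <- matrix(0, 100, 2, dimnames = list(g, c("top", "bottom")))
  sig <- g[1:3]
  m[, 1] <- rev(seq_len(100))          # G001 highest
  m[, 2] <- seq_len(100)               # G001 lowest
  st <- auc_score(m, sig, top_frac = 0.05)
  expect_equal(st$score[st$barcode == "top"], 1)
  expect_equal(st$score[st$barcode == "bottom"], 0)
  expect_error(auc_score(m, c("Nope1", "Nope2")), "no genes")
})

test_that("auc scores match exhaustive recovery-curve enumeration", {
  for (s in 1:20) {
    set.seed(s)
    g <- sprintf("G%02d", 1:10)
    expr <- rpois(10, 3)
    m <- matrix(expr, ncol = 1, dimnames = list(g, "S1"))
    sig <- sample(g, 2)
    st <- auc_score(m, sig, top_frac = 0.5)
    expect_equal(st$score, bf_auc(expr, g, sig, 0.5))
  }
})

test_that("auc scores are rank-based and monotone invariant", {
  set.seed(11)
  g <- sprintf("G%03d", 1:200)
  m <- matrix(rnbinom(200 * 5, mu = 3, size = 2), 200, 5,
              dimnames = list(g, sprintf("S%d", 1:5)))
  sig <- sample(g, 10)
  a <- auc_score(m, sig, top_frac = 0.1)
  b <- auc_score(log1p(m) * 7 + 2, sig, top_frac = 0.1)
  expect_equal(a$score, b$score)
  expect_true(all(a$score >= 0 & a$score <= 1))
})

test_that("module scores equal the direct mean difference", {
  set.seed(3)
  g <- sprintf("G%02d", 1:20)
  m <- matrix(rpois(20 * 6, 5), 20, 6, dimnames = list(g, sprintf("S%d", 1:6)))
  sig <- c("G03", "G11", "G17")
  # one bin + full control pool: control mean is the overall gene mean
  st <- module_score(m, sig, n_bins = 1, n_ctrl = 20, seed = 1)
  x <- as.matrix(normalize_log1p_cp10k(m))
  want <- colMeans(x[sig, ]) - colMeans(x)
  expect_equal(st$score, unname(want))
  # a constant added to a spot's normalized profile cancels
  x2 <- x; x2[, 2] <- x2[, 2] + 5
  st2 <- module_score(x2, sig, n_bins = 1, n_ctrl = 20, seed = 1,
                      normalize = FALSE)
  st1 <- module_score(x, sig, n_bins = 1, n_ctrl = 20, seed = 1,
                      normalize = FALSE)
  expect_equal(st2$score, st1$score, tolerance = 1e-12)
})

test_that("degenerate one-gene bins make signatures their own controls", {
  g <- sprintf("G%02d", 1:6)
  set.seed(5)
  # well-separated means so every gene sits alone in its bin
  m <- matrix(rep(c(1, 5, 25, 125, 625, 3125), 4), 6, 4,
              dimnames = list(g, sprintf("S%d", 1:4)))
  expect_warning(st <- module_score(m, c("G03"), n_bins = 6, n_ctrl = 3,
                                    seed = 2), "replacement")
  expect_equal(st$score, rep(0, 4))
})

test_that("population mapping reduces to marker calls for 1-gene sets", {
  set.seed(13)
  g <- c("CD44", sprintf("G%03d", 1:99))
  m <- matrix(rnbinom(100 * 50, mu = 3, size = 2), 100, 50,
              dimnames = list(g, sprintf("S%03d", 1:50)))
  maps <- population_signature_map(m, library = list(pop = "CD44"),
                                   q = 0.2, top_frac = 0.2)
  # auc of a single gene is monotone in its rank, hence in its expression;
  # ties in auc scores and raw counts break identically (by barcode)
  call <- call_marker_niches(m, marker = "CD44", q = 0.2)
  # both select spots where CD44 is relatively high; compare score order
  st <- maps$pop$scores
  auc_rank <- st$barcode[order(-st$score, st$barcode)][1:10]
  expect_setequal(maps$pop$members, auc_rank)
})

test_that("disjoint signatures on orthogonal blocks give disjoint spot sets", {
  g <- sprintf("G%03d", 1:40)
  m <- matrix(1, 40, 20, dimnames = list(g, sprintf("S%03d", 1:20)))
  m[1:5, 1:10] <- 50    # block A high in first half of spots
  m[6:10, 11:20] <- 50  # block B high in second half
  maps <- population_signature_map(
    m, library = list(A = g[1:5], B = g[6:10]), q = 0.5, top_frac = 0.25)
  expect_length(intersect(maps$A$members, maps$B$members), 0L)
  expect_true(all(maps$A$members %in% sprintf("S%03d", 1:10)))
  expect_true(all(maps$B$members %in% sprintf("S%03d", 11:20)))
})

test_that("edge-planted population signatures map to the tumor rim", {
  hits <- vapply(1:5, function(s) {
    cfg <- hex_cfg(seed = s, section_extent_um = c(2200, 2200),
                   tumor_radius_um = 600,
                   zone_edges_um = c(120, 240, 360, 480))
    sec <- simulate_section(cfg, cells = FALSE)
    adj <- build_adjacency(sec$grid)
    regs <- extract_tumor_regions(sec$compartments, adj, sec$grid)
    fld <- spot_edge_distance(regs[[1]], sec$grid)
    maps <- population_signature_map(
      sec$counts, sec$compartments,
      library = list(iCAF = c("Col1a1", "Il11")),
      q = 0.10, scope = "tumor_only")
    d <- fld$distance_um[match(maps$iCAF$members, fld$subject_id)]
    mean(d <= 2 * 100, na.rm = TRUE)  # within two pitches of the boundary
  }, numeric(1))
  expect_gte(mean(hits >= 0.8), 0.8)
})
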
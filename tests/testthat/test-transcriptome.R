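toy_sce <- function(counts, library_id = "L1", ...) {
  extras <- list(...)
  cd <- S4Vectors::DataFrame(
    library_id = rep(library_id, length.out = ncol(counts)))
  for (nm in names(extras)) cd[[nm]] <- extras[[nm]]
  rownames(cd) <- colnames(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd)
}

rand_counts <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 2), n_genes, n_cells,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  m
}

test_that("QC filter applies strict printed-style thresholds", {
  m <- rand_counts(10, 5, 1)
  sce <- toy_sce(m, n_genes_detected = c(1200, 1400, 2000, 900, 1350),
                 total_umi = rep(5000, 5), mito_fraction = rep(0.1, 5))
  spec <- library_filter_spec("L1", min_genes = 1300)
  out <- qc_filter(sce, spec)
  expect_equal(ncol(out), 3)
  expect_equal(S4Vectors::metadata(out)$qc_summary$n_pass, 3)
  # boundary mito exactly at the limit fails (strict <)
  sce2 <- toy_sce(m, n_genes_detected = rep(2000, 5),
                  total_umi = rep(5000, 5),
                  mito_fraction = c(0.25, 0.249, 0.3, 0.1, 0.2501))
  out2 <- qc_filter(sce2, library_filter_spec("L1"))
  expect_equal(ncol(out2), 2)
  expect_error(qc_filter(sce, library_filter_spec("Lx", min_genes = 1)),
               "no filter spec")
})

test_that("QC filter agrees with brute-force per-cell re-evaluation", {
  for (rep in 1:10) {
    m <- rand_counts(30, 40, rep)
    ng <- sample(500:2500, 40, replace = TRUE)
    umi <- sample(1000:90000, 40, replace = TRUE)
    mito <- runif(40, 0, 0.5)
    lib <- sample(c("A", "B"), 40, replace = TRUE)
    sce <- toy_sce(m, library_id = lib, n_genes_detected = ng,
                   total_umi = umi, mito_fraction = mito)
    spec <- library_filter_spec(c("A", "B"),
                                min_genes = c(1300, 1000),
                                max_umi = c(80000, 30000),
                                max_mito = c(0.25, 0.25))
    out <- qc_filter(sce, spec)
    expected <- vapply(seq_len(40), function(i) {
      s <- spec[spec$library_id == lib[i], ]
      ng[i] > s$min_genes && umi[i] < s$max_umi && mito[i] < s$max_mito
    }, logical(1))
    expect_equal(S4Vectors::metadata(out)$qc_pass, expected)
    expect_equal(ncol(out), sum(expected))
  }
})

test_that("germ-cell selection keeps cells with marker transcripts", {
  m <- matrix(0L, 3, 3,
              dimnames = list(c("Dazl", "Ddx4", "Other"),
                              c("c1", "c2", "c3")))
  m["Dazl", 2] <- 2; m["Ddx4", 3] <- 3; m["Other", ] <- 5L
  sce <- toy_sce(m)
  expect_equal(ncol(select_germ_cells(sce)), 2)
  expect_equal(ncol(select_germ_cells(sce, min_count = 0)), 3)
  expect_error(select_germ_cells(sce, marker_genes = c("Dazl", "Nope")),
               "Nope")
})

test_that("normalisation fixes per-cell totals and log-transforms", {
  m <- rand_counts(20, 10, 3) + 1L
  sce <- normalize_log(toy_sce(m), scale_factor = 1e4)
  norm <- SummarizedExperiment::assay(sce, "normcounts")
  expect_equal(unname(Matrix::colSums(norm)), rep(1e4, 10))
  expect_equal(as.matrix(SummarizedExperiment::assay(sce, "logcounts")),
               log1p(as.matrix(norm)), tolerance = 1e-12)
  # single cell with scale factor = library size reproduces log1p(counts)
  one <- toy_sce(m[, 1, drop = FALSE])
  one <- normalize_log(one, scale_factor = sum(m[, 1]))
  expect_equal(as.numeric(SummarizedExperiment::assay(one, "logcounts")),
               log1p(as.numeric(m[, 1])))
})

test_that("z-scoring flags constant genes and standardises the rest", {
  m <- rand_counts(15, 20, 4)
  m[3, ] <- 7L  # constant gene (after normalisation it may still vary)
  sce <- normalize_log(toy_sce(m))
  z <- zscore_genes(sce)
  live <- setdiff(rownames(z), attr(z, "zero_variance_genes"))
  expect_equal(unname(rowMeans(z[live, ])), rep(0, length(live)),
               tolerance = 1e-12)
  expect_equal(unname(apply(z[live, ], 1, sd)), rep(1, length(live)),
               tolerance = 1e-12)
  # a truly constant logcounts row comes back as zeros
  m2 <- matrix(5L, 4, 6, dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  z2 <- zscore_genes(normalize_log(toy_sce(m2)))
  expect_true(all(z2 == 0))
  expect_setequal(attr(z2, "zero_variance_genes"), rownames(z2))
})

test_that("variable-gene selection finds the within-bin outlier", {
  set.seed(5)
  n_cells <- 200
  m <- matrix(rpois(40 * n_cells, 5), 40, n_cells,
              dimnames = list(paste0("g", 1:40),
                              paste0("c", seq_len(n_cells))))
  # one gene with the same mean but inflated dispersion
  burst <- rpois(n_cells, 1) * 5L
  m[7, ] <- burst + as.integer(round(5 - mean(burst)))
  sce <- normalize_log(toy_sce(pmax(m, 0L)))
  sel <- variable_genes(sce, n_bins = 4, z_cutoff = 1)
  expect_true("g7" %in% sel)
  # permutation invariance
  perm <- sample(nrow(m))
  sce_p <- normalize_log(toy_sce(m[perm, ]))
  sel_p <- variable_genes(sce_p, n_bins = 4, z_cutoff = 1)
  expect_setequal(sel, sel_p)
  expect_error(variable_genes(sce, n_bins = 100), "fewer genes")
})

test_that("identical dispersions select nothing at a positive cutoff", {
  m <- matrix(rep(c(2L, 4L), each = 10, times = 12), nrow = 12, byrow = TRUE)
  dimnames(m) <- list(paste0("g", 1:12), paste0("c", 1:20))
  sce <- normalize_log(toy_sce(m))
  expect_length(variable_genes(sce, n_bins = 1, z_cutoff = 1), 0)
})

two_blob_matrix <- function(n_per = 100, n_genes = 40, sep = 4, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n_genes * 2 * n_per), n_genes, 2 * n_per)
  base[1:10, seq_len(n_per)] <- base[1:10, seq_len(n_per)] + sep
  dimnames(base) <- list(paste0("g", seq_len(n_genes)),
                         paste0("c", seq_len(2 * n_per)))
  base
}

test_that("graph clustering separates two Gaussian blobs exactly", {
  z <- two_blob_matrix()
  cr <- cluster_graph(z, n_pcs = 10, k = 15, resolution = 0.6, seed = 3)
  truth <- rep(1:2, each = 100)
  expect_equal(length(unique(cr$labels)), 2)
  tab <- table(cr$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), 200)  # perfect agreement
  # determinism under the same seed
  cr2 <- cluster_graph(z, n_pcs = 10, k = 15, resolution = 0.6, seed = 3)
  expect_identical(cr$labels, cr2$labels)
  # labels are size-ordered
  expect_true(all(diff(as.integer(cr$sizes)) <= 0))
})

test_that("vanishing resolution collapses connected data to one cluster", {
  set.seed(2)
  z <- matrix(rnorm(30 * 80), 30, 80,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:80)))
  cr <- cluster_graph(z, n_pcs = 5, k = 10, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(cr$labels)), 1)
  expect_error(cluster_graph(z, k = 100, seed = 1), "k must be smaller")
})

test_that("resolution selection isolates a planted population", {
  cfg <- small_counts_config(n_cells = c(P6 = 500), rare_effect = 3)
  sce <- normalize_log(simulate_counts(cfg, seed = 6))
  hv <- variable_genes(sce)
  z <- zscore_genes(sce)[hv, , drop = FALSE]
  sel <- select_resolution(z, reference = sce$rare, k = 15, seed = 2)
  cl <- sel$result$labels
  best <- which.max(tabulate(cl[sce$rare]))
  expect_gte(sum(sce$rare & cl == best) / sum(sce$rare), 0.8)
  expect_true(all(c("resolution", "containment", "purity") %in%
                    names(sel$table)))
})

test_that("unreachable criteria error and carry the scan table", {
  set.seed(8)
  z <- matrix(rnorm(30 * 120), 30, 120,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:120)))
  ref <- sample(c(TRUE, FALSE), 120, replace = TRUE, prob = c(0.1, 0.9))
  err <- tryCatch(
    select_resolution(z, ref, grid = c(0.6, 1.0), k = 10, seed = 1,
                      containment_min = 0.99, enrichment_min = 0.99),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_s3_class(attr(err, "table"), "data.frame")
  expect_error(select_resolution(z, logical(120), k = 10), "empty")
})

test_that("marker statistics satisfy the dotplot identities", {
  m <- rand_counts(25, 60, 9)
  sce <- normalize_log(toy_sce(m))
  labels <- rep(1:3, each = 20)
  ms <- marker_stats(sce, labels)
  expect_equal(unname(rowSums(ms$scaled)), rep(0, 25), tolerance = 1e-10)
  expect_true(all(ms$detection >= 0 & ms$detection <= 1))
  # gene expressed only in cluster 1 (in half its cells) passes
  m2 <- m; m2["g1", ] <- 0L; m2["g1", 1:10] <- 5L
  ms2 <- marker_stats(normalize_log(toy_sce(m2)), labels)
  expect_true(passes_marker_criteria(ms2, "g1"))
  # gene detected in 5% of each cluster's cells fails the 10% rule
  m3 <- m; m3["g2", ] <- 0L; m3["g2", c(1, 21, 41)] <- 5L
  ms3 <- marker_stats(normalize_log(toy_sce(m3)), labels)
  expect_false(passes_marker_criteria(ms3, "g2"))
})

test_that("cluster annotation ranks by SSC-versus-differentiation score", {
  cfg <- small_counts_config(n_cells = c(P6 = 400))
  sce <- normalize_log(simulate_counts(cfg, seed = 10))
  panels <- S4Vectors::metadata(sce)$panels
  # cluster cells by their true continuum position
  labels <- cut(sce$u, breaks = quantile(sce$u, c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE, labels = c("low", "mid", "high"))
  ms <- marker_stats(sce, as.character(labels))
  ann <- annotate_clusters(ms, list(ssc = panels$ssc, diff = panels$diff))
  expect_equal(ann$ssc_like, "low")
  # swapping panels flips the call to the other extreme
  swapped <- annotate_clusters(ms, list(ssc = panels$diff,
                                        diff = panels$ssc))
  expect_equal(swapped$ssc_like, "high")
  # single cluster is trivially the argmax
  ms1 <- marker_stats(sce, rep(1, ncol(sce)))
  ann1 <- annotate_clusters(ms1, list(ssc = panels$ssc,
                                      diff = panels$diff))
  expect_equal(ann1$ssc_like, "1")
  expect_error(annotate_clusters(ms, list(ssc = character(0),
                                          diff = panels$diff)), "empty")
})

test_that("cluster overlap matches the contingency-table oracle", {
  a <- rep(c("x", "y"), each = 10)
  ov <- cluster_overlap(a, a)
  expect_equal(unname(diag(ov)), c(100, 100))
  b <- rep(c("p", "q"), times = 10)
  ov2 <- cluster_overlap(a, b)
  expect_equal(unname(ov2["x", ]), c(50, 50))
  set.seed(3)
  la <- sample(1:4, 200, replace = TRUE)
  lb <- sample(1:3, 200, replace = TRUE)
  ov3 <- cluster_overlap(la, lb)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(ov3[i, j], 100 * sum(la == i & lb == j) / sum(la == i))
  }
  expect_equal(unname(rowSums(ov3)), rep(100, 4))
  expect_error(cluster_overlap(la, lb[-1]), "different cell universes")
})

test_that("modified RV has the required coefficient properties", {
  set.seed(4)
  x <- matrix(rnorm(100 * 5), 100, 5)
  y <- matrix(rnorm(100 * 7), 100, 7)
  expect_equal(modified_rv(x, x), 1)
  expect_equal(modified_rv(x, y), modified_rv(y, x))
  expect_equal(modified_rv(x, x[, sample(5)]), 1)
  r <- modified_rv(x, y)
  expect_lt(abs(r), 0.2)
  expect_true(r >= -1 && r <= 1)
  expect_warning(rc <- modified_rv(matrix(1, 100, 3), y), "constant")
  expect_true(is.na(rc))
  expect_error(modified_rv(x, y[-1, ]), "row universe")
})

test_that("replicate pseudobulk profiles correlate near one", {
  cfg <- small_counts_config(n_cells = c(P6 = 300))
  a <- normalize_log(simulate_counts(cfg, seed = 21))
  b <- normalize_log(simulate_counts(cfg, seed = 22))
  pb <- cbind(pseudobulk(a), pseudobulk(b))
  r <- modified_rv(pb[, 1, drop = FALSE], pb[, 2, drop = FALSE])
  expect_gt(r, 0.9)
})
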
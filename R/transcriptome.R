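#' Per-library quality-control filter specification
#'
#' One row per library with printed-style threshold rules. All comparisons
#' are strict, matching the ">" / "<" convention of per-library QC reports:
#' a cell passes iff `n_genes_detected > min_genes`, `n_genes_detected <
#' max_genes` (when set), `total_umi < max_umi` (when set) and
#' `mito_fraction < max_mito`. Boundary cells fail.
#'
#' @param library_id character vector of library ids.
#' @param min_genes,max_genes,max_umi numeric per-library bounds; `NA`
#'   disables a bound.
#' @param max_mito maximum mitochondrial fraction (default 0.25 for all
#'   libraries).
#' @return data.frame of class `library_filter_spec`.
#' @export
library_filter_spec <- function(library_id, min_genes = NA, max_genes = NA,
                                max_umi = NA, max_mito = 0.25) {
  spec <- data.frame(library_id = library_id,
                     min_genes = as.numeric(min_genes),
                     max_genes = as.numeric(max_genes),
                     max_umi = as.numeric(max_umi),
                     max_mito = as.numeric(max_mito),
                     stringsAsFactors = FALSE)
  bad <- !is.na(spec$min_genes) & !is.na(spec$max_genes) &
    spec$min_genes >= spec$max_genes
  if (any(bad)) stop("inconsistent bounds: min_genes >= max_genes for ",
                     paste(spec$library_id[bad], collapse = ", "))
  class(spec) <- c("library_filter_spec", class(spec))
  spec
}

.qc_pass <- function(n_genes, total_umi, mito, spec_row) {
  pass <- rep(TRUE, length(n_genes))
  if (!is.na(spec_row$min_genes)) pass <- pass & (n_genes > spec_row$min_genes)
  if (!is.na(spec_row$max_genes)) pass <- pass & (n_genes < spec_row$max_genes)
  if (!is.na(spec_row$max_umi)) pass <- pass & (total_umi < spec_row$max_umi)
  if (!is.na(spec_row$max_mito)) pass <- pass & (mito < spec_row$max_mito)
  pass
}

#' Filter low-quality cells with per-library threshold rules
#'
#' @param sce a SingleCellExperiment with colData columns `library_id`,
#'   `n_genes_detected`, `total_umi`, `mito_fraction` (recomputed from the
#'   counts assay when absent).
#' @param specs a [library_filter_spec()] covering every library in `sce`.
#' @return the filtered SingleCellExperiment; a per-library pass/fail table
#'   is attached as `metadata(sce)$qc_summary` and the per-cell logical as
#'   attribute is stored in `metadata(sce)$qc_pass`.
#' @export
qc_filter <- function(sce, specs) {
  stopifnot(is(sce, "SingleCellExperiment"))
  cd <- SummarizedExperiment::colData(sce)
  counts <- SummarizedExperiment::assay(sce, "counts")
  n_genes <- if ("n_genes_detected" %in% names(cd)) cd$n_genes_detected
             else Matrix::colSums(counts > 0)
  umi <- if ("total_umi" %in% names(cd)) cd$total_umi
         else Matrix::colSums(counts)
  mito <- if ("mito_fraction" %in% names(cd)) cd$mito_fraction
          else rep(0, ncol(sce))
  libs <- as.character(cd$library_id)
  unknown <- setdiff(unique(libs), specs$library_id)
  if (length(unknown))
    stop("no filter spec for library: ", paste(unknown, collapse = ", "))
  pass <- rep(NA, ncol(sce))
  for (lib in unique(libs)) {
    i <- libs == lib
    row <- specs[specs$library_id == lib, , drop = FALSE]
    pass[i] <- .qc_pass(n_genes[i], umi[i], mito[i], row)
  }
  tab <- do.call(rbind, lapply(unique(libs), function(lib) {
    i <- libs == lib
    data.frame(library_id = lib, n_cells = sum(i), n_pass = sum(pass[i]),
               n_fail = sum(!pass[i]))
  }))
  out <- sce[, pass]
  S4Vectors::metadata(out)$qc_summary <- tab
  S4Vectors::metadata(out)$qc_pass <- pass
  out
}

#' Select germ cells by marker transcript abundance
#'
#' Germ cells are separated from contaminating soma by the summed counts of
#' canonical germline markers (Dazl and Ddx4 by default).
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param marker_genes character, default `c("Dazl", "Ddx4")`.
#' @param min_count keep cells with summed marker counts at or above this
#'   (default 1).
#' @return the subset SingleCellExperiment.
#' @export
select_germ_cells <- function(sce, marker_genes = c("Dazl", "Ddx4"),
                              min_count = 1) {
  missing <- setdiff(marker_genes, rownames(sce))
  if (length(missing))
    stop("marker genes absent from matrix: ", paste(missing, collapse = ", "))
  counts <- SummarizedExperiment::assay(sce, "counts")
  total <- Matrix::colSums(counts[marker_genes, , drop = FALSE])
  sce[, total >= min_count]
}

#' Library-size normalisation and log transform
#'
#' Per cell: counts are divided by the cell's total, multiplied by
#' `scale_factor` and log1p-transformed into a `logcounts` assay; the
#' pre-log normalised matrix is stored as `normcounts`.
#'
#' @param sce a SingleCellExperiment with positive library sizes.
#' @param scale_factor default 1e4.
#' @return `sce` with `normcounts` and `logcounts` assays added.
#' @export
normalize_log <- function(sce, scale_factor = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  lib <- Matrix::colSums(counts)
  stopifnot(all(lib > 0))
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / lib)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "normcounts") <- norm
  SummarizedExperiment::assay(sce, "logcounts") <- log1p(norm)
  sce
}

#' Z-score genes across cells
#'
#' Centres and scales each gene of the `logcounts` assay to mean 0, sd 1
#' across cells. Zero-variance genes become all-zero rows and are flagged.
#'
#' @param sce a SingleCellExperiment after [normalize_log()].
#' @return a dense matrix (genes x cells) with attribute
#'   `"zero_variance_genes"`.
#' @export
zscore_genes <- function(sce) {
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  flat <- s == 0
  s[flat] <- 1
  z <- (x - mu) / s
  z[flat, ] <- 0
  attr(z, "zero_variance_genes") <- rownames(x)[flat]
  z
}

#' Mean/dispersion variable-gene selection with expression binning
#'
#' Per gene, dispersion is variance over mean of the normalised (pre-log)
#' expression; genes are binned into `n_bins` equal-frequency bins of mean
#' expression and dispersions are z-scored within each bin; genes with
#' within-bin z above `z_cutoff` are selected. Binning removes the
#' mean-dispersion trend so highly variable genes stand out at every
#' expression level.
#'
#' @param sce a SingleCellExperiment after [normalize_log()].
#' @param n_bins equal-frequency mean-expression bins (default 20).
#' @param z_cutoff within-bin dispersion z-score cutoff (default 1).
#' @return character vector of selected gene names; the per-gene table is
#'   attached as attribute `"table"`.
#' @export
variable_genes <- function(sce, n_bins = 20L, z_cutoff = 1) {
  x <- SummarizedExperiment::assay(sce, "normcounts")
  if (nrow(x) < n_bins) stop("fewer genes than bins")
  mu <- Matrix::rowMeans(x)
  v <- Matrix::rowMeans(x^2) - mu^2
  v <- v * ncol(x) / (ncol(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2) factor(rep("bin1", length(mu)))
         else cut(mu, breaks = br, include.lowest = TRUE)
  z <- numeric(length(disp))
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  tab <- data.frame(gene = rownames(x), mean = mu, dispersion = disp,
                    bin = bin, z = z, stringsAsFactors = FALSE)
  sel <- tab$gene[tab$z > z_cutoff]
  attr(sel, "table") <- tab
  sel
}

.knn_graph <- function(pcs, k) {
  n <- nrow(pcs)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(dist(pcs))
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::simplify(g)
}

#' KNN-graph community clustering in principal-component space
#'
#' PCA on the scaled matrix, a K-nearest-neighbour graph on Euclidean
#' distance in PC space, then Louvain modularity optimisation at the given
#' resolution. Deterministic under a fixed seed; cluster labels are
#' relabelled in decreasing size order (1 = largest).
#'
#' @param scaled genes x cells z-scored matrix (e.g. from [zscore_genes()],
#'   subset to variable genes).
#' @param n_pcs principal components retained (default: 20, clamped to the
#'   matrix rank bound; an explicit value beyond `min(dim(scaled))` errors).
#' @param k neighbours (default 20).
#' @param resolution Louvain resolution (default 0.6).
#' @param seed RNG seed for the community search.
#' @param ages optional per-cell age labels for the per-cluster age
#'   distribution.
#' @return list of class `cluster_result`: `labels` (integer per cell),
#'   `resolution`, `k`, `n_pcs`, `sizes`, `age_distribution` (proportion
#'   table or NULL), `pcs` (cells x n_pcs scores).
#' @export
cluster_graph <- function(scaled, n_pcs = NULL, k = 20L, resolution = 0.6,
                          seed = 1L, ages = NULL) {
  if (is.null(n_pcs)) n_pcs <- min(20L, dim(scaled) - 1L)
  stopifnot(k >= 2, n_pcs >= 1, n_pcs <= min(dim(scaled)))
  pcs <- prcomp(t(scaled), center = FALSE, scale. = FALSE)$x
  pcs <- pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
  g <- .knn_graph(pcs, k)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  sizes <- table(raw)
  relabel <- setNames(seq_along(sizes),
                      names(sort(sizes, decreasing = TRUE)))
  labels <- unname(relabel[as.character(raw)])
  age_dist <- if (!is.null(ages))
    prop.table(table(cluster = labels, age = ages), margin = 1) else NULL
  structure(list(labels = labels, resolution = resolution, k = k,
                 n_pcs = n_pcs, sizes = table(labels),
                 age_distribution = age_dist, pcs = pcs),
            class = "cluster_result")
}

#' Choose the clustering resolution that isolates a reference population
#'
#' Scans a resolution grid and, at each value, finds the cluster best
#' containing the reference cell set: containment = share of the reference
#' inside that cluster, purity = share of that cluster made of reference
#' cells. The chosen resolution is the smallest one at which the reference
#' population is enriched within a single cluster (containment and purity
#' above their minima).
#'
#' @param scaled genes x cells z-scored matrix.
#' @param reference logical or integer index of reference cells (e.g. the
#'   known SSC population).
#' @param grid numeric resolutions to scan (default `seq(0.2, 1.2, 0.2)`).
#' @param containment_min default 0.8.
#' @param enrichment_min minimum purity, default 0.5.
#' @param ... passed to [cluster_graph()] (`n_pcs`, `k`, `seed`, `ages`).
#' @return list: `resolution`, `result` (the chosen [cluster_graph()]
#'   output), `table` (per-resolution containment/purity). If no grid value
#'   satisfies the criteria an error is thrown carrying the table as
#'   attribute `"table"`.
#' @export
select_resolution <- function(scaled, reference,
                              grid = seq(0.2, 1.2, by = 0.2),
                              containment_min = 0.8, enrichment_min = 0.5,
                              ...) {
  if (is.logical(reference)) reference <- which(reference)
  if (!length(reference)) stop("reference set is empty")
  if (!length(grid)) stop("resolution grid is empty")
  grid <- sort(grid)
  rows <- list(); results <- list()
  for (res in grid) {
    cr <- cluster_graph(scaled, resolution = res, ...)
    per <- vapply(sort(unique(cr$labels)), function(cl) {
      inter <- sum(reference %in% which(cr$labels == cl))
      c(containment = inter / length(reference),
        purity = inter / sum(cr$labels == cl))
    }, numeric(2))
    best <- which.max(per["containment", ])
    rows[[length(rows) + 1L]] <- data.frame(
      resolution = res, n_clusters = length(unique(cr$labels)),
      best_cluster = sort(unique(cr$labels))[best],
      containment = per["containment", best],
      purity = per["purity", best])
    results[[as.character(res)]] <- cr
  }
  tab <- do.call(rbind, rows)
  ok <- tab$containment >= containment_min & tab$purity >= enrichment_min
  if (!any(ok)) {
    e <- simpleError(paste0(
      "no resolution in the grid isolates the reference population ",
      "(containment >= ", containment_min, ", purity >= ", enrichment_min,
      ")"))
    attr(e, "table") <- tab
    stop(e)
  }
  chosen <- tab$resolution[which(ok)[1]]
  list(resolution = chosen, result = results[[as.character(chosen)]],
       table = tab)
}

#' Dot-plot marker statistics per gene and cluster
#'
#' For every gene and cluster: the cluster-mean log-normalised expression
#' z-scored across clusters (so each gene's scaled values have mean zero
#' over clusters) and the detection fraction (share of the cluster's cells
#' with a nonzero count).
#'
#' @param sce a SingleCellExperiment after [normalize_log()].
#' @param labels integer/character cluster labels covering all cells.
#' @return list of class `marker_stats`: `scaled` and `detection`, both
#'   genes x clusters matrices.
#' @export
marker_stats <- function(sce, labels) {
  stopifnot(length(labels) == ncol(sce))
  logc <- SummarizedExperiment::assay(sce, "logcounts")
  counts <- SummarizedExperiment::assay(sce, "counts")
  cl <- sort(unique(labels))
  means <- sapply(cl, function(c)
    Matrix::rowMeans(logc[, labels == c, drop = FALSE]))
  det <- sapply(cl, function(c)
    Matrix::rowMeans(counts[, labels == c, drop = FALSE] > 0))
  colnames(means) <- colnames(det) <- as.character(cl)
  mu <- rowMeans(means)
  s <- apply(means, 1, sd)
  flat <- is.na(s) | s == 0
  s[flat] <- 1
  scaled <- (means - mu) / s
  scaled[flat, ] <- 0
  structure(list(scaled = scaled, detection = det), class = "marker_stats")
}

#' Marker criterion: scaled expression and detection in at least one cluster
#'
#' A gene qualifies as a usable marker when some cluster shows scaled
#' expression above `scaled_min` (default 0) and transcripts detected in
#' more than `detect_min` (default 10%) of its cells.
#'
#' @param stats a [marker_stats()] result.
#' @param genes genes to evaluate (default all).
#' @param scaled_min,detect_min thresholds (strict).
#' @return named logical vector.
#' @export
passes_marker_criteria <- function(stats, genes = NULL, scaled_min = 0,
                                   detect_min = 0.10) {
  stopifnot(inherits(stats, "marker_stats"))
  if (is.null(genes)) genes <- rownames(stats$scaled)
  vapply(genes, function(g) {
    any(stats$scaled[g, ] > scaled_min & stats$detection[g, ] > detect_min)
  }, logical(1))
}

#' Score clusters against marker panels and label the SSC-like cluster
#'
#' Each cluster's panel score is its mean scaled expression over the
#' panel's genes; the SSC-like label goes to the cluster maximising the
#' SSC-program score minus the differentiation-program score (highest SSC
#' markers, lowest differentiation markers). The full score table is
#' returned; no hidden thresholds.
#'
#' @param stats a [marker_stats()] result.
#' @param panels named list of non-empty gene panels; must contain `ssc`
#'   and `diff` entries for the SSC-like call.
#' @return list: `scores` (clusters x panels), `ssc_like` (cluster label),
#'   `ranking` (clusters ordered by descending SSC - differentiation
#'   score).
#' @export
annotate_clusters <- function(stats, panels) {
  stopifnot(inherits(stats, "marker_stats"), length(panels) >= 1)
  if (any(!lengths(panels))) stop("empty marker panel")
  missing <- setdiff(unlist(panels), rownames(stats$scaled))
  if (length(missing))
    stop("panel genes absent: ", paste(missing, collapse = ", "))
  scores <- sapply(panels, function(p)
    colMeans(stats$scaled[p, , drop = FALSE]))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = 1,
                     dimnames = list(NULL, names(panels)))
  rownames(scores) <- colnames(stats$scaled)
  if (!all(c("ssc", "diff") %in% names(panels)))
    stop("panels must include 'ssc' and 'diff'")
  delta <- scores[, "ssc"] - scores[, "diff"]
  ranking <- rownames(scores)[order(delta, decreasing = TRUE)]
  list(scores = scores, ssc_like = ranking[1], ranking = ranking)
}

#' Pairwise cluster overlap between two labelings of the same cells
#'
#' `overlap[a, b]` is the percentage of cluster `a` (first labelling)
#' contained in cluster `b` (second labelling); each row sums to 100.
#'
#' @param labels_a,labels_b equal-length labelings of one cell universe.
#' @return matrix of percentages, rows = clusters of `labels_a`.
#' @export
cluster_overlap <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings cover different cell universes")
  tab <- table(labels_a, labels_b)
  100 * prop.table(tab, margin = 1)
}

#' Modified multivariate RV coefficient between two matrices
#'
#' Matrix-level correlation of two datasets sharing a feature universe
#' (rows): columns are centred, the row-space inner-product matrices are
#' formed and their diagonals set to zero (removing the self-similarity
#' terms that inflate the plain RV coefficient), and the coefficient is
#' their Frobenius cosine. Values of 0.96-0.99 between replicate
#' pseudobulk profiles indicate negligible batch effects.
#'
#' @param x,y numeric matrices with identical row universes (at least 2
#'   rows); columns may differ.
#' @return scalar in \[-1, 1\]; `NA` with a warning when either centred
#'   cross-product matrix has zero norm (constant matrix).
#' @export
modified_rv <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("matrices must share their row universe")
  if (nrow(x) < 2) stop("need at least 2 rows")
  cp <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    s <- tcrossprod(m)
    diag(s) <- 0
    s
  }
  sx <- cp(x); sy <- cp(y)
  nx <- sqrt(sum(sx^2)); ny <- sqrt(sum(sy^2))
  if (nx == 0 || ny == 0) {
    warning("modified RV undefined: constant matrix")
    return(NA_real_)
  }
  sum(sx * sy) / (nx * ny)
}

#' Per-replicate pseudobulk profiles
#'
#' Mean log-normalised expression per gene within each replicate library;
#' the feature space used for replicate matrix correlations.
#'
#' @param sce a SingleCellExperiment after [normalize_log()].
#' @param by colData column naming the replicate (default `library_id`).
#' @return genes x replicates matrix.
#' @export
pseudobulk <- function(sce, by = "library_id") {
  groups <- as.character(SummarizedExperiment::colData(sce)[[by]])
  logc <- SummarizedExperiment::assay(sce, "logcounts")
  out <- sapply(unique(groups), function(g)
    Matrix::rowMeans(logc[, groups == g, drop = FALSE]))
  colnames(out) <- unique(groups)
  out
}
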
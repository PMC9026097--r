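#' Gene filtering parameters
#'
#' @param detect_percentile per-array percentile defining detectable expression
#'   (default 20): a gene is detected on an array when its intensity is strictly
#'   above this percentile of all genes on that array.
#' @param min_detect_samples minimum number of samples, within a two-group
#'   comparison, in which a gene must be detected (default 2).
#' @param sd_percentile_floor percentile of across-sample SDs below which genes
#'   are dropped (default 5).
#' @param outlier_z absolute z threshold for single-sample outlier exclusion
#'   (default 2.50).
#' @param outlier_sample optional sample ID against which outlier exclusion is
#'   applied (e.g. a borderline control replicate).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(detect_percentile = 20, min_detect_samples = 2L,
                          sd_percentile_floor = 5, outlier_z = 2.50,
                          outlier_sample = NULL) {
  stopifnot_param(detect_percentile > 0 && detect_percentile < 100,
                  "detect_percentile must be in (0, 100)")
  stopifnot_param(sd_percentile_floor > 0 && sd_percentile_floor < 100,
                  "sd_percentile_floor must be in (0, 100)")
  stopifnot_param(outlier_z > 0, "outlier_z must be > 0")
  stopifnot_param(min_detect_samples >= 1, "min_detect_samples must be >= 1")
  structure(list(detect_percentile = detect_percentile,
                 min_detect_samples = as.integer(min_detect_samples),
                 sd_percentile_floor = sd_percentile_floor,
                 outlier_z = outlier_z,
                 outlier_sample = outlier_sample),
            class = "filter_params")
}

#' Collapse probes to genes by highest average expression
#'
#' When several probes map to one gene, the probe with the highest mean across
#' all samples survives; ties are broken by lexicographic probe ID. Probes with
#' no gene mapping are dropped.
#'
#' @param probe_matrix numeric matrix, probes x samples.
#' @param probe_to_gene named character vector probe -> gene (each probe maps
#'   to at most one gene).
#' @return list with `matrix` (one row per gene, rownames = genes) and
#'   `report` (data.frame: gene, probe_kept, n_probes, tie).
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping", call. = FALSE)
  probes <- intersect(rownames(probe_matrix), names(probe_to_gene))
  if (length(probes) == 0) stop("no probes in the matrix are mapped", call. = FALSE)
  m <- probe_matrix[probes, , drop = FALSE]
  gene <- probe_to_gene[probes]
  means <- rowMeans(m)
  ord <- order(gene, -means, probes)  # per gene: highest mean, then smaller ID
  probes_o <- probes[ord]
  gene_o <- gene[ord]
  keep <- !duplicated(gene_o)
  kept_probes <- probes_o[keep]
  report <- data.frame(
    gene = gene_o[keep],
    probe_kept = kept_probes,
    n_probes = as.integer(table(gene)[gene_o[keep]]),
    stringsAsFactors = FALSE
  )
  # flag exact ties in means within a gene
  tie_genes <- unique(gene[duplicated(paste(gene, means))])
  report$tie <- report$gene %in% tie_genes
  out <- m[kept_probes, , drop = FALSE]
  rownames(out) <- report$gene
  o <- order(report$gene)
  list(matrix = out[o, , drop = FALSE], report = report[o, ])
}

#' Detection filter for a two-group comparison
#'
#' A gene is detected on an array when its intensity is strictly above that
#' array's own `detect_percentile` quantile (type-7, over all genes); the gene
#' passes when detected in at least `min_detect_samples` of the comparison's
#' samples.
#'
#' @param matrix genes x samples numeric matrix.
#' @param comparison_samples sample IDs entering the comparison.
#' @param params a [filter_params()].
#' @return named logical vector over genes.
#' @export
detection_filter <- function(matrix, comparison_samples, params = filter_params()) {
  if (!all(comparison_samples %in% colnames(matrix))) {
    stop("comparison_samples must be columns of the matrix", call. = FALSE)
  }
  if (length(comparison_samples) < params$min_detect_samples) {
    stop("fewer comparison samples than min_detect_samples", call. = FALSE)
  }
  sub <- matrix[, comparison_samples, drop = FALSE]
  cuts <- apply(sub, 2, quantile, probs = params$detect_percentile / 100,
                type = 7, names = FALSE)
  detected <- sweep(sub, 2, cuts, ">")
  setNames(rowSums(detected) >= params$min_detect_samples, rownames(matrix))
}

#' Variability filter on across-sample standard deviation
#'
#' Genes are retained when their SD across all samples (n-1 denominator) is at
#' or above the `sd_percentile_floor` percentile of all gene SDs.
#'
#' @inheritParams detection_filter
#' @return named logical vector over genes (TRUE = retained).
#' @export
variability_filter <- function(matrix, params = filter_params()) {
  if (ncol(matrix) < 2) stop("variability filter needs >= 2 samples", call. = FALSE)
  sds <- apply(matrix, 1, sd)
  floor_val <- quantile(sds, probs = params$sd_percentile_floor / 100,
                        type = 7, names = FALSE)
  setNames(sds >= floor_val, rownames(matrix))
}

#' Single-sample outlier gene exclusion
#'
#' A gene is excluded when, using its across-sample mean and SD, the designated
#' sample's |z| exceeds `outlier_z` AND that sample's value is the strict
#' minimum or maximum across samples. With no designated sample the filter is a
#' no-op (with a warning), mirroring its role as a remedial screen for one
#' borderline replicate.
#'
#' @inheritParams detection_filter
#' @return named logical vector (TRUE = excluded).
#' @export
outlier_gene_filter <- function(matrix, params = filter_params()) {
  genes <- rownames(matrix)
  if (is.null(params$outlier_sample)) {
    warning("no outlier_sample designated; no genes excluded")
    return(setNames(rep(FALSE, nrow(matrix)), genes))
  }
  s <- params$outlier_sample
  if (!s %in% colnames(matrix)) {
    stop(sprintf("outlier_sample '%s' not found", s), call. = FALSE)
  }
  mu <- rowMeans(matrix)
  sds <- apply(matrix, 1, sd)
  z <- ifelse(sds > 0, (matrix[, s] - mu) / sds, 0)
  v <- matrix[, s]
  others <- matrix[, setdiff(colnames(matrix), s), drop = FALSE]
  strict_min <- v < apply(others, 1, min)
  strict_max <- v > apply(others, 1, max)
  setNames(abs(z) > params$outlier_z & (strict_min | strict_max), genes)
}

#' Combined per-comparison filter report
#'
#' @inheritParams detection_filter
#' @return list of class `filter_report` with per-gene flags (`detected`,
#'   `variable`, `outlier_excluded`, `retained`) and a `counts` summary.
#' @export
filter_report <- function(matrix, comparison_samples, params = filter_params()) {
  detected <- detection_filter(matrix, comparison_samples, params)
  variable <- variability_filter(matrix, params)
  excluded <- if (is.null(params$outlier_sample)) {
    setNames(rep(FALSE, nrow(matrix)), rownames(matrix))
  } else {
    outlier_gene_filter(matrix, params)
  }
  retained <- detected & variable & !excluded
  structure(list(
    detected = detected, variable = variable, outlier_excluded = excluded,
    retained = retained,
    counts = c(total = nrow(matrix), detected = sum(detected),
               variable = sum(variable), outlier_excluded = sum(excluded),
               retained = sum(retained))
  ), class = "filter_report")
}

#' Grubbs maximum normalized residual test
#'
#' Two-sided test for a single outlier: `G = max |x - mean| / sd`, with the
#' p-value from the t-distribution closed form.
#'
#' @param x numeric vector, length >= 3.
#' @return list with `G`, `p`, and `which` (index of the most extreme value).
#' @export
grubbs_test <- function(x) {
  n <- length(x)
  if (n < 3) stop("Grubbs test needs >= 3 values", call. = FALSE)
  z <- abs(x - mean(x)) / sd(x)
  G <- max(z)
  t2 <- n * (n - 2) * G^2 / ((n - 1)^2 - n * G^2)
  p <- if (t2 <= 0 || !is.finite(t2)) {
    # G at or beyond its algebraic maximum (n-1)/sqrt(n)
    if (G^2 * n >= (n - 1)^2) 0 else 1
  } else {
    min(1, 2 * n * pt(sqrt(t2), df = n - 2, lower.tail = FALSE))
  }
  list(G = G, p = p, which = which.max(z))
}

#' PCA sample screening with a Grubbs test on PC1
#'
#' Standardizes each gene (mean 0, SD 1; constant genes dropped), runs PCA with
#' samples as observations, and applies the two-sided Grubbs test to the PC1
#' scores.
#'
#' @param matrix genes x samples numeric matrix, >= 3 samples.
#' @return list with `scores` (samples x PCs), `outlier_sample`, `G`, `p`.
#' @export
sample_pca_outlier_test <- function(matrix) {
  if (ncol(matrix) < 3) stop("PCA outlier test needs >= 3 samples", call. = FALSE)
  sds <- apply(matrix, 1, sd)
  z <- (matrix[sds > 0, , drop = FALSE] - rowMeans(matrix[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  g <- grubbs_test(pc$x[, 1L])
  list(scores = pc$x, outlier_sample = colnames(matrix)[g$which], G = g$G, p = g$p)
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance on gene vectors with average linkage.
#'
#' @param matrix genes x samples numeric matrix, >= 2 samples.
#' @return an [stats::hclust] object over samples.
#' @export
cluster_samples <- function(matrix) {
  if (ncol(matrix) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  hclust(dist(t(matrix), method = "euclidean"), method = "average")
}
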
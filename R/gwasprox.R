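#' Build a locus map from gene and locus intervals
#'
#' @param genes data.frame with chrom, start, end, name (0-based half-open), as
#'   from [read_bed()] or [simulate_genome_and_loci()].
#' @param loci data.frame with chrom, start (0-based locus positions; `end` is
#'   ignored, loci are single-base points).
#' @return list of class `locus_map` holding `GenomicRanges::GRanges` for both.
#' @export
locus_map <- function(genes, loci) {
  if (anyDuplicated(genes$name)) stop("duplicate gene names", call. = FALSE)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = if (!is.null(genes$strand)) genes$strand else "+"
  )
  names(gene_gr) <- genes$name
  if (nrow(loci) == 0) stop("locus map needs >= 1 locus", call. = FALSE)
  loci_gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, width = 1L)
  )
  structure(list(genes = gene_gr, loci = loci_gr), class = "locus_map")
}

#' Nearest-locus distance per gene
#'
#' Distance in bp between the gene body and the nearest locus on the same
#' chromosome: 0 when the locus falls inside (or immediately adjacent to) the
#' gene, otherwise the size of the gap. Genes with no same-chromosome locus get
#' `Inf`.
#'
#' @param map a [locus_map()].
#' @param gene optional gene name(s); default all genes in the map.
#' @return named numeric vector of distances.
#' @export
nearest_locus_distance <- function(map, gene = NULL) {
  stopifnot(inherits(map, "locus_map"))
  gr <- map$genes
  if (!is.null(gene)) {
    missing <- setdiff(gene, names(gr))
    if (length(missing)) {
      stop(sprintf("unknown gene(s): %s", paste(missing, collapse = ",")), call. = FALSE)
    }
    gr <- gr[gene]
  }
  d <- setNames(rep(Inf, length(gr)), names(gr))
  hits <- GenomicRanges::distanceToNearest(gr, map$loci, ignore.strand = TRUE)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Proximity-test parameters
#'
#' @param top_n size of the top-gene list (default 30).
#' @param windows strictly increasing distance windows in bp.
#' @param n_trials resampling trials for the mean-distance null (default 1000).
#' @param seed integer seed.
#' @return list of class `proximity_params`.
#' @export
proximity_params <- function(top_n = 30L,
                             windows = c(0, 1e4, 5e4, 1e5, 5e5, 1e6),
                             n_trials = 1000L, seed = 1L) {
  stopifnot_param(top_n >= 1, "top_n must be >= 1")
  stopifnot_param(all(diff(windows) > 0), "windows must be strictly increasing")
  stopifnot_param(n_trials >= 1, "n_trials must be >= 1")
  structure(list(top_n = as.integer(top_n), windows = windows,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "proximity_params")
}

#' Locus-proximity overlap scan across distance windows
#'
#' For each window d, the "near" set is the genes whose nearest-locus distance
#' is at most d; a one-sided Fisher's exact test asks whether the top-gene list
#' is enriched in the near set relative to the rest of the universe. The near
#' fraction among non-top genes is reported as the background curve.
#'
#' @param deg_top character vector, the top gene list (subset of the universe).
#' @param universe character vector of genes (all must be in the map).
#' @param map a [locus_map()].
#' @param params a [proximity_params()].
#' @return data.frame per window: window, near_top, near_background,
#'   frac_top, frac_background, p.
#' @export
window_overlap_scan <- function(deg_top, universe, map, params = proximity_params()) {
  if (!all(deg_top %in% universe)) {
    stop("deg_top must be a subset of the universe", call. = FALSE)
  }
  d <- nearest_locus_distance(map, universe)
  is_top <- universe %in% deg_top
  rows <- lapply(params$windows, function(w) {
    near <- d <= w
    a <- sum(near & is_top); b <- sum(!near & is_top)
    c_ <- sum(near & !is_top); dd <- sum(!near & !is_top)
    p <- if (a + c_ == 0) 1 else {
      fisher.test(matrix(c(a, b, c_, dd), 2, byrow = TRUE),
                  alternative = "greater")$p.value
    }
    data.frame(window = w, near_top = a, near_background = c_,
               frac_top = a / sum(is_top), frac_background = c_ / sum(!is_top),
               p = p)
  })
  do.call(rbind, rows)
}

#' Mean nearest-locus distance against a random-gene-set null
#'
#' The observed statistic is the mean nearest-locus distance over the top
#' genes (genes with no same-chromosome locus are excluded from the mean and
#' counted). Each trial draws an equal-sized gene set uniformly without
#' replacement from the universe; the empirical p is lower-tail with the
#' add-one estimator (the hypothesis being that the top genes sit closer to
#' loci than chance). A two-sided variant doubles the smaller tail.
#'
#' @inheritParams window_overlap_scan
#' @param two_sided report the two-sided empirical p instead (default FALSE).
#' @return list: `observed`, `null` (trial means), `p`, `n_finite`,
#'   `n_infinite`, `marginal` (TRUE when p < 0.10).
#' @export
mean_distance_null <- function(deg_top, universe, map, params = proximity_params(),
                               two_sided = FALSE) {
  if (length(universe) < length(deg_top)) {
    stop("universe smaller than the top gene list", call. = FALSE)
  }
  d_all <- nearest_locus_distance(map, universe)
  d_top <- d_all[deg_top]
  finite <- is.finite(d_top)
  if (!any(finite)) stop("no top gene has a finite locus distance", call. = FALSE)
  observed <- mean(d_top[finite])
  k <- length(deg_top)
  null <- with_seed(params$seed, {
    vapply(seq_len(params$n_trials), function(i) {
      dd <- sample(d_all, k)
      mean(dd[is.finite(dd)])
    }, numeric(1))
  })
  lo <- (1 + sum(null <= observed, na.rm = TRUE)) / (params$n_trials + 1)
  hi <- (1 + sum(null >= observed, na.rm = TRUE)) / (params$n_trials + 1)
  p <- if (two_sided) min(1, 2 * min(lo, hi)) else lo
  list(observed = observed, null = null, p = p,
       n_finite = sum(finite), n_infinite = sum(!finite),
       marginal = p < 0.10)
}
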
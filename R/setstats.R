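#' Directional signature concordance (Fisher's exact test)
#'
#' Restricts to detectable genes, drops genes with log2fc exactly 0 (their
#' count is reported), and tests the 2x2 table
#' {signature, background} x {increased, decreased} with a two-sided Fisher's
#' exact test. An exact binomial test of the signature's up-fraction against
#' 50% is reported alongside, since either reading of "concordance" is
#' defensible.
#'
#' @param de a `de_result` (or table).
#' @param sig a [signature_set()].
#' @return list of class `direction_test`: `n_expressed`, `n_zero_fc`,
#'   `frac_up`, `frac_down`, `odds_ratio`, `fisher_p`, `binom_p`, `table`.
#' @export
direction_fisher <- function(de, sig) {
  tab <- de_table(de)
  tab <- tab[tab$detected, , drop = FALSE]
  in_sig <- tab$gene %in% sig$members
  if (!any(in_sig)) stop("no signature member has detectable expression", call. = FALSE)
  nz <- tab$log2fc != 0
  n_zero <- sum(!nz & in_sig)
  t22 <- table(factor(in_sig[nz], levels = c(TRUE, FALSE)),
               factor(tab$log2fc[nz] > 0, levels = c(TRUE, FALSE)))
  dimnames(t22) <- list(set = c("signature", "background"),
                        change = c("up", "down"))
  ft <- fisher.test(t22)
  n_up <- t22["signature", "up"]
  n_dn <- t22["signature", "down"]
  bt <- binom.test(n_up, n_up + n_dn, p = 0.5)
  structure(list(
    n_expressed = sum(in_sig), n_zero_fc = n_zero,
    frac_up = n_up / (n_up + n_dn), frac_down = n_dn / (n_up + n_dn),
    odds_ratio = unname(ft$estimate), fisher_p = ft$p.value,
    binom_p = bt$p.value, table = t22
  ), class = "direction_test")
}

#' Signed cumulative-overlap area statistic
#'
#' All detectable genes are ranked by log2 fold change, descending (ties broken
#' by gene ID). With M expressed members among N genes, the running curve is
#' `C(k) = (members among top k)/M - k/N`; the area statistic is the mean of
#' `C(k)` over k. Positive values mean the signature concentrates among
#' increased genes, negative among decreased genes; the statistic lies in
#' `[-0.5, 0.5]`. The p-value is a two-sided rank-sum test of member fold-change
#' ranks against non-members.
#'
#' @inheritParams direction_fisher
#' @return list of class `area_stat`: `area`, `wilcoxon_p`, `n_members`, `n`.
#' @export
cumulative_overlap_area <- function(de, sig) {
  tab <- de_table(de)
  tab <- tab[tab$detected, , drop = FALSE]
  members <- intersect(sig$members, tab$gene)
  if (!length(members)) stop("no signature member has detectable expression", call. = FALSE)
  if (length(members) >= nrow(tab)) {
    stop("signature covers the whole universe; area undefined", call. = FALSE)
  }
  ord <- order(-tab$log2fc, tab$gene)
  is_mem <- tab$gene[ord] %in% members
  N <- length(is_mem)
  M <- sum(is_mem)
  curve <- cumsum(is_mem) / M - seq_len(N) / N
  area <- mean(curve)
  fc <- tab$log2fc
  idx <- which(tab$gene %in% members)
  p <- suppressWarnings(wilcox.test(fc[idx], fc[-idx], exact = FALSE,
                                    correct = TRUE)$p.value)
  structure(list(area = area, wilcoxon_p = p, n_members = M, n = N),
            class = "area_stat")
}

#' Hypergeometric annotation enrichment
#'
#' One-sided upper-tail hypergeometric test per term, BH-adjusted; terms with
#' zero overlap are skipped.
#'
#' @param deg_set character vector of significant genes (subset of `universe`).
#' @param universe character vector, the detectable gene universe.
#' @param term_to_genes named list, term -> gene vector.
#' @param n_examples number of example overlap genes to list (default 5).
#' @return data.frame per term: term, term_size, overlap, p, fdr, examples.
#' @export
annotation_enrichment <- function(deg_set, universe, term_to_genes, n_examples = 5L) {
  if (!all(deg_set %in% universe)) {
    stop("deg_set must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  K <- length(deg_set)
  rows <- list()
  for (term in names(term_to_genes)) {
    tg <- intersect(term_to_genes[[term]], universe)
    if (!length(tg)) {
      warning(sprintf("term '%s' is disjoint from the universe; skipped", term))
      next
    }
    ov <- intersect(tg, deg_set)
    if (!length(ov)) next
    p <- phyper(length(ov) - 1, length(tg), N - length(tg), K, lower.tail = FALSE)
    rows[[term]] <- data.frame(
      term = term, term_size = length(tg), overlap = length(ov), p = p,
      examples = paste(head(sort(ov), n_examples), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0), fdr = numeric(0),
                      examples = character(0)))
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  rownames(res) <- NULL
  res[order(res$p), c("term", "term_size", "overlap", "p", "fdr", "examples")]
}

#' Aggregate disease-gene sources into a tier table
#'
#' @param source_sets named list, source -> gene vector (e.g. the 7 database
#'   sources linking genes to a disease).
#' @return list of class `disease_gene_table` with `table` (data.frame: gene,
#'   tier, sources) and `tier_counts`.
#' @export
aggregate_disease_sources <- function(source_sets) {
  if (!length(source_sets)) stop("need >= 1 source", call. = FALSE)
  genes <- sort(unique(unlist(source_sets)))
  membership <- vapply(source_sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = length(genes))
  tier <- rowSums(membership)
  tab <- data.frame(
    gene = genes, tier = as.integer(tier),
    sources = apply(membership, 1, function(r) {
      paste(names(source_sets)[r], collapse = ",")
    }),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 tier_counts = table(factor(tab$tier, levels = seq_along(source_sets))),
                 n_sources = length(source_sets)),
            class = "disease_gene_table")
}

#' @rdname aggregate_disease_sources
#' @param x a `disease_gene_table`.
#' @param min_tier minimum number of sources.
#' @return `disease_genes_at_tier()`: genes linked by at least `min_tier`
#'   sources.
#' @export
disease_genes_at_tier <- function(x, min_tier) {
  stopifnot(inherits(x, "disease_gene_table"))
  x$table$gene[x$table$tier >= min_tier]
}

#' Random-gene-set null for mean absolute fold change
#'
#' The observed statistic is the mean |log2fc| over the target genes (after
#' intersecting with the detectable universe); the null resamples equal-sized
#' gene sets without replacement. The empirical p uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_trials + 1)`.
#'
#' @param de a `de_result` (or table).
#' @param target_genes character vector of genes of interest.
#' @param n_trials number of resampling trials (default 10000).
#' @param seed integer seed.
#' @return list: `observed`, `null` (trial means), `p`, `n_target`.
#' @export
random_set_fc_null <- function(de, target_genes, n_trials = 10000L, seed = 1L) {
  stopifnot_param(n_trials >= 1, "n_trials must be >= 1")
  tab <- de_table(de)
  tab <- tab[tab$detected, , drop = FALSE]
  abs_fc <- setNames(abs(tab$log2fc), tab$gene)
  target <- intersect(target_genes, names(abs_fc))
  if (!length(target)) stop("no target gene has detectable expression", call. = FALSE)
  observed <- mean(abs_fc[target])
  k <- length(target)
  null <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) mean(sample(abs_fc, k)), numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (n_trials + 1)
  list(observed = observed, null = null, p = p, n_target = k)
}

#' Correlation between two fold-change vectors, with quadrant fractions
#'
#' @param deA,deB `de_result` objects (or tables).
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `r`, `p`, `n`, and `quadrants` (fractions of shared genes in
#'   each sign combination, labelled `up_up`, `up_down`, `down_up`,
#'   `down_down`).
#' @export
fc_vector_correlation <- function(deA, deB, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ta <- de_table(deA); tb <- de_table(deB)
  shared <- intersect(ta$gene[ta$detected], tb$gene[tb$detected])
  if (length(shared) < 3) stop("need >= 3 shared detectable genes", call. = FALSE)
  x <- ta$log2fc[match(shared, ta$gene)]
  y <- tb$log2fc[match(shared, tb$gene)]
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate fold-change variance", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method))
  quad <- c(up_up = mean(x > 0 & y > 0), up_down = mean(x > 0 & y < 0),
            down_up = mean(x < 0 & y > 0), down_down = mean(x < 0 & y < 0))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       quadrants = quad)
}

#' Overlap of top-k gene lists (one-sided Fisher test)
#'
#' Takes the top k genes by signed log2 fold change from each result
#' (descending for `direction = "up"`, ascending for `"down"`) over the shared
#' detectable universe and tests their overlap for enrichment.
#'
#' @param deA,deB `de_result` objects (or tables).
#' @param k list size (default 100).
#' @param direction `"up"` or `"down"`.
#' @return list: `overlap`, `expected`, `p` (one-sided hypergeometric),
#'   `genes` (overlapping genes).
#' @export
top_k_overlap <- function(deA, deB, k = 100L, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ta <- de_table(deA); tb <- de_table(deB)
  shared <- intersect(ta$gene[ta$detected], tb$gene[tb$detected])
  if (length(shared) < 2 * k) stop("k exceeds half the shared universe", call. = FALSE)
  pick_top <- function(tt) {
    tt <- tt[match(shared, tt$gene), ]
    ord <- if (direction == "up") order(-tt$log2fc, tt$gene) else order(tt$log2fc, tt$gene)
    tt$gene[ord][seq_len(k)]
  }
  topA <- pick_top(ta)
  topB <- pick_top(tb)
  ov <- intersect(topA, topB)
  N <- length(shared)
  p <- phyper(length(ov) - 1, k, N - k, k, lower.tail = FALSE)
  list(overlap = length(ov), expected = k^2 / N, p = p, genes = sort(ov))
}
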
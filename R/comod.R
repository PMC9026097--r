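#' Module detection parameters
#'
#' @param min_module_size smallest accepted module (default 25).
#' @param prune_depth relative height-gap a branch must show against its parent
#'   merge to be accepted as a module (default 0.15); larger values prune more
#'   aggressively.
#' @param rs_edge_threshold signed Spearman threshold for medoid-network edges
#'   (default 0.80).
#' @return list of class `module_params`.
#' @export
module_params <- function(min_module_size = 25L, prune_depth = 0.15,
                          rs_edge_threshold = 0.80) {
  stopifnot_param(min_module_size >= 2, "min_module_size must be >= 2")
  stopifnot_param(prune_depth > 0 && prune_depth < 1, "prune_depth must be in (0, 1)")
  stopifnot_param(rs_edge_threshold > 0 && rs_edge_threshold <= 1,
                  "rs_edge_threshold must be in (0, 1]")
  structure(list(min_module_size = as.integer(min_module_size),
                 prune_depth = prune_depth,
                 rs_edge_threshold = rs_edge_threshold),
            class = "module_params")
}

#' Standardize a reference expression matrix gene-wise
#'
#' Centers and scales each gene to mean 0, SD 1 (n-1 denominator) across the
#' reference samples. Constant genes cannot be scaled; they are dropped and
#' recorded in the `constant_genes` attribute.
#'
#' @param ref_matrix genes x samples numeric matrix, >= 2 samples.
#' @return the standardized matrix with attribute `constant_genes`.
#' @export
standardize_reference <- function(ref_matrix) {
  if (ncol(ref_matrix) < 2) stop("need >= 2 reference samples", call. = FALSE)
  sds <- apply(ref_matrix, 1, sd)
  if (all(sds == 0)) stop("all genes are constant; nothing to standardize", call. = FALSE)
  keep <- sds > 0
  z <- (ref_matrix[keep, , drop = FALSE] - rowMeans(ref_matrix[keep, , drop = FALSE])) /
    sds[keep]
  attr(z, "constant_genes") <- rownames(ref_matrix)[!keep]
  z
}

#' Detect co-expression modules by variable-height dendrogram pruning
#'
#' Genes are clustered with Euclidean distance and average linkage; the
#' dendrogram is then pruned top-down. A branch is accepted as a module when it
#' has at least `min_module_size` leaves and its own (internal) merge height
#' drops by at least a fraction `prune_depth` relative to its attachment
#' height — the height at which its lineage last joined a substantial sibling
#' (one with at least `min_module_size` leaves). Skipping insubstantial
#' siblings makes the criterion robust to straggler genes that chain onto a
#' tight branch just below the top of the tree: co-expressed blocks complete
#' their internal merges well below where they attach to the background, while
#' branches of pure noise complete only marginally below it. The coarsest
#' qualifying branch wins; leaves under no qualifying branch stay unassigned
#' (module 0).
#'
#' @param z_matrix standardized genes x samples matrix
#'   (see [standardize_reference()]).
#' @param params a [module_params()].
#' @return list of class `module_set` with `assignment` (named integer vector,
#'   0 = unassigned), `sizes`, and `params`.
#' @export
detect_modules <- function(z_matrix, params = module_params()) {
  genes <- rownames(z_matrix)
  n <- length(genes)
  assignment <- setNames(integer(n), genes)
  if (n < params$min_module_size) {
    return(structure(list(assignment = assignment, sizes = integer(0),
                          params = params), class = "module_set"))
  }
  hc <- hclust(dist(z_matrix, method = "euclidean"), method = "average")
  n_nodes <- nrow(hc$merge)
  members <- vector("list", n_nodes)
  size <- integer(n_nodes)
  node_leaves <- function(k) if (k < 0) -k else members[[k]]
  for (i in seq_len(n_nodes)) {
    members[[i]] <- c(node_leaves(hc$merge[i, 1]), node_leaves(hc$merge[i, 2]))
    size[i] <- length(members[[i]])
  }
  node_height <- function(k) if (k < 0) 0 else hc$height[k]

  node_size <- function(k) if (k < 0) 1L else size[k]

  modules <- list()
  # stack of (internal-node index, attachment height) pairs to descend into
  stack_node <- n_nodes
  stack_attach <- hc$height[n_nodes]
  while (length(stack_node)) {
    i <- length(stack_node)
    v <- stack_node[i]
    attach_v <- stack_attach[i]
    stack_node <- stack_node[-i]
    stack_attach <- stack_attach[-i]
    hv <- hc$height[v]
    kids <- hc$merge[v, ]
    for (j in 1:2) {
      c_idx <- kids[j]
      if (c_idx < 0) next
      sib_size <- node_size(kids[3 - j])
      attach_c <- if (sib_size >= params$min_module_size) hv else attach_v
      gap <- if (attach_c > 0) (attach_c - node_height(c_idx)) / attach_c else 0
      if (gap >= params$prune_depth && size[c_idx] >= params$min_module_size) {
        modules[[length(modules) + 1L]] <- members[[c_idx]]
      } else {
        stack_node <- c(stack_node, c_idx)
        stack_attach <- c(stack_attach, attach_c)
      }
    }
  }
  if (length(modules)) {
    modules <- modules[order(-lengths(modules))]
    for (m in seq_along(modules)) assignment[modules[[m]]] <- m
  }
  structure(list(assignment = assignment, sizes = lengths(modules),
                 params = params), class = "module_set"
  )
}

#' Label modules by their most-annotated member gene
#'
#' Label = `<gene>-<size>` where the gene carries the largest annotation-term
#' count among members (missing genes count 0, ties break lexicographically).
#' Identical labels across modules are disambiguated with a numeric suffix.
#'
#' @param module_set a `module_set` from [detect_modules()].
#' @param go_term_counts named numeric vector, gene -> annotation-term count.
#' @return the `module_set` with a `labels` element (module id -> label).
#' @export
label_modules <- function(module_set, go_term_counts) {
  asg <- module_set$assignment
  ids <- sort(unique(asg[asg > 0]))
  labels <- character(length(ids))
  for (i in seq_along(ids)) {
    mem <- sort(names(asg)[asg == ids[i]])
    cnt <- go_term_counts[mem]
    cnt[is.na(cnt)] <- 0
    top <- mem[order(-cnt, mem)][1L]
    labels[i] <- paste0(top, "-", length(mem))
  }
  dup <- duplicated(labels) | duplicated(labels, fromLast = TRUE)
  if (any(dup)) {
    for (lb in unique(labels[dup])) {
      k <- which(labels == lb)
      labels[k] <- paste0(lb, ".", seq_along(k))
    }
  }
  module_set$labels <- setNames(labels, ids)
  module_set
}

#' Module medoids
#'
#' The medoid of a module is the member gene whose standardized profile
#' minimizes the summed Euclidean distance to all other members.
#'
#' @param z_matrix standardized genes x samples matrix.
#' @param module_set a `module_set`.
#' @return the `module_set` with a `medoids` element (module id -> gene).
#' @export
module_medoids <- function(z_matrix, module_set) {
  asg <- module_set$assignment
  ids <- sort(unique(asg[asg > 0]))
  medoids <- character(length(ids))
  for (i in seq_along(ids)) {
    mem <- names(asg)[asg == ids[i]]
    if (length(mem) == 1L) {
      medoids[i] <- mem
    } else {
      dm <- as.matrix(dist(z_matrix[mem, , drop = FALSE]))
      sums <- rowSums(dm)
      medoids[i] <- mem[order(sums, mem)][1L]
    }
  }
  module_set$medoids <- setNames(medoids, ids)
  module_set
}

#' Mean log2 fold change of module members
#'
#' @param de a `de_result` (or table) covering the module genes.
#' @param module_set a `module_set`.
#' @return named numeric vector, module id -> mean member log2fc.
#' @export
module_mean_fc <- function(de, module_set) {
  tab <- de_table(de)
  asg <- module_set$assignment
  ids <- sort(unique(asg[asg > 0]))
  vapply(as.character(ids), function(i) {
    mem <- names(asg)[asg == as.integer(i)]
    mean(tab$log2fc[match(mem, tab$gene)], na.rm = TRUE)
  }, numeric(1))
}

#' Medoid correlation network
#'
#' Undirected edges connect module pairs whose medoid profiles have a signed
#' Spearman correlation at or above the threshold. Vertex values carry the mean
#' member log2 fold change; an edge's value is the mean of its two vertices.
#'
#' @param medoid_profiles modules x samples matrix of medoid profiles
#'   (rownames = module ids or labels).
#' @param module_fc named numeric vector of mean member log2fc per module
#'   (see [module_mean_fc()]).
#' @param params a [module_params()] (uses `rs_edge_threshold`).
#' @return list with `vertices` (data.frame: module, mean_fc) and `edges`
#'   (data.frame: from, to, r_s, edge_fc).
#' @export
module_network <- function(medoid_profiles, module_fc, params = module_params()) {
  if (nrow(medoid_profiles) < 2) stop("need >= 2 modules for a network", call. = FALSE)
  ids <- rownames(medoid_profiles)
  r <- cor(t(medoid_profiles), method = "spearman")
  # small tolerance so exact-boundary correlations (r_s = threshold) keep
  # their edge despite floating-point rank arithmetic
  pairs <- which(upper.tri(r) & r >= params$rs_edge_threshold - 1e-9, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[pairs[, 1L]],
    to = ids[pairs[, 2L]],
    r_s = r[pairs],
    stringsAsFactors = FALSE
  )
  edges$edge_fc <- (module_fc[edges$from] + module_fc[edges$to]) / 2
  list(vertices = data.frame(module = ids, mean_fc = module_fc[ids],
                             stringsAsFactors = FALSE),
       edges = edges)
}

# Two-sided rank-sum p for members vs the rest, given midranks over all genes.
# Normal approximation with tie correction and continuity correction.
ranksum_p_approx <- function(rank_all, member_idx, tie_term) {
  N <- length(rank_all)
  k <- length(member_idx)
  W <- sum(rank_all[member_idx])
  mu <- k * (N + 1) / 2
  sigma2 <- k * (N - k) / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

#' Differential module expression test
#'
#' Per module, a two-sample Wilcoxon rank-sum test of the members' log2 fold
#' changes against all other detectable genes, BH-adjusted across modules. The
#' normal approximation (tie- and continuity-corrected) is used except for very
#' small modules (<= 10 detectable members), where the exact distribution is
#' used.
#'
#' @param de a `de_result` (or table) over the detectable universe.
#' @param module_set a `module_set`.
#' @param alpha_fdr DEM significance cutoff recorded in the result
#'   (default 0.05).
#' @return data.frame per module: module, n_members, shift (median member
#'   log2fc minus median of the rest), W, p, fdr, direction, significant.
#' @export
dem_test <- function(de, module_set, alpha_fdr = 0.05) {
  tab <- de_table(de)
  tab <- tab[tab$detected, , drop = FALSE]
  fc <- setNames(tab$log2fc, tab$gene)
  asg <- module_set$assignment
  asg <- asg[names(asg) %in% names(fc)]
  ids <- sort(unique(asg[asg > 0]))
  if (!length(ids)) stop("no modules with detectable genes", call. = FALSE)
  rk <- rank(fc)
  tie_counts <- table(fc)
  N <- length(fc)
  tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
  rows <- list()
  for (i in ids) {
    mem <- names(asg)[asg == i]
    mem <- intersect(mem, names(fc))
    if (length(mem) < 2) {
      warning(sprintf("module %d has < 2 detectable members; skipped", i))
      next
    }
    if (length(mem) >= N) stop("module spans the whole universe; test undefined",
                               call. = FALSE)
    idx <- match(mem, names(fc))
    if (length(mem) <= 10) {
      p <- suppressWarnings(
        wilcox.test(fc[idx], fc[-idx], exact = TRUE)$p.value
      )
    } else {
      p <- ranksum_p_approx(rk, idx, tie_term)
    }
    shift <- median(fc[idx]) - median(fc[-idx])
    rows[[length(rows) + 1L]] <- data.frame(
      module = i, n_members = length(mem), shift = shift,
      W = sum(rk[idx]) - length(mem) * (length(mem) + 1) / 2,
      p = p, direction = if (shift >= 0) "up" else "down",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res$significant <- res$fdr < alpha_fdr
  res[, c("module", "n_members", "shift", "W", "p", "fdr", "direction", "significant")]
}
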
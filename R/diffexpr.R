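#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`, used when moment-matching the
#' scaled inverse-chi-square variance prior on the log scale.
#'
#' @param y positive target value.
#' @param tol convergence tolerance (default 1e-8).
#' @return x with `trigamma(x) = y` (capped at 1e6, treated as infinity).
#' @keywords internal
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100) {
  if (y <= 0) return(1e6)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  min(x, 1e6)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching of a scaled inverse-chi-square prior to observed residual
#' variances on the log scale: with `z = log(s^2)` and residual df `d`, the
#' excess of `var(z - digamma(d/2) + log(d/2))` over `trigamma(d/2)` determines
#' the prior df `d0` through a trigamma inversion, and the prior variance
#' `s0^2` from the mean.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_eb_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("all residual variances are zero; prior unidentifiable", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0_half <- trigamma_inverse(evar)
    d0 <- 2 * d0_half
    if (d0 >= 1e6) {
      d0 <- Inf
      s0_sq <- exp(emean)
    } else {
      s0_sq <- exp(emean + digamma(d0_half) - log(d0_half))
    }
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Two-group differential expression with moderated t-statistics
#'
#' Per gene: `log2fc` is the difference of group means (treatment minus
#' control); the pooled residual variance with `d = n_a + n_b - 2` df is shrunk
#' toward an empirical-Bayes prior estimated by [estimate_eb_prior()], giving
#' the posterior variance `(d0*s0^2 + d*s^2) / (d0 + d)` and a moderated t with
#' `d + d0` df (normal when `d0` is infinite).
#'
#' @param matrix genes x samples numeric (log2) matrix.
#' @param group_a_samples treatment sample IDs.
#' @param group_b_samples control sample IDs.
#' @param d0_override optional forced prior df (e.g. `Inf` or `0` for the
#'   ordinary t); the prior variance is still estimated from the data unless
#'   `s0_sq_override` is given too.
#' @param s0_sq_override optional forced prior variance.
#' @return list of class `de_result` with a per-gene data.frame `table`
#'   (gene, log2fc, fc, t, p, fdr, mean_expr, detected) and `prior`
#'   (the [estimate_eb_prior()] output).
#' @export
fit_moderated_t <- function(matrix, group_a_samples, group_b_samples,
                            d0_override = NULL, s0_sq_override = NULL) {
  if (length(group_a_samples) < 2 || length(group_b_samples) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  a <- matrix[, group_a_samples, drop = FALSE]
  b <- matrix[, group_b_samples, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  d <- na + nb - 2
  ma <- rowMeans(a); mb <- rowMeans(b)
  log2fc <- ma - mb
  ssa <- rowSums((a - ma)^2)
  ssb <- rowSums((b - mb)^2)
  s2 <- (ssa + ssb) / d
  prior <- estimate_eb_prior(s2, d)
  if (!is.null(d0_override)) prior$d0 <- d0_override
  if (!is.null(s0_sq_override)) prior$s0_sq <- s0_sq_override
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else (d0 * s0 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log2fc / se, 0)
  df_total <- d + d0
  p <- if (is.infinite(df_total)) {
    2 * pnorm(-abs(t_mod))
  } else {
    2 * pt(-abs(t_mod), df = df_total)
  }
  tab <- data.frame(
    gene = rownames(matrix),
    log2fc = log2fc,
    fc = 2^log2fc,
    t = t_mod,
    p = p,
    fdr = bh_adjust(p),
    mean_expr = (ma * na + mb * nb) / (na + nb),
    detected = TRUE,
    stringsAsFactors = FALSE,
    row.names = rownames(matrix)
  )
  structure(list(table = tab, prior = prior,
                 df_residual = d, n_a = na, n_b = nb),
            class = "de_result")
}

#' DEG calling criteria
#'
#' @param p_max raw-p cutoff for the lenient call (default 0.05).
#' @param fc_up,fc_down linear fold-change gates (defaults 1.25 and 0.80).
#' @param stringent_fdr FDR cutoff for the stringent call (default 0.10).
#' @return list of class `deg_criteria`.
#' @export
deg_criteria <- function(p_max = 0.05, fc_up = 1.25, fc_down = 0.80,
                         stringent_fdr = 0.10) {
  stopifnot_param(fc_up > 1 && fc_down < 1 && fc_down > 0,
                  "need fc_up > 1 > fc_down > 0")
  structure(list(p_max = p_max, fc_up = fc_up, fc_down = fc_down,
                 stringent_fdr = stringent_fdr), class = "deg_criteria")
}

#' Call differentially expressed genes
#'
#' Lenient mode: `p < p_max` with `fc > fc_up` (up) or `fc < fc_down` (down).
#' Stringent mode substitutes `fdr < stringent_fdr` for the raw-p gate. All
#' inequalities are strict; boundary equality is excluded.
#'
#' @param de a `de_result` from [fit_moderated_t()] (or its `table`).
#' @param criteria a [deg_criteria()].
#' @param mode `"lenient"` or `"stringent"`.
#' @return list with character vectors `up` and `down`.
#' @export
call_degs <- function(de, criteria = deg_criteria(), mode = c("lenient", "stringent")) {
  mode <- match.arg(mode)
  tab <- de_table(de)
  sig <- if (mode == "lenient") tab$p < criteria$p_max else tab$fdr < criteria$stringent_fdr
  list(up = tab$gene[sig & tab$fc > criteria$fc_up],
       down = tab$gene[sig & tab$fc < criteria$fc_down])
}

de_table <- function(de) {
  if (inherits(de, "de_result")) de$table else as.data.frame(de)
}

#' Per-gene maximum absolute log2 fold change across comparisons
#'
#' @param de_list list of `de_result` objects over the same gene universe.
#' @return named numeric vector, `max_g |log2fc|` over the comparisons.
#' @export
max_abs_fc <- function(de_list) {
  tabs <- lapply(de_list, de_table)
  genes <- tabs[[1L]]$gene
  for (t2 in tabs[-1L]) {
    if (!identical(sort(t2$gene), sort(genes))) {
      stop("de_list results cover different gene universes", call. = FALSE)
    }
  }
  m <- vapply(tabs, function(tt) abs(tt$log2fc[match(genes, tt$gene)]), numeric(length(genes)))
  setNames(apply(cbind(m), 1, max), genes)
}

#' Treatment arrows in principal-component space
#'
#' PCA on the gene-standardized matrix with samples as observations; one arrow
#' per non-control group from the control centroid (PC1/PC2 bivariate mean) to
#' that group's centroid. Longer arrows correspond to stronger treatment
#' effects; PC sign flips change only the orientation, never the length.
#'
#' @param matrix genes x samples numeric matrix.
#' @param groups named character vector sample -> group.
#' @param control control group label (default `"CTL"`).
#' @return data.frame per treatment: origin/tip coordinates in PC1/PC2 and
#'   arrow `length`.
#' @export
pc_treatment_vectors <- function(matrix, groups, control = "CTL") {
  groups <- groups[colnames(matrix)]
  if (!control %in% groups) stop("control group absent", call. = FALSE)
  sds <- apply(matrix, 1, sd)
  z <- (matrix[sds > 0, , drop = FALSE] - rowMeans(matrix[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  pc <- prcomp(t(z), center = TRUE)
  sc <- pc$x[, 1:2, drop = FALSE]
  centroid <- function(g) colMeans(sc[groups == g, , drop = FALSE])
  ctl <- centroid(control)
  treatments <- setdiff(unique(groups), control)
  out <- lapply(treatments, function(g) {
    tip <- centroid(g)
    data.frame(group = g, x0 = ctl[1], y0 = ctl[2], x1 = tip[1], y1 = tip[2],
               length = sqrt(sum((tip - ctl)^2)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman correlation between two fold-change profiles
#'
#' @param deA,deB `de_result` objects (or tables) sharing detectable genes.
#' @return list with `r_s`, `p`, and `n` (shared genes used).
#' @export
fc_scatter_stats <- function(deA, deB) {
  ta <- de_table(deA); tb <- de_table(deB)
  shared <- intersect(ta$gene[ta$detected], tb$gene[tb$detected])
  if (length(shared) < 3) stop("need >= 3 shared detectable genes", call. = FALSE)
  x <- ta$log2fc[match(shared, ta$gene)]
  y <- tb$log2fc[match(shared, tb$gene)]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(r_s = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
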
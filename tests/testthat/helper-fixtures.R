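# Shared helpers for building small fixtures in code.

# Adjusted Rand index between two labelings (0 = unassigned counts as a label).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Small labeled expression matrix: k groups x r replicates, all-null unless
# shifts (named list group -> named gene shift vector) are given.
toy_matrix <- function(n_genes = 50, groups = c("CTL", "TRT"), r = 3,
                       noise_sd = 0.25, shifts = list(), seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- unlist(lapply(groups, function(g) paste0(g, "-", seq_len(r))))
  grp <- setNames(rep(groups, each = r), samples)
  x <- matrix(rnorm(n_genes * length(samples), mean = 7, sd = noise_sd),
              nrow = n_genes, dimnames = list(genes, samples))
  for (g in names(shifts)) {
    sh <- shifts[[g]]
    x[names(sh), grp == g] <- x[names(sh), grp == g] + sh
  }
  expression_matrix(x, grp)
}

# de_result-like table from a named log2fc vector (all detectable, p = NA).
fc_table <- function(log2fc, detected = TRUE) {
  data.frame(gene = names(log2fc), log2fc = unname(log2fc),
             fc = 2^unname(log2fc), t = NA_real_, p = NA_real_, fdr = NA_real_,
             mean_expr = 7, detected = detected, stringsAsFactors = FALSE)
}

demo_pwm <- function(id = "M8") {
  pwm_model(id, rbind(
    A = c(.97, .01, .01, .01, .97, .01, .97, .01),
    C = c(.01, .97, .01, .01, .01, .01, .01, .97),
    G = c(.01, .01, .97, .01, .01, .97, .01, .01),
    T = c(.01, .01, .01, .97, .01, .01, .01, .01)
  ))
}
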
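test_that("probe collapse keeps the highest-mean probe with a stable tie-break", {
  m <- rbind(p1 = c(5, 5, 5), p2 = c(7, 7, 7), q1 = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  map <- c(p1 = "GENE1", p2 = "GENE1", q1 = "GENE2")
  out <- collapse_probes(m, map)
  expect_equal(unname(out$matrix["GENE1", ]), c(7, 7, 7))
  expect_equal(unname(out$matrix["GENE2", ]), c(1, 2, 3))  # single probe unchanged
  expect_identical(out$report$probe_kept[out$report$gene == "GENE1"], "p2")

  # exact tie: smaller probe ID wins, and swapping IDs swaps the winner
  m2 <- rbind(a2 = c(3, 3), a1 = c(3, 3))
  colnames(m2) <- c("s1", "s2")
  out2 <- collapse_probes(m2, c(a2 = "G", a1 = "G"))
  expect_identical(out2$report$probe_kept, "a1")
  expect_true(out2$report$tie)
  rownames(m2) <- c("a1", "a2")
  expect_identical(collapse_probes(m2, c(a1 = "G", a2 = "G"))$report$probe_kept, "a1")

  expect_error(collapse_probes(m, setNames(character(0), character(0))), "empty")
})

test_that("detection filter uses a strict per-array percentile rule", {
  set.seed(1)
  n <- 100
  x <- matrix(rnorm(n * 6, 7), n, 6,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("s%d", 1:6)))
  # g001: above the 20th percentile on exactly 2 arrays, at the minimum elsewhere
  x["g001", ] <- apply(x, 2, min) - 1
  x["g001", 1:2] <- apply(x[, 1:2], 2, max) + 1
  flags <- detection_filter(x, colnames(x))
  expect_true(flags[["g001"]])
  # g002: the minimum on every array -> never detected
  x["g002", ] <- apply(x, 2, min) - 2
  expect_false(detection_filter(x, colnames(x))[["g002"]])
  # degenerate array: all genes identical -> strict ">" detects nothing there
  y <- matrix(5, 10, 6, dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_true(all(!detection_filter(y, colnames(y))))
  expect_error(detection_filter(x, "s1", filter_params(min_detect_samples = 2)),
               "fewer comparison samples")
})

test_that("variability filter drops the low-SD tail and keeps boundary SDs", {
  set.seed(2)
  n <- 100
  x <- matrix(rnorm(n * 12, 7), n, 12,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:12)))
  constant <- sprintf("g%03d", 1:5)  # exactly 5% constant
  x[constant, ] <- 7
  keep <- variability_filter(x)
  expect_identical(sort(names(keep)[!keep]), constant)
  # all genes with equal SD -> none dropped (">=" at the floor)
  y <- matrix(rep(c(1, 2), each = 10), 10, 2,
              dimnames = list(paste0("g", 1:10), c("a", "b")))
  expect_true(all(variability_filter(y)))
  expect_error(variability_filter(x[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("outlier gene exclusion needs both |z| > threshold and a strict extremum", {
  # 12 samples; designated sample CTL-1 is column 1
  base <- c(10, rep(0, 11))
  x <- rbind(
    extreme = base * 1,            # z of CTL-1 large, strict max -> excluded
    tied = c(10, 10, rep(0, 10)),  # not a strict extremum -> retained
    normal = rep(c(0, 1), 6)
  )
  colnames(x) <- c("CTL-1", sprintf("s%02d", 2:12))
  fp <- filter_params(outlier_sample = "CTL-1")
  flags <- outlier_gene_filter(x, fp)
  expect_true(flags[["extreme"]])
  expect_false(flags[["tied"]])
  expect_false(flags[["normal"]])
  expect_warning(out <- outlier_gene_filter(x, filter_params()), "no outlier_sample")
  expect_true(all(!out))
  # z just over 2.50 with a strict max is excluded
  v <- c(rep(0, 11), 1)
  v <- v * 2.51 / abs((1 - mean(v)) / sd(v)) * abs((1 - mean(v)) / sd(v))
  x2 <- matrix(c(8.7, rep(0, 11)), 1, dimnames = list("g", colnames(x)))
  z1 <- (x2[1, 1] - mean(x2)) / sd(x2)
  expect_gt(z1, 2.50)
  expect_true(outlier_gene_filter(x2, fp)[["g"]])
})

test_that("filter report flags are consistent and filters commute", {
  p <- sim_params(n_genes = 300, seed = 31)
  e <- simulate_experiment(p)
  g <- sample_groups(e$matrix)
  cmp <- names(g)[g %in% c("CTL", "IDMF")]
  fp <- filter_params(outlier_sample = "CTL-1")
  rep_ <- filter_report(unclass(e$matrix), cmp, fp)
  expect_identical(rep_$retained,
                   rep_$detected & rep_$variable & !rep_$outlier_excluded)
  expect_equal(unname(rep_$counts["retained"]), sum(rep_$retained))
  # flags are computed independently per gene, so order of application is moot
  d1 <- detection_filter(unclass(e$matrix), cmp, fp)
  v1 <- variability_filter(unclass(e$matrix), fp)
  expect_identical(sum(d1 & v1), sum(v1 & d1))
})

test_that("Grubbs test matches its closed form and a Monte-Carlo null", {
  x <- c(-1, 0, 1, 10)
  g <- grubbs_test(x)
  expect_equal(g$G, (10 - mean(x)) / sd(x))
  # G = 1.4805 sits just under its n = 4 algebraic maximum of 1.5; the exact
  # two-sided p is 0.0523 (Monte-Carlo verified below), marginally non-significant
  expect_lt(g$p, 0.06)
  expect_gt(g$p, 0.04)
  expect_identical(g$which, 4L)
  # symmetric scores: no outlier
  expect_gt(grubbs_test(c(-2, -1, 1, 2))$p, 0.5)
  # p-value calibration against a 100,000-draw null at n = 12
  set.seed(99)
  n <- 12
  draws <- matrix(rnorm(1e5 * n), ncol = n)
  mu <- rowMeans(draws)
  sds <- sqrt(rowSums((draws - mu)^2) / (n - 1))
  G_null <- apply(abs(draws - mu) / sds, 1, max)
  for (a in c(3, 5, 10)) {
    v <- c(rnorm(n - 1), a)
    g_v <- grubbs_test(v)
    p_mc <- mean(G_null >= g_v$G)
    expect_lt(abs(g_v$p - p_mc), 0.01)
  }
})

test_that("PCA outlier screen finds a planted extreme sample", {
  p <- sim_params(n_genes = 400, effect_fraction_per_group = c(MMF = 0, DRF = 0, IDMF = 0),
                  seed = 17)
  e <- simulate_experiment(p)
  x <- unclass(e$matrix)
  x[, "MMF-2"] <- x[, "MMF-2"] + 10 * 0.25  # 10-SD global shift
  res <- sample_pca_outlier_test(x)
  expect_identical(res$outlier_sample, "MMF-2")
  expect_lt(res$p, 0.05)
  expect_error(sample_pca_outlier_test(x[, 1:2]), ">= 3 samples")
})

test_that("sample clustering follows average-linkage geometry", {
  # identical samples merge first at height 0
  x <- cbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  rownames(x) <- c("g1", "g2")
  hc <- cluster_samples(x)
  expect_equal(hc$height[1], 0)
  # mutual distances 1, 1, 2: the distance-1 pair merges first
  y <- cbind(s1 = 0, s2 = 1, s3 = -1)
  rownames(y) <- "g"
  hc2 <- cluster_samples(y)
  first <- sort(hc2$labels[-hc2$merge[1, ]])
  expect_true(identical(first, c("s1", "s2")) || identical(first, c("s1", "s3")))
  expect_equal(hc2$height[1], 1)
  # planted group structure: replicates co-cluster
  p <- sim_params(n_genes = 500, effect_size_log2 = 2, seed = 23)
  e <- simulate_experiment(p)
  hc3 <- cluster_samples(unclass(e$matrix))
  k4 <- cutree(hc3, k = 4)
  g <- sample_groups(e$matrix)
  expect_equal(ari(k4, g[names(k4)]), 1)
})
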
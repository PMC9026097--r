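# two-sided Fisher oracle: sum of hypergeometric point probabilities <= observed
fisher_two_sided_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("direction test matches the exact hypergeometric oracle", {
  set.seed(61)
  # planted: signature with 8 up / 2 down against a balanced background
  fc <- c(rep(1, 8), rep(-1, 2), rnorm(10000))
  names(fc) <- sprintf("g%05d", seq_along(fc))
  sig <- signature_set("S", names(fc)[1:10], "up")
  res <- direction_fisher(fc_table(fc), sig)
  n_up_bg <- sum(fc[-(1:10)] > 0); n_dn_bg <- sum(fc[-(1:10)] < 0)
  expect_equal(res$fisher_p, fisher_two_sided_oracle(8, 2, n_up_bg, n_dn_bg),
               tolerance = 1e-9)
  expect_equal(res$frac_up, 0.8)
  expect_equal(res$frac_up + res$frac_down, 1)

  # all-up signature: extreme table still returns a valid p and OR convention
  sig2 <- signature_set("S2", names(fc)[1:8], "up")
  res2 <- direction_fisher(fc_table(fc), sig2)
  expect_true(res2$fisher_p > 0 && res2$fisher_p <= 1)
  expect_equal(res2$frac_up, 1)

  # zero-FC members are dropped from fractions but counted
  fc2 <- c(a = 0, b = 1, c = -1, d = 2, e = -2, f = 0.5)
  res3 <- direction_fisher(fc_table(fc2), signature_set("Z", c("a", "b", "c")))
  expect_equal(res3$n_zero_fc, 1)
  expect_equal(res3$frac_up + res3$frac_down, 1)
  expect_error(direction_fisher(fc_table(fc2), signature_set("W", "nope")),
               "detectable")
})

test_that("the area statistic is extreme at the top, zero when interleaved, antisymmetric", {
  n <- 1000; m <- 50
  fc <- seq(n, 1) / n  # strictly decreasing, gene g0001 ranked first
  names(fc) <- sprintf("g%04d", 1:n)
  top_sig <- signature_set("TOP", names(fc)[1:m])
  res_top <- cumulative_overlap_area(fc_table(fc), top_sig)
  # closed form when members occupy exactly the top m ranks
  curve <- pmin(1:n / m, 1) - (1:n) / n
  expect_equal(res_top$area, mean(curve))
  expect_gt(res_top$area, 0)
  expect_lte(res_top$area, 0.5)

  # uniformly interleaved members: |area| small
  every <- signature_set("EVERY", names(fc)[seq(10, n, by = 20)])
  expect_lt(abs(cumulative_overlap_area(fc_table(fc), every)$area), 0.02)

  # reversing the ranking flips the sign exactly
  set.seed(62)
  fc_r <- setNames(rnorm(n), names(fc))
  sig <- signature_set("S", sample(names(fc), 100))
  a1 <- cumulative_overlap_area(fc_table(fc_r), sig)$area
  a2 <- cumulative_overlap_area(fc_table(-fc_r), sig)$area
  expect_equal(a1, -a2, tolerance = 1e-12)

  expect_error(cumulative_overlap_area(fc_table(fc), signature_set("U", names(fc))),
               "whole universe")
})

test_that("direction and area statistics agree in sign on planted splits", {
  set.seed(63)
  agree <- vapply(1:50, function(i) {
    fc <- rnorm(2000, sd = 0.3)
    names(fc) <- sprintf("g%04d", seq_along(fc))
    mem <- sample(names(fc), 50)
    up <- sample(mem, 35)  # planted 70/30 up split
    fc[up] <- abs(fc[up]) + 0.2
    fc[setdiff(mem, up)] <- -abs(fc[setdiff(mem, up)])
    tab <- fc_table(fc)
    sig <- signature_set("S", mem)
    d <- direction_fisher(tab, sig)
    a <- cumulative_overlap_area(tab, sig)
    sign(d$frac_up - 0.5) == sign(a$area)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("annotation enrichment equals the hypergeometric tail sum", {
  universe <- sprintf("g%02d", 1:20)
  degs <- universe[1:5]
  terms <- list(T1 = universe[c(1:4, 10)],  # overlap 4 of term size 5
                T2 = universe[6:10],        # overlap 0 -> skipped
                T3 = degs)                  # identical to the DEG set
  res <- annotation_enrichment(degs, universe, terms)
  oracle <- sum(choose(5, 4:5) * choose(15, 5 - (4:5))) / choose(20, 5)
  expect_equal(res$p[res$term == "T1"], oracle, tolerance = 1e-12)
  expect_false("T2" %in% res$term)
  expect_equal(res$overlap[res$term == "T3"], 5)
  expect_equal(res$p[res$term == "T3"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_warning(annotation_enrichment(degs, universe, list(BAD = "zzz")),
                 "disjoint")
  expect_error(annotation_enrichment("zzz", universe, terms), "subset")
})

test_that("disease source aggregation partitions genes into tiers", {
  src <- list(s1 = c("a", "b"), s2 = c("a", "c"), s3 = c("a"), s4 = c("a"),
              s5 = c("a"), s6 = c("a"), s7 = c("a", "d"))
  dt <- aggregate_disease_sources(src)
  tiers <- setNames(dt$table$tier, dt$table$gene)
  expect_equal(tiers[["a"]], 7L)
  expect_equal(tiers[["d"]], 1L)
  expect_equal(sum(dt$tier_counts), nrow(dt$table))
  expect_identical(disease_genes_at_tier(dt, 6), "a")
  expect_error(aggregate_disease_sources(list()), ">= 1 source")
})

test_that("the random-set |FC| null uses the add-one estimator and a fixed seed", {
  set.seed(64)
  fc <- rnorm(1000)
  names(fc) <- sprintf("g%04d", seq_along(fc))
  tab <- fc_table(fc)
  # extreme target: the k genes with the largest |fc|
  target <- names(sort(abs(fc), decreasing = TRUE))[1:20]
  res <- random_set_fc_null(tab, target, n_trials = 200, seed = 9)
  expect_equal(res$p, 1 / 201)
  # determinism
  res2 <- random_set_fc_null(tab, target, n_trials = 200, seed = 9)
  expect_identical(res$null, res2$null)
  # n_trials = 1: p is 1/2 or 1
  r1 <- random_set_fc_null(tab, sample(names(fc), 10), n_trials = 1, seed = 2)
  expect_true(r1$p %in% c(1 / 2, 1))
  expect_error(random_set_fc_null(tab, "zzz"), "detectable")
})

test_that("fold-change vector correlation reports quadrants", {
  set.seed(65)
  fc <- rnorm(500)
  names(fc) <- sprintf("g%03d", seq_along(fc))
  ta <- fc_table(fc)
  anti <- fc_table(setNames(-fc, names(fc)))
  res <- fc_vector_correlation(ta, anti, method = "pearson")
  expect_equal(res$r, -1)
  expect_equal(unname(res$quadrants["up_down"] + res$quadrants["down_up"]), 1)
  expect_error(fc_vector_correlation(ta, fc_table(setNames(rep(0, 500), names(fc)))),
               "degenerate")
})

test_that("top-k overlap matches the hypergeometric oracle and its expectation", {
  set.seed(66)
  n <- 2000; k <- 100
  fc <- setNames(rnorm(n), sprintf("g%04d", 1:n))
  ta <- fc_table(fc)
  self <- top_k_overlap(ta, ta, k = k)
  expect_equal(self$overlap, k)
  # independent rankings: observed overlap near k^2/N on average
  ov <- vapply(1:30, function(i) {
    tb <- fc_table(setNames(rnorm(n), names(fc)))
    top_k_overlap(ta, tb, k = k)$overlap
  }, numeric(1))
  expect_lt(abs(mean(ov) - k^2 / n), 1.5)
  # p equals the one-sided hypergeometric tail for the same table
  tb <- fc_table(setNames(rnorm(n), names(fc)))
  res <- top_k_overlap(ta, tb, k = k)
  expect_equal(res$p, phyper(res$overlap - 1, k, n - k, k, lower.tail = FALSE))
  expect_error(top_k_overlap(ta, tb, k = 1500), "half the shared universe")
})
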
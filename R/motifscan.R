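#' Position weight matrix model
#'
#' Per-position nucleotide probabilities over A/C/G/T with a pseudocount and a
#' background distribution. Scores are log2 odds against the background;
#' ambiguous bases (N) contribute 0.
#'
#' @param id PWM identifier.
#' @param mat 4 x width matrix (rows A, C, G, T) of probabilities or counts;
#'   columns are normalized after adding `pseudocount`.
#' @param pseudocount added to every cell before normalization (default 0.01).
#' @param background length-4 background frequencies (default uniform).
#' @return object of class `pwm_model` with elements `id`, `prob`, `logodds`,
#'   `width`, `background`, `max_score`.
#' @export
pwm_model <- function(id, mat, pseudocount = 0.01, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(mat) < 4) stop("PWM width must be >= 4", call. = FALSE)
  if (any(mat < 0)) stop("PWM entries must be nonnegative", call. = FALSE)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 frequencies summing to 1", call. = FALSE)
  }
  p <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  stopifnot(all(abs(colSums(p) - 1) < 1e-9))
  rownames(p) <- c("A", "C", "G", "T")
  rownames(mat) <- c("A", "C", "G", "T")
  lo <- log2(p / background)
  structure(list(id = id, raw = mat, prob = p, logodds = lo, width = ncol(p),
                 background = background, pseudocount = pseudocount,
                 max_score = sum(apply(lo, 2, max))),
            class = "pwm_model")
}

#' @rdname pwm_model
#' @param pwm a `pwm_model`.
#' @return `pwm_consensus()`: the consensus string (argmax base per column).
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_model"))
  paste(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Read / write PWMs in a simple 4-row text format
#'
#' Each record is an ID header line (optionally prefixed with `>`) followed by
#' four whitespace-delimited numeric rows in A, C, G, T order. Several records
#' may share one file.
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm_model()].
#' @return a named list of [pwm_model()] objects.
#' @export
read_pwm <- function(path, pseudocount = 0.01, background = rep(0.25, 4)) {
  tx <- read_text_lines(path)
  lines <- trimws(tx$lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  numbers <- tx$numbers[keep]
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    id <- sub("^>", "", lines[i])
    if (i + 4L > length(lines) + 1L || (i + 4L - 1L) > length(lines)) {
      format_error(path, numbers[i], "PWM record needs 4 numeric rows after the ID")
    }
    rows <- lapply(1:4, function(k) {
      v <- suppressWarnings(as.numeric(strsplit(lines[i + k], "\\s+")[[1L]]))
      if (anyNA(v)) format_error(path, numbers[i + k], "non-numeric PWM row")
      v
    })
    if (length(unique(lengths(rows))) != 1L) {
      format_error(path, numbers[i + 1L], "PWM rows have unequal lengths")
    }
    pwms[[id]] <- pwm_model(id, do.call(rbind, rows),
                            pseudocount = pseudocount, background = background)
    i <- i + 5L
  }
  pwms
}

#' @rdname read_pwm
#' @param pwms named list of [pwm_model()] objects.
#' @export
write_pwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header(), con)
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    # emit the raw (pre-pseudocount) matrix so read_pwm reconstructs the model
    for (k in 1:4) {
      writeLines(paste(format(p$raw[k, ], digits = 15, trim = TRUE,
                              scientific = FALSE), collapse = " "), con)
    }
  }
  invisible(path)
}

encode_dna <- function(sequence) {
  s <- toupper(as.character(sequence))
  v <- utf8ToInt(s)
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 1L
  code[v == utf8ToInt("C")] <- 2L
  code[v == utf8ToInt("G")] <- 3L
  code[v == utf8ToInt("T")] <- 4L
  code  # N and anything else -> 0
}

score_windows <- function(code, lo) {
  w <- ncol(lo)
  nw <- length(code) - w + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  for (j in seq_len(w)) {
    v <- code[j:(j + nw - 1L)]
    ok <- v > 0L
    contrib <- numeric(nw)
    contrib[ok] <- lo[cbind(v[ok], j)]
    s <- s + contrib
  }
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Log2-odds scoring against the PWM background; N bases contribute 0. The hit
#' threshold defaults to 80% of the maximal achievable score. Reverse-strand
#' windows are reported by the 0-based start of the window on the forward
#' sequence.
#'
#' @param sequence character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param pwm a [pwm_model()].
#' @param threshold_frac hit threshold as a fraction of the maximal achievable
#'   score (default 0.8).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return list with `max_score`, `hits` (data.frame: pos, strand, score) and
#'   `n_hits`. A sequence shorter than the PWM width gives `max_score = -Inf`
#'   and zero hits.
#' @export
pwm_scan <- function(sequence, pwm, threshold_frac = 0.8, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm_model"))
  s <- as.character(sequence)
  code <- encode_dna(s)
  w <- pwm$width
  thr <- threshold_frac * pwm$max_score
  fwd <- score_windows(code, pwm$logodds)
  if (length(fwd) == 0L) {
    return(list(max_score = -Inf,
                hits = data.frame(pos = integer(0), strand = character(0),
                                  score = numeric(0)),
                n_hits = 0L))
  }
  hits <- data.frame(pos = which(fwd >= thr) - 1L,
                     strand = rep("+", sum(fwd >= thr)),
                     score = fwd[fwd >= thr])
  max_score <- max(fwd)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- score_windows(encode_dna(rc), pwm$logodds)
    len <- nchar(s)
    idx <- which(rev >= thr)
    if (length(idx)) {
      hits <- rbind(hits, data.frame(pos = len - w - (idx - 1L),
                                     strand = "-", score = rev[idx]))
    }
    max_score <- max(max_score, rev)
  }
  hits <- hits[order(hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(max_score = max_score, hits = hits, n_hits = nrow(hits))
}

#' Per-gene motif features over a promoter set
#'
#' Runs [pwm_scan()] on every promoter and returns hit counts (default) or the
#' maximal log-odds score per gene, plus the GC fraction covariate.
#'
#' @param promoters named [Biostrings::DNAStringSet].
#' @param pwms named list of [pwm_model()] objects.
#' @param feature `"count"` (hits at the threshold) or `"score"` (max score).
#' @param threshold_frac passed to [pwm_scan()].
#' @return list with `features` (genes x PWMs matrix), `gc` (named vector),
#'   `hit_positions` (list of per-PWM 0-based hit position vectors).
#' @export
motif_features <- function(promoters, pwms, feature = c("count", "score"),
                           threshold_frac = 0.8) {
  feature <- match.arg(feature)
  genes <- names(promoters)
  feats <- matrix(0, nrow = length(genes), ncol = length(pwms),
                  dimnames = list(genes, names(pwms)))
  pos <- setNames(vector("list", length(pwms)), names(pwms))
  seq_chr <- as.character(promoters)
  for (k in seq_along(pwms)) {
    acc <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      sc <- pwm_scan(seq_chr[[i]], pwms[[k]], threshold_frac = threshold_frac)
      feats[i, k] <- if (feature == "count") sc$n_hits else sc$max_score
      acc[[i]] <- sc$hits$pos
    }
    pos[[k]] <- unlist(acc)
  }
  gc <- Biostrings::letterFrequency(promoters, "GC", as.prob = TRUE)[, 1L]
  list(features = feats, gc = setNames(gc, genes), hit_positions = pos)
}

spline_basis <- function(x) {
  kn <- unique(quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7))
  kn <- kn[kn > min(x) & kn < max(x)]
  splines::bs(x, knots = kn, degree = 3)
}

ridge_logistic <- function(X, y, lambda = 1e-4, tol = 1e-8, max_iter = 100) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wv <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * Wv) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  list(beta = beta, loglik = ll)
}

#' Motif enrichment among DEGs with spline-adjusted logistic models
#'
#' For each PWM, fits `logit P(DEG) = beta * feature + s(gc) [+ s(length)]`
#' where `s()` is a fixed-knot cubic B-spline (unpenalized, interior knots at
#' covariate quintiles), and tests `beta = 0` by a 1-df likelihood-ratio test.
#' P-values are BH-adjusted across PWMs. Cases of quasi-separation are refit
#' with a small ridge penalty and flagged.
#'
#' @param deg_flags named 0/1 vector over the gene universe.
#' @param motif_feature named numeric vector (one PWM) or genes x PWMs matrix
#'   from [motif_features()].
#' @param covariates data.frame with at least a `gc` column and optionally
#'   `length` (rownames = genes), or a named `gc` vector.
#' @return data.frame per PWM: `pwm`, `beta`, `lrt_p`, `fdr`, `direction`,
#'   `separation`.
#' @export
gam_motif_enrichment <- function(deg_flags, motif_feature, covariates) {
  if (is.numeric(covariates)) covariates <- data.frame(gc = covariates)
  if (is.null(dim(motif_feature))) {
    motif_feature <- matrix(motif_feature, ncol = 1,
                            dimnames = list(names(motif_feature), "motif"))
  }
  genes <- rownames(motif_feature)
  y <- deg_flags[genes]
  if (anyNA(y)) stop("deg_flags must cover every gene in motif_feature", call. = FALSE)
  if (min(sum(y == 1), sum(y == 0)) < 20) {
    stop("need >= 20 genes in each class (DEG and background)", call. = FALSE)
  }
  gc <- covariates$gc
  X0 <- cbind(1, spline_basis(gc))
  if (!is.null(covariates$length) && length(unique(covariates$length)) > 1) {
    X0 <- cbind(X0, spline_basis(covariates$length))
  }
  fit0 <- suppressWarnings(glm.fit(X0, y, family = binomial()))
  ll0 <- -fit0$deviance / 2
  out <- lapply(colnames(motif_feature), function(id) {
    f <- motif_feature[, id]
    if (length(unique(f)) == 1L) {
      stop(sprintf("motif feature for PWM '%s' is constant; beta inestimable", id),
           call. = FALSE)
    }
    X1 <- cbind(X0, motif = as.numeric(scale(f, scale = FALSE)))
    sep <- FALSE
    fit1 <- suppressWarnings(glm.fit(X1, y, family = binomial()))
    beta <- fit1$coefficients[["motif"]]
    ll1 <- -fit1$deviance / 2
    if (!fit1$converged || !is.finite(beta) || abs(beta) > 15) {
      sep <- TRUE
      r0 <- ridge_logistic(X0, y)
      r1 <- ridge_logistic(X1, y)
      beta <- r1$beta[length(r1$beta)]
      ll0_r <- r0$loglik
      p <- pchisq(2 * (r1$loglik - ll0_r), df = 1, lower.tail = FALSE)
    } else {
      p <- pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
    }
    data.frame(pwm = id, beta = beta, lrt_p = p,
               direction = if (beta > 0) "enriched" else "depleted",
               separation = sep, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$fdr <- bh_adjust(res$lrt_p)
  res[, c("pwm", "beta", "lrt_p", "fdr", "direction", "separation")]
}

#' IRF-family motif profile across DEG sets
#'
#' Runs [gam_motif_enrichment()] for each PWM in each DEG set and, for PWMs
#' reaching the FDR cutoff, histograms hit positions across the promoter window
#' in 250-bp bins.
#'
#' @param deg_sets named list of gene vectors (e.g. increased/decreased DEGs
#'   per compound).
#' @param irf_pwms named list of [pwm_model()] objects.
#' @param promoters named [Biostrings::DNAStringSet] covering the universe.
#' @param fdr_cutoff significance cutoff for the positional histogram
#'   (default 0.05).
#' @param bin_width histogram bin width in bp (default 250).
#' @return list with `enrichment` (data.frame: deg_set x pwm results) and
#'   `position_histograms` (named list of tables for significant PWMs).
#' @export
irf_profile <- function(deg_sets, irf_pwms, promoters, fdr_cutoff = 0.05,
                        bin_width = 250L) {
  feats <- motif_features(promoters, irf_pwms)
  universe <- names(promoters)
  tabs <- lapply(names(deg_sets), function(nm) {
    flags <- setNames(as.integer(universe %in% deg_sets[[nm]]), universe)
    res <- gam_motif_enrichment(flags, feats$features, data.frame(gc = feats$gc))
    res$deg_set <- nm
    res
  })
  enrich <- do.call(rbind, tabs)
  sig <- unique(enrich$pwm[enrich$fdr < fdr_cutoff])
  width <- max(Biostrings::width(promoters))
  breaks <- seq(0, ceiling(width / bin_width) * bin_width, by = bin_width)
  hists <- setNames(lapply(sig, function(id) {
    pos <- feats$hit_positions[[id]]
    table(cut(pos, breaks = breaks, right = FALSE))
  }), sig)
  list(enrichment = enrich, position_histograms = hists)
}
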
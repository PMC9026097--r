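#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores the global `.Random.seed`, so simulator calls are
#' reproducible from their explicit `seed` argument without disturbing (or
#' being disturbed by) the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation parameters
#'
#' Bundles the settings of the synthetic-data generators. Defaults emulate the
#' study design the package targets: a 4-treatment (CTL, MMF, DRF, IDMF)
#' astrocyte experiment with 3 replicates per treatment, log2-scale intensities,
#' and a 24-sample reference set carrying correlated gene modules. The default
#' per-group perturbed fractions are asymmetric (IDMF perturbs the most genes),
#' matching the relative breadth of the three compounds' transcriptomic effects.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_reps_per_group replicates per treatment group (default 3).
#' @param groups ordered treatment labels; the first is the control.
#' @param effect_fraction_per_group named fractions of genes perturbed in each
#'   non-control group.
#' @param effect_size_log2 planted |log2 fold change| of perturbed genes.
#' @param noise_sd per-gene residual standard deviation (log2 scale).
#' @param n_ref_samples number of reference samples for module simulation.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range integer length-2 vector, min/max module size.
#' @param module_signal latent-factor loading of module genes; with residual
#'   SD `noise_sd` the expected within-module Pearson correlation is
#'   `module_signal^2 / (module_signal^2 + noise_sd^2)`.
#' @param seed integer seed; identical parameters give identical output.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_genes = 5000L,
                       n_reps_per_group = 3L,
                       groups = c("CTL", "MMF", "DRF", "IDMF"),
                       effect_fraction_per_group = c(MMF = 0.031, DRF = 0.026, IDMF = 0.109),
                       effect_size_log2 = 1.0,
                       noise_sd = 0.25,
                       n_ref_samples = 24L,
                       n_modules = 8L,
                       module_size_range = c(25L, 196L),
                       module_signal = 0.6,
                       seed = 1L) {
  p <- list(
    n_genes = as.integer(n_genes),
    n_reps_per_group = as.integer(n_reps_per_group),
    groups = as.character(groups),
    effect_fraction_per_group = effect_fraction_per_group,
    effect_size_log2 = effect_size_log2,
    noise_sd = noise_sd,
    n_ref_samples = as.integer(n_ref_samples),
    n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    module_signal = module_signal,
    seed = as.integer(seed)
  )
  stopifnot_param(p$n_genes > 0, "n_genes must be > 0")
  stopifnot_param(p$n_reps_per_group > 0, "n_reps_per_group must be > 0")
  stopifnot_param(length(p$groups) >= 2, "need a control plus at least one treatment")
  stopifnot_param(!anyDuplicated(p$groups), "group labels must be unique")
  non_ctl <- setdiff(p$groups, p$groups[1L])
  if (is.null(names(p$effect_fraction_per_group))) {
    stopifnot_param(length(p$effect_fraction_per_group) == length(non_ctl),
                    "effect_fraction_per_group must be named or match the non-control groups")
    names(p$effect_fraction_per_group) <- non_ctl
  }
  stopifnot_param(all(non_ctl %in% names(p$effect_fraction_per_group)),
                  "effect_fraction_per_group must cover every non-control group")
  p$effect_fraction_per_group <- p$effect_fraction_per_group[non_ctl]
  stopifnot_param(all(p$effect_fraction_per_group >= 0 & p$effect_fraction_per_group <= 1),
                  "effect fractions must lie in [0, 1]")
  stopifnot_param(p$effect_size_log2 >= 0, "effect_size_log2 must be >= 0")
  stopifnot_param(p$noise_sd > 0, "noise_sd must be > 0")
  stopifnot_param(p$n_ref_samples > 0, "n_ref_samples must be > 0")
  stopifnot_param(p$n_modules >= 0, "n_modules must be >= 0")
  stopifnot_param(length(p$module_size_range) == 2 && p$module_size_range[1] >= 2 &&
                    p$module_size_range[1] <= p$module_size_range[2],
                  "module_size_range must be [min >= 2, max >= min]")
  stopifnot_param(p$module_signal >= 0, "module_signal must be >= 0")
  structure(p, class = "sim_params")
}

stopifnot_param <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid parameters: ", msg, call. = FALSE)
}

gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Construct an expression matrix with group labels
#'
#' @param values numeric matrix, genes x samples, log2 intensities, with
#'   row and column names.
#' @param groups named character vector mapping sample -> group.
#' @return the matrix with a `groups` attribute and class `expr_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene IDs in expression matrix", call. = FALSE)
  }
  if (!all(colnames(values) %in% names(groups))) {
    stop("every sample must have a group label", call. = FALSE)
  }
  attr(values, "groups") <- groups[colnames(values)]
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
sample_groups <- function(x) attr(x, "groups")

#' Simulate the four-treatment experiment with planted differential expression
#'
#' Gene baselines are drawn once (log2 intensities, N(7, 1.5)); each
#' non-control group shifts a planted subset of genes by a signed
#' `effect_size_log2`, and i.i.d. Gaussian noise with SD `noise_sd` is added to
#' every cell. The planted up:down split is 2:1 for MMF-style asymmetric
#' effects and balanced otherwise.
#'
#' @param params a [sim_params()] object.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`, whose
#'   `planted_deg_sets` element maps each non-control group to a named sign
#'   vector (+1 up, -1 down).
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    genes <- gene_names(params$n_genes)
    ctl <- params$groups[1L]
    samples <- unlist(lapply(params$groups, function(g) {
      paste0(g, "-", seq_len(params$n_reps_per_group))
    }))
    grp <- rep(params$groups, each = params$n_reps_per_group)
    names(grp) <- samples

    mu <- rnorm(params$n_genes, mean = 7, sd = 1.5)
    x <- matrix(mu, nrow = params$n_genes, ncol = length(samples))
    dimnames(x) <- list(genes, samples)

    planted <- list()
    for (g in setdiff(params$groups, ctl)) {
      n_eff <- round(params$effect_fraction_per_group[[g]] * params$n_genes)
      if (n_eff > 0) {
        idx <- sample.int(params$n_genes, n_eff)
        up_frac <- if (g == "MMF") 2 / 3 else 0.5
        sgn <- ifelse(runif(n_eff) < up_frac, 1, -1)
        shift <- sgn * params$effect_size_log2
        x[idx, grp[samples] == g] <- x[idx, grp[samples] == g] + shift
        planted[[g]] <- setNames(sgn, genes[idx])
      } else {
        planted[[g]] <- setNames(numeric(0), character(0))
      }
    }
    x <- x + matrix(rnorm(length(x), sd = params$noise_sd), nrow = nrow(x))

    truth <- structure(list(planted_deg_sets = planted,
                            params = params),
                       class = "ground_truth")
    list(matrix = expression_matrix(x, grp), truth = truth)
  })
}

#' Simulate the reference sample set with planted co-expression modules
#'
#' Module genes load on a per-module latent factor: for gene g in module m and
#' sample s, `x[g, s] = module_signal * f[m, s] + noise_sd * eps`, so the
#' expected within-module Pearson correlation is
#' `module_signal^2 / (module_signal^2 + noise_sd^2)`. Non-module genes are
#' pure noise. Gene labels are shared with [simulate_experiment()] for the same
#' `n_genes`.
#'
#' @param params a [sim_params()] object.
#' @return list with `matrix` (genes x `n_ref_samples`) and `truth`, whose
#'   `planted_modules` element maps gene -> module id (0 = none).
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_ref_samples < 4) {
    stop("invalid parameters: n_ref_samples must be >= 4", call. = FALSE)
  }
  with_seed(params$seed + 1L, {
    genes <- gene_names(params$n_genes)
    sizes <- if (params$n_modules > 0) {
      sample(seq(params$module_size_range[1], params$module_size_range[2]),
             params$n_modules, replace = TRUE)
    } else {
      integer(0)
    }
    if (sum(sizes) > params$n_genes) {
      stop("invalid parameters: planted module sizes exceed n_genes", call. = FALSE)
    }
    assignment <- setNames(integer(params$n_genes), genes)
    pool <- sample.int(params$n_genes)
    used <- 0L
    for (m in seq_along(sizes)) {
      idx <- pool[(used + 1L):(used + sizes[m])]
      assignment[idx] <- m
      used <- used + sizes[m]
    }
    samples <- sprintf("REF-%02d", seq_len(params$n_ref_samples))
    x <- matrix(rnorm(params$n_genes * params$n_ref_samples, sd = params$noise_sd),
                nrow = params$n_genes, dimnames = list(genes, samples))
    for (m in seq_along(sizes)) {
      f <- rnorm(params$n_ref_samples)
      members <- which(assignment == m)
      x[members, ] <- x[members, ] +
        params$module_signal * matrix(f, nrow = length(members),
                                      ncol = params$n_ref_samples, byrow = TRUE)
    }
    grp <- setNames(rep("REF", length(samples)), samples)
    truth <- structure(list(planted_modules = assignment, module_sizes = sizes,
                            params = params),
                       class = "ground_truth")
    list(matrix = expression_matrix(x, grp), truth = truth)
  })
}

#' Simulate gene coordinates and GWAS-style loci with planted proximity
#'
#' Genes are laid out as non-overlapping intervals (0-based, half-open) along
#' synthetic chromosomes of 200 Mb capacity. A designated subset of genes can
#' have a locus planted within `window` bp of the gene body; the remaining loci
#' are placed uniformly.
#'
#' @param n_genes,n_loci counts of genes and loci.
#' @param planted_fraction fraction of the designated gene list that receives a
#'   nearby locus.
#' @param seed integer seed.
#' @param planted_n size of the designated gene list (default 30, the size of
#'   the top-gene lists used in proximity tests).
#' @param window planting distance bound in bp (default 100 kb).
#' @return list with `genes` (data.frame: chrom, start, end, name, strand),
#'   `loci` (data.frame: chrom, start, end), and `truth` with
#'   `planted_proximal_genes` and `designated_genes`.
#' @export
simulate_genome_and_loci <- function(n_genes, n_loci, planted_fraction, seed,
                                     planted_n = 30L, window = 1e5) {
  stopifnot_param(n_genes > 0 && n_loci >= 0, "counts must be > 0")
  stopifnot_param(planted_fraction >= 0 && planted_fraction <= 1,
                  "planted_fraction must lie in [0, 1]")
  planted_n <- min(as.integer(planted_n), n_genes)
  chrom_capacity <- 2e8
  genes_per_chrom <- 1000L
  with_seed(seed, {
    genes <- gene_names(n_genes)
    n_chrom <- ceiling(n_genes / genes_per_chrom)
    chrom <- rep(sprintf("chr%d", seq_len(n_chrom)),
                 each = genes_per_chrom)[seq_len(n_genes)]
    len <- round(runif(n_genes, 1e3, 5e3))
    gap <- round(runif(n_genes, 5e3, 5e4))
    start <- unlist(lapply(split(seq_len(n_genes), chrom)[unique(chrom)], function(i) {
      cumsum(gap[i]) + c(0, cumsum(len[i]))[seq_along(i)]
    }), use.names = FALSE)
    end <- start + len
    if (any(end > chrom_capacity)) {
      stop("invalid parameters: chromosome capacity exceeded", call. = FALSE)
    }
    gene_df <- data.frame(chrom = chrom, start = start, end = end,
                          name = genes, score = 0L, strand = "+",
                          stringsAsFactors = FALSE)

    designated <- sort(sample(genes, planted_n))
    n_plant <- round(planted_fraction * planted_n)
    if (n_plant > n_loci) {
      stop("invalid parameters: n_loci too small for the planted fraction", call. = FALSE)
    }
    planted_genes <- if (n_plant > 0) sample(designated, n_plant) else character(0)
    loci <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    if (n_plant > 0) {
      gi <- match(planted_genes, gene_df$name)
      d <- round(runif(n_plant, 0, window))
      side <- runif(n_plant) < 0.5
      pos <- ifelse(side, pmax(gene_df$start[gi] - d, 0), gene_df$end[gi] - 1 + d)
      loci <- data.frame(chrom = gene_df$chrom[gi], start = pos, end = pos + 1)
    }
    n_unif <- n_loci - n_plant
    if (n_unif > 0) {
      span <- vapply(split(gene_df$end, gene_df$chrom), max, numeric(1))
      ch <- sample(names(span), n_unif, replace = TRUE)
      pos <- round(runif(n_unif, 0, span[ch]))
      loci <- rbind(loci, data.frame(chrom = ch, start = pos, end = pos + 1))
    }
    rownames(loci) <- NULL
    truth <- structure(list(planted_proximal_genes = sort(planted_genes),
                            designated_genes = designated,
                            window = window),
                       class = "ground_truth")
    list(genes = gene_df, loci = loci, truth = truth)
  })
}

#' Simulate promoter sequences with planted motif instances
#'
#' Each gene receives an i.i.d. background sequence with the requested GC
#' fraction; genes in `plant_in` additionally carry one exact PWM consensus
#' instance at a uniformly drawn, recorded position.
#'
#' @param gene_list character vector of gene IDs (FASTA headers).
#' @param pwm a [pwm_model()] object.
#' @param plant_in subset of `gene_list` whose promoters carry the consensus.
#' @param length promoter length in bp (default 5000, i.e. 5 kb upstream).
#' @param gc background GC fraction (default 0.5).
#' @param seed integer seed.
#' @return list with `sequences` (a named [Biostrings::DNAStringSet]) and
#'   `truth` whose `planted_motif_positions` records 0-based insert positions.
#' @export
simulate_promoters <- function(gene_list, pwm, plant_in = character(0),
                               length = 5000L, gc = 0.5, seed = 1L) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (!all(plant_in %in% gene_list)) {
    stop("invalid parameters: plant_in must be a subset of gene_list", call. = FALSE)
  }
  cons <- pwm_consensus(pwm)
  w <- nchar(cons)
  if (w > length) {
    stop("invalid parameters: consensus longer than sequence", call. = FALSE)
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- vapply(gene_list, function(g) {
      paste(sample(bases, length, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
    pos <- setNames(rep(NA_integer_, length(plant_in)), plant_in)
    for (g in plant_in) {
      p0 <- sample.int(length - w + 1L, 1L) - 1L  # 0-based
      substr(seqs[[g]], p0 + 1L, p0 + w) <- cons
      pos[[g]] <- p0
    }
    truth <- structure(list(planted_motif_genes = plant_in,
                            planted_motif_positions = pos,
                            consensus = cons),
                       class = "ground_truth")
    list(sequences = Biostrings::DNAStringSet(setNames(seqs, gene_list)),
         truth = truth)
  })
}
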
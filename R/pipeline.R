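#' Generate a demo configuration with synthetic inputs
#'
#' Writes a complete set of synthetic input files (experiment matrix, reference
#' matrix, signatures, disease sources, gene/locus BED, promoters, PWMs,
#' annotation term counts) into `dir` and returns the matching run
#' configuration.
#'
#' @param dir output directory (created if needed).
#' @param seed global seed for the generators.
#' @param n_genes universe size (default 2000, large enough for stable
#'   statistics while keeping the demo fast).
#' @return a named list usable as [run_pipeline()] config.
#' @export
demo_config <- function(dir, seed = 1L, n_genes = 2000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- sim_params(n_genes = n_genes, seed = seed, n_modules = 4L,
                       module_size_range = c(25L, max(25L, min(196L, n_genes %/% 8L))))
  exper <- simulate_experiment(params)
  ref <- simulate_reference(params)
  write_expression_tsv(exper$matrix, file.path(dir, "expression.tsv"), seed = seed)
  write_expression_tsv(ref$matrix, file.path(dir, "reference.tsv"), seed = seed)
  grp <- sample_groups(exper$matrix)
  write.table(data.frame(sample = names(grp), group = unname(grp)),
              file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # signatures: planted-direction sets drawn from the IDMF ground truth
  truth <- exper$truth$planted_deg_sets
  sigs <- list(
    signature_set("PLANTED_IDMF_UP", names(truth$IDMF)[truth$IDMF > 0], "up"),
    signature_set("PLANTED_IDMF_DOWN", names(truth$IDMF)[truth$IDMF < 0], "down")
  )
  write_gmt(sigs, file.path(dir, "signatures.gmt"), seed = seed)

  # disease sources: 7 synthetic sources sampling planted + background genes
  genes <- rownames(exper$matrix)
  sources <- with_seed(seed + 2L, {
    lapply(1:7, function(i) {
      base <- sample(genes, 150)
      enriched <- sample(names(truth$IDMF), 30)
      unique(c(base, enriched))
    })
  })
  names(sources) <- paste0("SOURCE", 1:7)
  write_gmt(mapply(signature_set, names(sources), sources,
                   MoreArgs = list(direction = "none"), SIMPLIFY = FALSE),
            file.path(dir, "disease_sources.gmt"), seed = seed)

  gl <- simulate_genome_and_loci(n_genes, n_loci = 60, planted_fraction = 0.5,
                                 seed = seed + 3L)
  write_bed(gl$genes, file.path(dir, "genes.bed"), seed = seed)
  write_bed(gl$loci, file.path(dir, "loci.bed"), seed = seed)

  pwm <- pwm_model("DEMO_MOTIF", rbind(
    A = c(.97, .01, .01, .01, .97, .01, .97, .01),
    C = c(.01, .97, .01, .01, .01, .01, .01, .97),
    G = c(.01, .01, .97, .01, .01, .97, .01, .01),
    T = c(.01, .01, .01, .97, .01, .01, .01, .01)
  ))
  write_pwm(list(pwm), file.path(dir, "pwms.txt"))
  promoter_genes <- with_seed(seed + 4L, sample(genes, 400))
  plant_in <- intersect(promoter_genes, names(truth$IDMF))
  prom <- simulate_promoters(promoter_genes, pwm, plant_in = plant_in,
                             length = 1000L, seed = seed + 5L)
  write_fasta(prom$sequences, file.path(dir, "promoters.fa"))

  go_counts <- with_seed(seed + 6L, setNames(rpois(length(genes), 5), genes))
  write.table(data.frame(gene = names(go_counts), n_terms = unname(go_counts)),
              file.path(dir, "go_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    reference = file.path(dir, "reference.tsv"),
    signatures = file.path(dir, "signatures.gmt"),
    disease_sources = file.path(dir, "disease_sources.gmt"),
    genes_bed = file.path(dir, "genes.bed"),
    loci_bed = file.path(dir, "loci.bed"),
    promoters = file.path(dir, "promoters.fa"),
    pwms = file.path(dir, "pwms.txt"),
    go_counts = file.path(dir, "go_counts.tsv"),
    control = "CTL",
    contrasts = c("MMF", "DRF", "IDMF"),
    outlier_sample = NULL,
    min_module_size = 25,
    fc_trials = 1000,
    distance_trials = 1000,
    top_n = 30,
    seed = seed,
    out_dir = file.path(dir, "results")
  )
}

validate_config <- function(config) {
  file_keys <- c("expression", "groups", "reference", "signatures",
                 "disease_sources", "genes_bed", "loci_bed", "promoters",
                 "pwms", "go_counts")
  for (k in file_keys) {
    if (is.null(config[[k]])) stop(sprintf("config is missing '%s'", k), call. = FALSE)
    if (!file.exists(config[[k]])) {
      stop(sprintf("config file for '%s' does not exist: %s", k, config[[k]]),
           call. = FALSE)
    }
  }
  for (k in c("control", "contrasts", "seed", "out_dir")) {
    if (is.null(config[[k]])) stop(sprintf("config is missing '%s'", k), call. = FALSE)
  }
  invisible(config)
}

write_stage_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stage order: filtering -> differential expression (one contrast per
#' treatment vs control) -> module detection and DEM tests -> signature and
#' disease-gene statistics -> GWAS-locus proximity -> promoter motif
#' enrichment -> summary table. Each stage writes its tables before the next
#' starts; any stage error halts with a stage-named message. The manifest
#' records seeds and MD5 checksums so a re-run with the same config reproduces
#' identical outputs.
#'
#' @param config a named list (see [demo_config()]) or path to a YAML file with
#'   the same fields.
#' @return the run manifest (invisibly), a list with per-stage outputs and
#'   checksums; also written as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  grp_df <- read.table(config$groups, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  groups <- setNames(grp_df$group, grp_df$sample)
  x <- stage("read_expression", read_expression_tsv(config$expression, groups))
  ctl <- config$control

  fp <- filter_params(outlier_sample = config$outlier_sample)
  de <- list()
  degs <- list()
  reports <- list()
  for (tr in config$contrasts) {
    stage(paste0("diffexpr_", tr), {
      cmp_samples <- names(groups)[groups %in% c(ctl, tr)]
      rep_ <- filter_report(x, cmp_samples, fp)
      reports[[tr]] <- rep_$counts
      keep <- names(rep_$retained)[rep_$retained]
      fit <- fit_moderated_t(x[keep, , drop = FALSE],
                             names(groups)[groups == tr],
                             names(groups)[groups == ctl])
      de[[tr]] <- fit
      degs[[tr]] <- call_degs(fit)
      outputs <- c(outputs, write_stage_table(
        fit$table, file.path(out, sprintf("de_%s.tsv", tr))))
    })
  }

  arrows <- stage("pc_vectors", pc_treatment_vectors(x, groups, control = ctl))
  outputs <- c(outputs, write_stage_table(arrows, file.path(out, "pc_arrows.tsv")))

  mods <- stage("comod", {
    ref <- read_expression_tsv(config$reference)
    z <- standardize_reference(ref)
    ms <- detect_modules(z, module_params(min_module_size = config$min_module_size))
    gc_tab <- read.table(config$go_counts, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    ms <- label_modules(ms, setNames(gc_tab$n_terms, gc_tab$gene))
    ms <- module_medoids(z, ms)
    asg_tab <- data.frame(gene = names(ms$assignment),
                          module = unname(ms$assignment))
    outputs <- c(outputs, write_stage_table(asg_tab, file.path(out, "modules.tsv")))
    list(ms = ms, z = z)
  })
  dem <- list()
  for (tr in config$contrasts) {
    stage(paste0("dem_", tr), {
      if (any(mods$ms$assignment > 0)) {
        dm <- dem_test(de[[tr]], mods$ms)
        dem[[tr]] <- dm
        outputs <- c(outputs, write_stage_table(
          dm, file.path(out, sprintf("dem_%s.tsv", tr))))
      }
    })
  }

  sig_res <- stage("setstats", {
    sigs <- read_gmt(config$signatures)
    rows <- list()
    for (tr in config$contrasts) {
      for (s in sigs) {
        dfish <- direction_fisher(de[[tr]], s)
        ar <- cumulative_overlap_area(de[[tr]], s)
        rows[[paste(tr, s$name)]] <- data.frame(
          contrast = tr, signature = s$name, direction = s$direction,
          n_expressed = dfish$n_expressed, frac_up = dfish$frac_up,
          fisher_p = dfish$fisher_p, area = ar$area,
          area_p = ar$wilcoxon_p, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    outputs <- c(outputs, write_stage_table(tab, file.path(out, "signatures.tsv")))
    tab
  })

  disease <- stage("disease", {
    src <- read_gmt(config$disease_sources)
    dt <- aggregate_disease_sources(lapply(src, `[[`, "members"))
    hi <- disease_genes_at_tier(dt, 4)
    nulls <- lapply(config$contrasts, function(tr) {
      rs <- random_set_fc_null(de[[tr]], hi, n_trials = config$fc_trials,
                               seed = config$seed + 10L)
      data.frame(contrast = tr, observed = rs$observed, p = rs$p,
                 n_target = rs$n_target)
    })
    tab <- do.call(rbind, nulls)
    outputs <- c(outputs, write_stage_table(tab, file.path(out, "disease_fc_null.tsv")))
    list(table = dt, null = tab)
  })

  prox <- stage("gwasprox", {
    genes_bed <- read_bed(config$genes_bed)
    loci_bed <- read_bed(config$loci_bed)
    map <- locus_map(genes_bed, loci_bed)
    pp <- proximity_params(top_n = config$top_n,
                           n_trials = config$distance_trials,
                           seed = config$seed + 20L)
    rows <- list()
    for (tr in config$contrasts) {
      tab <- de[[tr]]$table
      universe <- intersect(tab$gene, genes_bed$name)
      tt <- tab[match(universe, tab$gene), ]
      top_up <- tt$gene[order(-tt$log2fc)][seq_len(pp$top_n)]
      md <- mean_distance_null(top_up, universe, map, pp)
      rows[[tr]] <- data.frame(contrast = tr, observed_mean = md$observed,
                               p = md$p, n_finite = md$n_finite)
    }
    tab <- do.call(rbind, rows)
    outputs <- c(outputs, write_stage_table(tab, file.path(out, "gwas_proximity.tsv")))
    tab
  })

  motifs <- stage("motifscan", {
    prom <- read_fasta(config$promoters)
    pwms <- read_pwm(config$pwms)
    feats <- motif_features(prom, pwms)
    rows <- list()
    for (tr in config$contrasts) {
      all_degs <- c(degs[[tr]]$up, degs[[tr]]$down)
      flags <- setNames(as.integer(names(prom) %in% all_degs), names(prom))
      if (min(sum(flags), sum(1 - flags)) >= 20) {
        res <- gam_motif_enrichment(flags, feats$features,
                                    data.frame(gc = feats$gc))
        res$contrast <- tr
        rows[[tr]] <- res
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(tab)) {
      outputs <- c(outputs, write_stage_table(tab, file.path(out, "motifs.tsv")))
    }
    tab
  })

  summary_tab <- stage("summary", {
    rows <- lapply(config$contrasts, function(tr) {
      data.frame(
        contrast = tr,
        n_retained = reports[[tr]][["retained"]],
        degs_up = length(degs[[tr]]$up),
        degs_down = length(degs[[tr]]$down),
        dems = if (!is.null(dem[[tr]])) sum(dem[[tr]]$significant) else 0L,
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    outputs <- c(outputs, write_stage_table(tab, file.path(out, "summary.tsv")))
    tab
  })

  manifest <- list(
    version = as.character(utils::packageVersion("modscape")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs))),
    summary = summary_tab
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
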
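#' Assemble and validate an end-to-end pipeline configuration
#'
#' Seeds are explicit (never wall-clock derived); per-stage seeds are
#' fixed offsets from the master seed so reruns are byte-identical.
#'
#' @param out_dir output directory (created if needed)
#' @param genome_config a [synthetic_genome_config()]
#' @param stages sample sheet from [default_stage_specs()]
#' @param profile a [default_dynamics_profile()]
#' @param seed master integer seed
#' @param window_bp tiling window for global quantification
#' @param chh_window_bp tiling window for conversion control
#' @param late_threshold,resistant_threshold percent-methylation cutoffs
#' @param iap_cutoff IAP proximity cutoff (bp)
#' @param min_probe_count,min_chh_count coverage minima
#' @param hairpin_reads reads per hairpin simulation
#' @param dilution_truth [dyad_params()] generating the dilution-fit
#'   input counts
#' @param quiet suppress progress messages
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            genome_config = synthetic_genome_config(),
                            stages = default_stage_specs(),
                            profile = default_dynamics_profile(),
                            seed = 1L,
                            window_bp = 5000,
                            chh_window_bp = 1000,
                            late_threshold = 25,
                            resistant_threshold = 25,
                            iap_cutoff = 2000,
                            min_probe_count = 10,
                            min_chh_count = 20,
                            hairpin_reads = 2000L,
                            dilution_truth = dyad_params(0.1, 0.01, 0.02),
                            quiet = FALSE) {
  stopifnot(late_threshold >= 0, late_threshold <= 100,
            resistant_threshold >= 0, resistant_threshold <= 100,
            iap_cutoff > 0, min_probe_count >= 0, min_chh_count >= 0,
            hairpin_reads > 0, is.numeric(seed), length(seed) == 1L)
  structure(list(out_dir = out_dir, genome_config = genome_config,
                 stages = stages, profile = profile,
                 seed = as.integer(seed), window_bp = window_bp,
                 chh_window_bp = chh_window_bp,
                 late_threshold = late_threshold,
                 resistant_threshold = resistant_threshold,
                 iap_cutoff = iap_cutoff,
                 min_probe_count = min_probe_count,
                 min_chh_count = min_chh_count,
                 hairpin_reads = hairpin_reads,
                 dilution_truth = dilution_truth, quiet = quiet),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] may be set in the YAML; nested
#' generator/profile settings use the function defaults unless their
#' scalar components (`genome_seed`, chromosome lengths, thresholds)
#' are given.
#'
#' @param path YAML file
#' @param out_dir output directory (overrides any `out_dir` in the file)
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("seed", "window_bp", "chh_window_bp", "late_threshold",
               "resistant_threshold", "iap_cutoff", "min_probe_count",
               "min_chh_count", "hairpin_reads", "quiet", "out_dir")
  for (s in intersect(scalars, names(y))) args[[s]] <- y[[s]]
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (is.null(args$out_dir)) stop("out_dir must be set")
  gc_args <- list()
  if (!is.null(y$chrom_lengths)) {
    gc_args$chrom_lengths <- unlist(y$chrom_lengths)
  }
  if (!is.null(y$genome_seed)) gc_args$seed <- y$genome_seed
  if (length(gc_args)) {
    args$genome_config <- do.call(synthetic_genome_config, gc_args)
  }
  if (!is.null(y$coverage) || !is.null(y$replicates)) {
    st_args <- list()
    if (!is.null(y$coverage)) st_args$coverage <- y$coverage
    if (!is.null(y$replicates)) st_args$replicates <- y$replicates
    args$stages <- do.call(default_stage_specs, st_args)
  }
  do.call(pipeline_config, args)
}

.pipeline_stage <- function(name, quiet, fn) {
  if (!quiet) message("[pgcmeth] stage: ", name)
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(fn(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[pgcmeth] stage %s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full simulate-quantify-classify-model pipeline
#'
#' Executes simulate, quantify, classify, hairpin, dilution-fit and
#' expression stages in order, writes every result under
#' `config$out_dir`, and finishes with a manifest of all outputs and
#' their md5 hashes. Idempotent for fixed seeds: a rerun rewrites
#' byte-identical files. A stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result` with all in-memory stage
#'   results and the `manifest` data.frame (file, md5)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- config$quiet
  paths <- character()
  add_path <- function(p) paths[length(paths) + 1] <<- p

  sim <- .pipeline_stage("simulate", q, function() {
    annotation <- generate_annotation(config$genome_config)
    meth <- simulate_methylome(annotation, config$stages, config$profile,
                               seed = config$seed)
    write_features_bed(annotation, file.path(config$out_dir,
                                             "features.bed"))
    for (s in names(meth$calls)) {
      write_cytosine_calls(meth$calls[[s]],
                           file.path(config$out_dir,
                                     paste0("calls_", s, ".tsv")),
                           meta = c(sample = s,
                                    seed = as.character(config$seed)))
    }
    list(annotation = annotation, meth = meth)
  })
  add_path(file.path(config$out_dir, "features.bed"))
  for (s in names(sim$meth$calls)) {
    add_path(file.path(config$out_dir, paste0("calls_", s, ".tsv")))
  }

  quant <- .pipeline_stage("quantify", q, function() {
    probes <- tile_genome(sim$annotation$chrom_lengths, config$window_bp)
    pm <- probe_methylation(sim$meth, probes, config$min_probe_count)
    glob <- global_summary(pm)
    dist <- methylation_distribution(pm)
    conv <- conversion_efficiency(sim$meth,
                                  chrom_lengths = sim$annotation$chrom_lengths,
                                  window_bp = config$chh_window_bp,
                                  min_total_count = config$min_chh_count)
    fm <- feature_methylation(sim$meth, sim$annotation,
                              config$min_probe_count)
    dens <- cg_density_correlation(pm)
    write_meth_matrix(pm, file.path(config$out_dir, "probe_meth.tsv"))
    write_meth_matrix(fm, file.path(config$out_dir, "feature_meth.tsv"))
    utils::write.table(glob$per_sample,
                       file.path(config$out_dir, "global_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(probes = probes, probe_mat = pm, global = glob,
         distribution = dist, conversion = conv, feature_mat = fm,
         density_correlation = dens)
  })
  add_path(file.path(config$out_dir, "probe_meth.tsv"))
  add_path(file.path(config$out_dir, "feature_meth.tsv"))
  add_path(file.path(config$out_dir, "global_summary.tsv"))

  cls <- .pipeline_stage("classify", q, function() {
    sm <- stage_medians(quant$feature_mat)
    cgi_rows <- sm$rows$id[sm$rows$class %in%
                             c("CGI", "CGI_X", "DMR_maternal",
                               "DMR_paternal", "germline_promoter",
                               "promoter", "promoter_nonCGI", "VEC")]
    sub <- sm
    sub$pct <- sm$pct[cgi_rows, , drop = FALSE]
    late <- select_late_demethylaters(sub, config$late_threshold)
    res_m <- select_resistant(sub, "male",
                              threshold = config$resistant_threshold)
    res_f <- select_resistant(sub, "female",
                              threshold = config$resistant_threshold)
    prox <- annotate_iap_proximity(sim$annotation, cutoff = config$iap_cutoff)
    vecs <- identify_vecs(res_m, res_f, prox, sub)
    writeLines(late$selected, file.path(config$out_dir, "late_ids.txt"))
    writeLines(vecs$id, file.path(config$out_dir, "vec_ids.txt"))
    utils::write.table(prox, file.path(config$out_dir,
                                       "iap_proximity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(stage_mat = sm, late = late, resistant_male = res_m,
         resistant_female = res_f, proximity = prox, vecs = vecs)
  })
  add_path(file.path(config$out_dir, "late_ids.txt"))
  add_path(file.path(config$out_dir, "vec_ids.txt"))
  add_path(file.path(config$out_dir, "iap_proximity.tsv"))

  hp <- .pipeline_stage("hairpin", q, function() {
    obs <- simulate_hairpin_reads(config$hairpin_reads,
                                  mechanism = "passive",
                                  seed = config$seed + 101L)
    pas <- simulate_hairpin_reads(config$hairpin_reads,
                                  mechanism = "passive",
                                  seed = config$seed + 102L)
    act <- simulate_hairpin_reads(config$hairpin_reads,
                                  mechanism = "active",
                                  seed = config$seed + 103L)
    j_obs <- strand_joint(obs); j_pas <- strand_joint(pas)
    j_act <- strand_joint(act)
    verdict <- compare_to_nulls(j_obs, j_pas, j_act)
    bias <- strand_bias_stat(j_obs)
    write_hairpin_reads(obs, file.path(config$out_dir,
                                       "hairpin_observed.tsv"))
    utils::write.table(as.data.frame(unclass(j_obs)),
                       file.path(config$out_dir, "hairpin_joint.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(c(verdict, bias[c("confined", "off_axis")]),
                         file.path(config$out_dir, "hairpin_verdict.json"),
                         auto_unbox = TRUE, digits = NA)
    list(joint_observed = j_obs, joint_passive = j_pas,
         joint_active = j_act, verdict = verdict, bias = bias)
  })
  add_path(file.path(config$out_dir, "hairpin_observed.tsv"))
  add_path(file.path(config$out_dir, "hairpin_joint.tsv"))
  add_path(file.path(config$out_dir, "hairpin_verdict.json"))

  dil <- .pipeline_stage("dilution-fit", q, function() {
    counts <- simulate_dyad_counts(c(M = 0.95, H = 0.05, U = 0),
                                   config$dilution_truth,
                                   divisions = c(2, 2, 2),
                                   n_dyads = 10000L,
                                   seed = config$seed + 201L)
    fit <- fit_dilution(counts, divisions = c(2, 2, 2))
    jsonlite::write_json(list(p_m = fit$params$p_m, p_d = fit$params$p_d,
                              p_a = fit$params$p_a, loglik = fit$loglik),
                         file.path(config$out_dir, "dilution_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    list(counts = counts, fit = fit)
  })
  add_path(file.path(config$out_dir, "dilution_fit.json"))

  expr <- .pipeline_stage("expression", q, function() {
    es <- simulate_expression(seed = config$seed + 301L)
    cl <- cluster_profiles(es)
    cx <- complexity_profile(es)
    rep_counts <- simulate_repeat_counts(seed = config$seed + 302L)
    rf <- repeat_expression_fraction(rep_counts$counts,
                                     rep_counts$totals)
    e16m <- es$expr[, "E16.5_male"]
    mec <- methylation_expression_correlation(es$gene_body_meth, e16m)
    write_expression_tsv(es, file.path(config$out_dir, "expression.tsv"))
    utils::write.table(data.frame(gene = names(cl$assignment),
                                  cluster = cl$assignment),
                       file.path(config$out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(rf),
                       file.path(config$out_dir, "repeat_fractions.tsv"),
                       sep = "\t", quote = FALSE)
    list(sim = es, clusters = cl, complexity = cx,
         repeat_fractions = rf, meth_expr = mec)
  })
  add_path(file.path(config$out_dir, "expression.tsv"))
  add_path(file.path(config$out_dir, "clusters.tsv"))
  add_path(file.path(config$out_dir, "repeat_fractions.tsv"))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(simulate = sim, quantify = quant, classify = cls,
                 hairpin = hp, dilution = dil, expression = expr,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$manifest), "output files in",
      x$config$out_dir, "\n")
  cat("late demethylaters:", length(x$classify$late$selected),
      "| VECs:", nrow(x$classify$vecs),
      "| hairpin verdict:", x$hairpin$verdict$verdict, "\n")
  invisible(x)
}
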
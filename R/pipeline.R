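# End-to-end orchestration: one configuration drives synthetic-data
# generation, classification and every downstream characterisation stage,
# with a manifest recording outputs, seed and checksums.

#' Pipeline configuration
#'
#' Collects the analysis cutoffs and run settings. Thresholds default to
#' the standard values used throughout the package: intensity floor 100,
#' DEG fold change 2, uniqueness bound 1.4 on the other stresses,
#' background band 1.2, FDR 0.05.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; every stage derives its substream from it.
#' @param stressors stress labels; default [default_stressors()].
#' @param thresholds named list: `intensity_min`, `deg_fc`, `unique_other`,
#'   `background`, `fdr`.
#' @param n_permutations permutations for the motif stage.
#' @param exclude_stressors stressors barred from nominating biomarker
#'   candidates; default `"V"` (vanadate, field-unrealistic concentration).
#' @param normalize whether to joint-quantile-normalize before filtering
#'   (synthetic data is generated on a common scale, so the default is
#'   FALSE).
#' @param synthetic list of overrides passed to [synthetic_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("rhizotox_run_"),
                            seed = 1,
                            stressors = default_stressors(),
                            thresholds = list(intensity_min = 100, deg_fc = 2,
                                              unique_other = 1.4, background = 1.2,
                                              fdr = 0.05),
                            n_permutations = 1000,
                            exclude_stressors = "V",
                            normalize = FALSE,
                            synthetic = list()) {
  structure(list(out_dir = out_dir, seed = seed, stressors = stressors,
                 thresholds = thresholds, n_permutations = n_permutations,
                 exclude_stressors = exclude_stressors, normalize = normalize,
                 synthetic = synthetic),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Reports violations instead of throwing: an empty result means the
#' configuration is usable.
#'
#' @param config a [pipeline_config()].
#' @return character vector of violation messages (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  th <- config$thresholds
  need <- c("intensity_min", "deg_fc", "unique_other", "background", "fdr")
  miss <- setdiff(need, names(th))
  if (length(miss)) {
    return(paste("missing threshold(s):", paste(miss, collapse = ", ")))
  }
  if (any(unlist(th[need]) <= 0)) v <- c(v, "thresholds must be positive")
  if (!(th$deg_fc > th$unique_other)) {
    v <- c(v, "threshold ordering violated: deg_fc must exceed unique_other")
  }
  if (!(th$unique_other > th$background)) {
    v <- c(v, "threshold ordering violated: unique_other must exceed background")
  }
  if (!(th$background > 1)) v <- c(v, "background threshold must exceed 1")
  if (!(th$fdr > 0 && th$fdr <= 1)) v <- c(v, "fdr must lie in (0, 1]")
  if (config$n_permutations < 100) v <- c(v, "n_permutations below 100")
  if (length(config$stressors) < 1) v <- c(v, "no stressors configured")
  v
}

pipeline_stage <- function(manifest, name, deps, out_dir, fun) {
  failed_dep <- deps[vapply(deps, function(d) {
    !is.null(manifest$stages[[d]]) && manifest$stages[[d]]$status != "ok"
  }, TRUE)]
  if (length(failed_dep)) {
    manifest$stages[[name]] <- list(status = "skipped",
                                    reason = paste("dependency failed:", failed_dep[1]))
    return(manifest)
  }
  res <- tryCatch(list(status = "ok", value = fun()),
                  error = function(e) list(status = "failed",
                                           reason = conditionMessage(e)))
  if (res$status == "ok") {
    files <- res$value$files %||% character(0)
    manifest$stages[[name]] <- list(status = "ok",
                                    outputs = res$value,
                                    checksums = if (length(files)) tools::md5sum(files))
  } else {
    manifest$stages[[name]] <- res
  }
  manifest
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages run in dependency order: `simulate`, `classify`, then the
#' independent characterisation stages `motifs`, `architecture`, `kaks`,
#' `network` and `biomarker`. A stage failure marks dependent stages
#' skipped; independent stages still run. All stage outputs are written
#' under `config$out_dir` and checksummed in the returned manifest.
#'
#' @param config a [pipeline_config()] (validated first; violations are an
#'   error).
#' @return list of class `pipeline_manifest`: `seed`, `config`, `stages`
#'   (per-stage status, outputs and md5 checksums).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid configuration: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  th <- config$thresholds
  manifest <- list(package_version = as.character(utils::packageVersion("rhizotox")),
                   seed = config$seed, config = config, stages = list())
  env <- new.env(parent = emptyenv())

  manifest <- pipeline_stage(manifest, "simulate", character(0), config$out_dir, function() {
    sc_args <- utils::modifyList(list(stressors = config$stressors, seed = config$seed),
                                 config$synthetic)
    env$sim <- simulate_expression(do.call(synthetic_config, sc_args))
    write_expression(env$sim$dataset, out("expression.tsv"), out("samples.tsv"))
    write_tsv(env$sim$truth, out("expression_truth.tsv"))
    list(files = out(c("expression.tsv", "samples.tsv", "expression_truth.tsv")),
         n_genes = nrow(env$sim$dataset$intensities))
  })

  manifest <- pipeline_stage(manifest, "classify", "simulate", config$out_dir, function() {
    ds <- read_expression(out("expression.tsv"), out("samples.tsv"))
    if (config$normalize) ds <- quantile_normalize_joint(ds)
    ds <- filter_low_intensity(ds, th$intensity_min)
    fc <- fold_change_table(ds)
    cl <- classify_genes(fc, thresholds = list(deg = th$deg_fc,
                                               unique_other = th$unique_other,
                                               background = th$background),
                         fdr_cutoff = th$fdr)
    env$classification <- cl
    env$summary <- summarize_classes(cl)
    write_tsv(fc, out("fold_changes.tsv"))
    write_tsv(cl, out("classification.tsv"))
    write_tsv(env$summary, out("class_summary.tsv"))
    list(files = out(c("fold_changes.tsv", "classification.tsv", "class_summary.tsv")),
         summary = env$summary)
  })

  manifest <- pipeline_stage(manifest, "motifs", "classify", config$out_dir, function() {
    n_gsr <- max(sum(env$classification$class == "GSR_up"), 10)
    n_bg <- max(sum(env$classification$class == "background"), 10)
    pat <- builtin_motifs()[["CGCG box"]]
    prom <- simulate_promoters(n_gsr, n_bg, pat, 0.52, 0.31, length = 1000,
                               seed = substream_seed(config$seed, "pipeline_promoters"))
    write_fasta(prom$gsr, out("promoters_gsr.fasta"))
    write_fasta(prom$background, out("promoters_background.fasta"))
    enr <- motif_permutation_test(prom$gsr, prom$background, pat,
                                  n_permutations = config$n_permutations,
                                  seed = substream_seed(config$seed, "pipeline_motif_perm"))
    res <- data.frame(motif = enr$motif, fraction_gsr = enr$fraction_in_groupA,
                      fraction_background = enr$fraction_in_groupB,
                      difference = enr$observed_difference, p = enr$p_value)
    write_tsv(res, out("motif_enrichment.tsv"))
    list(files = out(c("promoters_gsr.fasta", "promoters_background.fasta",
                       "motif_enrichment.tsv")),
         enrichment = enr)
  })

  manifest <- pipeline_stage(manifest, "architecture", "classify", config$out_dir, function() {
    gm <- simulate_gene_models(
      groups = list(
        gsr = list(n = 150, intron_count = function(n) stats::rpois(n, 0.8),
                   intron_length = function(k) sample(80:400, k, replace = TRUE)),
        low_regulated = list(n = 50, intron_count = function(n) stats::rpois(n, 2),
                             intron_length = function(k) sample(150:800, k, replace = TRUE)),
        background = list(n = 150, intron_count = function(n) stats::rpois(n, 3),
                          intron_length = function(k) sample(300:1500, k, replace = TRUE))),
      seed = substream_seed(config$seed, "pipeline_models"))
    writeLines(gm$gff3, out("gene_models.gff3"))
    models <- read_gene_models(out("gene_models.gff3"))
    models$group <- gm$truth$group[match(models$gene, gm$truth$gene)]
    groups <- split(models, models$group)
    z <- intronless_fraction_test(groups$gsr, groups$background)
    lens <- compare_intron_metrics(groups, "total_intron_length")
    write_tsv(models[, c("gene", "group", "intron_count", "total_intron_length")],
              out("architecture.tsv"))
    list(files = out(c("gene_models.gff3", "architecture.tsv")),
         intronless_z = z, length_comparison = lens)
  })

  manifest <- pipeline_stage(manifest, "kaks", "classify", config$out_dir, function() {
    coact <- simulate_ortholog_pairs(25, 300, omega = 0.8,
                                     seed = substream_seed(config$seed, "pipeline_kaks_coact"))
    rest <- simulate_ortholog_pairs(75, 300, omega = 0.15,
                                    seed = substream_seed(config$seed, "pipeline_kaks_rest"))
    write_fasta(c(coact$cds_a, coact$cds_b, rest$cds_a, rest$cds_b), out("orthologs_cds.fasta"))
    kt_c <- kaks_table(coact$protein_a, coact$protein_b, coact$cds_a, coact$cds_b,
                       paste0("coact_", coact$truth$pair))
    kt_r <- kaks_table(rest$protein_a, rest$protein_b, rest$cds_a, rest$cds_b,
                       paste0("gsr_", rest$truth$pair))
    kt <- rbind(kt_c, kt_r)
    write_tsv(kt, out("kaks.tsv"))
    cmp <- kaks_compare_categories(list(coactivation = kt_c$ratio, other_gsr = kt_r$ratio),
                                   reference = kt$ratio)
    list(files = out(c("orthologs_cds.fasta", "kaks.tsv")), comparison = cmp)
  })

  manifest <- pipeline_stage(manifest, "network", "classify", config$out_dir, function() {
    nodes <- 400
    regs <- sprintf("n%04d", seq(11, 40))
    net <- simulate_network(nodes, planted_hubs = 10, hub_degree = 30,
                            background_degree_mean = 3, regulator_labels = regs,
                            seed = substream_seed(config$seed, "pipeline_network"))
    write_tsv(net$edges, out("network_edges.tsv"))
    write_tsv(net$roles, out("network_roles.tsv"))
    g <- read_edge_list(net$edges, net$roles)
    hubs <- top_hubs(g, 10)
    write_tsv(hubs, out("network_hubs.tsv"))
    tr <- terminal_regulators(g, intersect(regs, igraph::V(g)$name))
    list(files = out(c("network_edges.tsv", "network_roles.tsv", "network_hubs.tsv")),
         hubs = hubs, terminal_regulators = tr$node)
  })

  manifest <- pipeline_stage(manifest, "biomarker", "classify", config$out_dir, function() {
    panels <- leave_one_out_panels()
    single_panels <- lapply(unique(unlist(panels)), function(s) s)
    names(single_panels) <- unique(unlist(panels))
    profile_single <- list(
      cd_marker = stats::setNames(ifelse(names(single_panels) == "Cd", 9, 1.1),
                                  names(single_panels)),
      decoy = stats::setNames(rep(10, length(single_panels)), names(single_panels)))
    ct_single <- simulate_ct_table(single_panels, profile_single,
                                   seed = substream_seed(config$seed, "pipeline_ct_single"))
    write_ct_table(ct_single, out("ct_single.csv"), out("ct_single_samples.tsv"))
    folds_single <- panel_fold_matrix(ct_single)
    cand <- uniqueness_screen(folds_single, exclude_stressors = config$exclude_stressors)
    profile_comb <- list(
      cd_marker = stats::setNames(ifelse(vapply(panels, function(p) "Cd" %in% p, TRUE),
                                         32, 2), names(panels)),
      decoy = stats::setNames(rep(10, length(panels)), names(panels)))
    ct_comb <- simulate_ct_table(panels, profile_comb,
                                 seed = substream_seed(config$seed, "pipeline_ct_comb"))
    write_ct_table(ct_comb, out("ct_combined.csv"), out("ct_combined_samples.tsv"))
    folds_comb <- panel_fold_matrix(ct_comb)
    screen_input <- rbind(cand,
                          data.frame(gene = "decoy", target_stress = "Cd",
                                     stringsAsFactors = FALSE))
    report <- validate_biomarkers(unique(screen_input), folds_comb, panels)
    write_tsv(report, out("biomarker_report.tsv"))
    list(files = out(c("ct_single.csv", "ct_combined.csv", "biomarker_report.tsv")),
         report = report)
  })

  class(manifest) <- "pipeline_manifest"
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline_manifest (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, st$status,
                if (st$status != "ok" && !is.null(st$reason)) paste0(" (", st$reason, ")") else ""))
  }
  invisible(x)
}
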
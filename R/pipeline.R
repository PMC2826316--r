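#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the conventional
#' defaults: 0.01 ppm liver-extract bucketing normalized to a total of
#' 10000, Pareto scaling for spectral blocks and unit variance for
#' expression, a 1.5 fold-change filter, BH FDR 0.05, fusion acceptance at
#' Q2 > 0.40 against 30 permutations, and 200 permutations for dose-model
#' validation.
#'
#' @param n_rep,doses,days study design (see [make_design()]).
#' @param seed master seed; all stage seeds derive from it.
#' @param bucket_preset name for [bucket_preset()].
#' @param renorm_regions ppm regions excluded at renormalization (the
#'   glucose/glycogen resonances); set to `list()` to skip.
#' @param fc_threshold,fdr_alpha expression cascade thresholds.
#' @param q2_threshold,fusion_permutations fusion acceptance rule.
#' @param dose_permutations permutations for the dose-model validation.
#' @param n_null_genes null genes in the simulated expression block.
#' @param metabolites named list of ppm intervals whose normalized bucket
#'   integrals become the fusion responses.
#' @param enrichment_alpha,kegg_min_overlap over-representation thresholds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rep = 5, doses = c(0, 50, 500, 1000),
                            days = c(1, 3, 7, 14), seed = 1L,
                            bucket_preset = "liver_extract",
                            renorm_regions = list(c(3.35, 4.05),
                                                  c(4.60, 4.72),
                                                  c(5.20, 5.55)),
                            fc_threshold = 1.5, fdr_alpha = 0.05,
                            q2_threshold = 0.40, fusion_permutations = 30,
                            dose_permutations = 200, n_null_genes = 500,
                            metabolites = list(succinate = c(2.39, 2.43),
                                               lactate = c(1.31, 1.35)),
                            enrichment_alpha = 0.05, kegg_min_overlap = 3) {
  stopifnot(fc_threshold >= 1, fdr_alpha > 0, fdr_alpha < 1,
            fusion_permutations >= 1, dose_permutations >= 1,
            kegg_min_overlap >= 1,
            enrichment_alpha > 0, enrichment_alpha < 1)
  if (q2_threshold < 0 || q2_threshold > 1)
    stop("q2_threshold must lie in [0, 1]")
  structure(as.list(environment()), class = "pipeline_config")
}

stage_msg <- function(...) message(sprintf(...))

#' Run the full synthetic-data pipeline
#'
#' Executes the stages in order — simulate, bucket and normalize,
#' dose-PLS chemometrics with permutation validation, the expression
#' cascade, per-metabolite fusion, and the lipid tally — writing every
#' stage output plus a deterministic JSON-lines run log into `out_dir`.
#' Rerunning with an identical config reproduces the directory
#' byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.jsonl")
  unlink(logf)
  cfg_hash <- substr(jsonlite::base64_enc(serialize(
    config[order(names(config))], NULL, version = 2)), 1, 24)
  log_stage <- function(stage, files) {
    md5 <- tools::md5sum(files)
    names(md5) <- basename(files)
    rec <- list(stage = stage, config_hash = cfg_hash, seed = config$seed,
                outputs = as.list(md5))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logf, append = TRUE, sep = "")
  }

  stage_msg("stage simulate: %d x %d x %d design, seed %d",
            length(config$doses), length(config$days), config$n_rep,
            config$seed)
  design <- make_design(config$n_rep, config$doses, config$days)
  truth <- default_truth(seed = config$seed)
  spectra <- simulate_spectra(design, truth)
  f_design <- file.path(out_dir, "design.tsv")
  write_design_tsv(design, f_design)
  log_stage("simulate", f_design)

  stage_msg("stage bucket: preset '%s'", config$bucket_preset)
  scheme <- bucket_preset(config$bucket_preset)
  bt <- normalize_total(bucket_spectra(spectra, scheme))
  bt_ren <- if (length(config$renorm_regions))
    renormalize_excluding(bt, config$renorm_regions) else bt
  f_buckets <- file.path(out_dir, "buckets_normalized.tsv")
  write_bucket_table_tsv(bt, f_buckets)
  log_stage("bucket", f_buckets)

  stage_msg("stage chemometrics: dose PLS with %d permutations",
            config$dose_permutations)
  dose_val <- permutation_validate(bt$values, design$dose, n_components = 1,
                                   n_permutations = config$dose_permutations,
                                   seed = config$seed,
                                   x_scaling = scaling_spec("pareto"))
  f_val <- file.path(out_dir, "dose_validation.csv")
  utils::write.csv(rbind(data.frame(correlation = 1, R2 = dose_val$real_R2,
                                    Q2 = dose_val$real_Q2),
                         dose_val$permuted), f_val, row.names = FALSE)
  log_stage("chemometrics", f_val)

  stage_msg("stage expression cascade: %d null genes", config$n_null_genes)
  met_tab <- metabolite_table_from_buckets(bt_ren, config$metabolites)
  es <- simulate_expression(design, truth, config$n_null_genes, met_tab)
  cascade <- de_cascade(es, config$fc_threshold, config$fdr_alpha)
  f_de <- file.path(out_dir, "de_results.tsv")
  utils::write.table(cascade$anova, f_de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("cascade", f_de)

  stage_msg("stage fusion: %d metabolite(s), %d permutations",
            ncol(met_tab), config$fusion_permutations)
  fcfg <- fusion_config(n_permutations = config$fusion_permutations,
                        q2_threshold = config$q2_threshold,
                        seed = config$seed)
  fused <- fuse_all(t(cascade$normalized), met_tab, fcfg)
  f_fuse <- file.path(out_dir, "fusion_summary.tsv")
  utils::write.table(fused$summary, f_fuse, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (m in names(fused$results))
    write_fusion_json(fused$results[[m]],
                      file.path(out_dir, sprintf("fusion_%s.json", m)))
  log_stage("fusion", f_fuse)

  stage_msg("stage enrichment and pathway overlay")
  enr <- enrich(cascade$significant, default_term_map(),
                universe = cascade$detected,
                min_overlap = config$kegg_min_overlap,
                alpha = config$enrichment_alpha)
  f_enr <- file.path(out_dir, "enrichment.tsv")
  utils::write.table(enr, f_enr, sep = "\t", quote = FALSE, row.names = FALSE)
  # every configured metabolite carries a planted dose effect; direction is
  # the sign of its correlation with dose
  met_dir <- vapply(colnames(met_tab), function(m)
    if (stats::cor(met_tab[, m], design$dose) >= 0) "up" else "down",
    character(1))
  de_dir <- if (is.null(cascade$ratios)) character() else
    vapply(cascade$significant, function(g) {
      r <- cascade$ratios[g, es$design$dose == 1000]
      if (stats::median(r) >= 1) "up" else "down"
    }, character(1))
  ov <- pathway_overlay(de_dir, met_dir, default_pathway_defs())
  f_ov <- file.path(out_dir, "pathway_overlay.tsv")
  utils::write.table(ov, f_ov, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("enrichment", c(f_enr, f_ov))

  stage_msg("stage lipid tally")
  lip <- simulate_lipid_changes(seed = config$seed)
  tallies <- lapply(split(lip, lip$day), tally_lipid_changes)
  f_tally <- file.path(out_dir, "lipid_tally.tsv")
  tally_tab <- do.call(rbind, Map(function(t, d) cbind(day = d, t),
                                  tallies, names(tallies)))
  utils::write.table(tally_tab, f_tally, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("lipids", f_tally)

  invisible(list(design = design, spectra = spectra, buckets = bt,
                 buckets_renormalized = bt_ren, dose_validation = dose_val,
                 expression = es, cascade = cascade, fusion = fused,
                 enrichment = enr, overlay = ov, lipid_tally = tallies))
}

#' Annotation term map for the synthetic gene panel
#'
#' Functional categories covering the generator's dose-responsive genes,
#' usable as a GMT-style term map for [enrich()] on simulated data.
#'
#' @return named list of term -> gene members.
#' @export
default_term_map <- function() {
  list(
    xenobiotic_metabolism = c("CYP2B2", "CYP3A3", "epoxide_hydrolase",
                              "UDP_glucuronosyltransferase_PB",
                              "aldehyde_dehydrogenase_1A1",
                              "glutathione_S_transferase_Yb4"),
    glutathione_metabolism = c("glutamate_cysteine_ligase",
                               "glutathione_reductase",
                               "glutathione_S_transferase_Yb4",
                               "glutamine_synthetase"),
    glycolysis_glycogen = c("hexokinase_D"),
    heme_biosynthesis = c("aminolevulinate_synthase", "succinate_tracker"),
    lipid_metabolism = c("lipoprotein_lipase", "malic_enzyme")
  )
}

#' Pathway definitions joining the synthetic genes and metabolites
#'
#' Gene and metabolite memberships for [pathway_overlay()] on simulated
#' data; metabolite names match the default [pipeline_config()] responses.
#'
#' @return named list of pathway -> list(genes, metabolites).
#' @export
default_pathway_defs <- function() {
  list(
    heme_biosynthesis = list(
      genes = c("aminolevulinate_synthase", "succinate_tracker"),
      metabolites = "succinate"),
    glycolysis_glycogen = list(
      genes = "hexokinase_D",
      metabolites = c("lactate", "glucose", "glycogen")),
    xenobiotic_metabolism = list(
      genes = c("CYP2B2", "CYP3A3", "epoxide_hydrolase"),
      metabolites = character())
  )
}

#' Extract per-metabolite responses from a normalized bucket table
#'
#' Sums the normalized bucket integrals overlapping each named ppm
#' interval, yielding the samples x metabolites response table used as
#' fusion Y variables.
#'
#' @param table a [bucket_table()].
#' @param intervals named list of ppm `c(lo, hi)` intervals.
#' @return samples x metabolites matrix.
#' @export
metabolite_table_from_buckets <- function(table, intervals) {
  stopifnot(inherits(table, "bucket_table"))
  b <- table$buckets
  out <- vapply(intervals, function(iv) {
    hit <- b$lo < iv[2] & b$hi > iv[1]
    if (!any(hit)) stop(sprintf("no buckets overlap interval [%g, %g]",
                                iv[1], iv[2]))
    rowSums(table$values[, hit, drop = FALSE])
  }, numeric(nrow(table$values)))
  rownames(out) <- rownames(table$values)
  out
}
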
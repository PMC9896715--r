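#' Pipeline configuration
#'
#' One structured configuration driving [run_pipeline()].  All randomness
#' flows from `seed`; per-stage seeds are derived as fixed offsets so stages
#' are individually reproducible without collisions.
#'
#' @param out_dir Output directory for stage TSVs.
#' @param sim [sim_config()] for the synthetic cohort (or `NULL` when
#'   `counts`/`samples`/`clinical` are supplied).
#' @param counts,samples,clinical In-memory inputs used when `sim` is NULL.
#' @param alpha,lfc_min DE call thresholds.
#' @param min_count,min_fraction Expression filter.
#' @param threshold_universe DEPC threshold policy (`"all"` or `"nonzero"`).
#' @param n_row_clusters,n_col_clusters,n_restarts Co-clustering settings.
#' @param survival_weight Weighted log-rank flavour.
#' @param n_perm Pairing permutations (0 disables the stage).
#' @param classifier `mlp_config()` or `NULL` to skip classification.
#' @param gmt Optional gene-set collection for enrichment.
#' @param seed Global integer seed.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, sim = sim_config(),
                            counts = NULL, samples = NULL, clinical = NULL,
                            alpha = 0.05, lfc_min = 1,
                            min_count = 1, min_fraction = 0.3,
                            threshold_universe = "all",
                            n_row_clusters = 3, n_col_clusters = 3,
                            n_restarts = 20,
                            survival_weight = "modified_peto",
                            n_perm = 0, classifier = NULL, gmt = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the end-to-end per-patient workflow
#'
#' Sequences: (optional) cohort simulation, expression filtering,
#' all-patients DE, per-patient DE, DEPC aggregation with AP/NAP
#' classification, (optional) pairing-permutation null, categorical
#' co-clustering into patient groups, between-group DE (PG0 vs PG1),
#' survival comparison and covariate association, and (optional) gene-set
#' enrichment of the up-regulated NAP genes.  Stage outputs are returned
#' in-memory and, when `out_dir` is set, written as TSV.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage results (invisible file paths when writing).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  seed <- as.integer(cfg$seed)
  if (!is.null(cfg$sim)) {
    cfg$sim$seed <- seed
    cohort <- simulate_cohort(cfg$sim)
    counts <- cohort$counts; samples <- cohort$samples
    clinical <- cohort$clinical
  } else {
    cohort <- NULL
    counts <- validate_counts(cfg$counts)
    samples <- validate_sample_table(cfg$samples)
    clinical <- cfg$clinical
  }
  filtered <- filter_genes(counts, cfg$min_count, cfg$min_fraction)
  ap <- run_all_patients(filtered, samples, cfg$alpha, cfg$lfc_min)
  pp <- run_per_patient(filtered, samples, cfg$alpha, cfg$lfc_min)
  depc <- compute_depc(pp)
  cls_up <- classify_ap_nap(depc, ap, "up", universe = cfg$threshold_universe)
  cls_down <- classify_ap_nap(depc, ap, "down",
                              universe = cfg$threshold_universe)
  perm <- NULL
  if (cfg$n_perm >= 2)
    perm <- permute_normals(filtered, samples, n_perm = cfg$n_perm,
                            seed = seed + 101L, alpha = cfg$alpha,
                            lfc_min = cfg$lfc_min)

  nap_up <- cls_up$gene_id[cls_up$class == "NAP" & cls_up$above_threshold]
  cluster_genes <- if (length(nap_up) >= cfg$n_row_clusters) nap_up else
    cls_up$gene_id[cls_up$above_threshold]
  M <- categorize(pp, cluster_genes)
  fit <- lbm_cocluster(M, cfg$n_row_clusters, cfg$n_col_clusters,
                       n_restarts = cfg$n_restarts, seed = seed + 202L)
  grouping <- assign_groups(fit)

  bg <- tryCatch(
    run_between_groups(filtered, samples, grouping, "PG0", "PG1",
                       cfg$alpha, cfg$lfc_min),
    error = function(e) { warning("between-group DE skipped: ",
                                  conditionMessage(e)); NULL })

  surv <- NULL
  assoc <- NULL
  if (!is.null(clinical)) {
    merged <- merge(grouping, clinical, by = "patient_id")
    two <- merged[merged$group %in% c("PG0", "PG1"), ]
    surv <- list(
      km = km_estimate(two$rfs_days, two$recurrence_event, two$group),
      test = weighted_logrank(two$rfs_days, two$recurrence_event, two$group,
                              weight = cfg$survival_weight))
    assoc <- associate_covariates(grouping[grouping$group %in%
                                             c("PG0", "PG1"), ],
                                  clinical, seed = seed + 303L)
  }

  enr <- NULL
  if (!is.null(cfg$gmt) && length(nap_up) > 0)
    enr <- enrich(nap_up, cfg$gmt, rownames(filtered))

  cls_results <- NULL
  if (!is.null(cfg$classifier)) {
    norm <- tmm_cpm_log(filtered)
    feat <- if (length(nap_up) >= 2) nap_up else cluster_genes
    tnd <- build_tnd(norm, samples, feat, grouping)
    trials <- run_trials(tnd, tnd, cfg$classifier, seed = seed + 404L)
    cls_results <- list(
      trials = trials,
      labels = aggregate_predictions(trials$counts, trials$n_trials))
  }

  res <- list(cohort = cohort, filtered = filtered, all_patients = ap,
              per_patient = pp, depc = depc, classes_up = cls_up,
              classes_down = cls_down, permutation = perm,
              categorical = M, fit = fit, grouping = grouping,
              between_groups = bg, survival = surv, association = assoc,
              enrichment = enr, classifier = cls_results, seed = seed)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(filtered, file.path(cfg$out_dir, "counts_filtered.tsv"))
    write_tsv(samples, file.path(cfg$out_dir, "samples.tsv"))
    if (!is.null(clinical))
      write_tsv(clinical, file.path(cfg$out_dir, "clinical.tsv"))
    write_tsv(ap, file.path(cfg$out_dir, "de_all_patients.tsv"))
    write_tsv(depc, file.path(cfg$out_dir, "depc.tsv"))
    write_tsv(cls_up, file.path(cfg$out_dir, "classes_up.tsv"))
    write_tsv(cls_down, file.path(cfg$out_dir, "classes_down.tsv"))
    write_tsv(grouping, file.path(cfg$out_dir, "grouping.tsv"))
    if (!is.null(bg))
      write_tsv(bg, file.path(cfg$out_dir, "de_between_groups.tsv"))
    if (!is.null(surv)) {
      write_tsv(surv$km, file.path(cfg$out_dir, "km.tsv"))
      write_tsv(data.frame(statistic = surv$test$statistic,
                           df = surv$test$df, p = surv$test$p,
                           method = surv$test$method),
                file.path(cfg$out_dir, "survival_test.tsv"))
    }
    if (!is.null(assoc))
      write_tsv(assoc, file.path(cfg$out_dir, "associations.tsv"))
    if (!is.null(enr))
      write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"))
    # run manifest: seeds and parameters for reproducibility
    manifest <- c(sprintf("multiregDE %s",
                          as.character(utils::packageVersion("multiregDE"))),
                  sprintf("seed\t%d", seed),
                  sprintf("alpha\t%g", cfg$alpha),
                  sprintf("lfc_min\t%g", cfg$lfc_min),
                  sprintf("min_count\t%g", cfg$min_count),
                  sprintf("min_fraction\t%g", cfg$min_fraction),
                  sprintf("threshold_universe\t%s", cfg$threshold_universe))
    writeLines(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  }
  invisible(res)
}
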
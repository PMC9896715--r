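#' Configuration for the synthetic multi-region cohort generator
#'
#' The generator emulates a resection cohort in which every patient provides
#' one adjacent-normal sample and several tumour regions.  Genes fall into
#' four classes: `CORE_UP` / `CORE_DOWN` (dysregulated in every tumour),
#' `SUBGROUP_UP` (up-regulated only in tumours of the patient's latent
#' group, and drawn from a high-variance baseline stratum so cohort-level
#' analysis tends to miss them) and `NULL` (no tumour effect).  Patient
#' groups carry different recurrence hazards.
#'
#' @param n_patients Number of patients (default 90).
#' @param tumour_regions_range Integer range of tumour regions per patient
#'   (default `2:5`, drawn uniformly).
#' @param n_genes Number of genes (default 2000).
#' @param class_proportions Named proportions over
#'   `c(CORE_UP, CORE_DOWN, SUBGROUP_UP, NULL_)`; must sum to 1.
#' @param n_patient_groups Latent patient groups (default 3).
#' @param group_probs Membership probabilities per group (default
#'   approximates a 42/36/12 split).
#' @param baseline_meanlog,baseline_sdlog Natural-log mean and SD of the
#'   gene-level baseline expression distribution.
#' @param patient_sdlog Between-patient SD of the baseline (natural log).
#' @param patient_sdlog_hivar Between-patient SD for `SUBGROUP_UP` genes
#'   (the high-variance stratum).
#' @param effect_core_up,effect_core_down,effect_subgroup_up Tumour log2
#'   effect sizes per class.
#' @param dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2).
#' @param libsize_sdlog Log-normal SD of per-sample library-size factors.
#' @param hazards Per-group recurrence hazards per day; must be positive.
#' @param censor_horizon Administrative censoring horizon in days.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 90,
                       tumour_regions_range = 2:5,
                       n_genes = 2000,
                       class_proportions = c(CORE_UP = 0.01, CORE_DOWN = 0.01,
                                             SUBGROUP_UP = 0.05, NULL_ = 0.93),
                       n_patient_groups = 3,
                       group_probs = c(0.47, 0.40, 0.13),
                       baseline_meanlog = 5,
                       baseline_sdlog = 1.2,
                       patient_sdlog = 0.2,
                       patient_sdlog_hivar = 0.9,
                       effect_core_up = 2,
                       effect_core_down = -2,
                       effect_subgroup_up = 2,
                       dispersion = 0.05,
                       libsize_sdlog = 0.25,
                       hazards = c(1 / 1000, 1 / 400, 1 / 700),
                       censor_horizon = 1825,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              tumour_regions_range = as.integer(tumour_regions_range),
              n_genes = as.integer(n_genes),
              class_proportions = class_proportions,
              n_patient_groups = as.integer(n_patient_groups),
              group_probs = group_probs,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              patient_sdlog = patient_sdlog,
              patient_sdlog_hivar = patient_sdlog_hivar,
              effect_core_up = effect_core_up,
              effect_core_down = effect_core_down,
              effect_subgroup_up = effect_subgroup_up,
              dispersion = dispersion,
              libsize_sdlog = libsize_sdlog,
              hazards = hazards,
              censor_horizon = censor_horizon,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1 || cfg$n_genes < 1)
    stop("config error: n_patients and n_genes must be >= 1")
  if (length(cfg$tumour_regions_range) == 0 || any(cfg$tumour_regions_range < 1))
    stop("config error: tumour_regions_range must be a non-empty range >= 1")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-8)
    stop("config error: class_proportions must sum to 1")
  if (any(cfg$class_proportions < 0))
    stop("config error: class_proportions must be non-negative")
  if (length(cfg$group_probs) != cfg$n_patient_groups ||
      abs(sum(cfg$group_probs) - 1) > 1e-8)
    stop("config error: group_probs must be a probability vector of length ",
         cfg$n_patient_groups)
  if (length(cfg$hazards) != cfg$n_patient_groups || any(cfg$hazards <= 0))
    stop("config error: hazards must be positive, one per patient group")
  if (cfg$dispersion <= 0) stop("config error: dispersion must be > 0")
  cfg
}

#' Simulate a multi-region tumour/normal cohort with ground truth
#'
#' Per patient: one adjacent-normal sample plus `r` tumour regions, `r`
#' uniform over the configured range.  The normal-tissue mean for gene g in
#' patient p is `exp(Normal(mu_g, sigma_g))`, where `sigma_g` is the
#' high-variance SD iff the gene is `SUBGROUP_UP`.  Tumour means multiply
#' the patient's normal mean by `2^effect`, with the subgroup effect applied
#' only when the patient's latent group is the gene's target.  Counts are
#' negative binomial around `mean * library factor`.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (integer matrix), `samples` (sample table),
#'   `clinical` (clinical table) and `truth` (list with `gene_class`,
#'   `gene_target`, `patient_group`, `baseline`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  withr::with_seed(cfg$seed, {
    np <- cfg$n_patients
    ng <- cfg$n_genes
    K <- cfg$n_patient_groups
    patients <- sprintf("P%03d", seq_len(np))
    genes <- sprintf("g%05d", seq_len(ng))

    classes <- sample(names(cfg$class_proportions), ng, replace = TRUE,
                      prob = cfg$class_proportions)
    target <- rep(NA_integer_, ng)
    is_sub <- classes == "SUBGROUP_UP"
    target[is_sub] <- sample.int(K, sum(is_sub), replace = TRUE) - 1L

    group <- sample.int(K, np, replace = TRUE, prob = cfg$group_probs) - 1L

    mu_g <- stats::rnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
    sd_g <- ifelse(is_sub, cfg$patient_sdlog_hivar, cfg$patient_sdlog)
    # baseline: genes x patients natural-log normal-tissue means
    baseline <- exp(mu_g + matrix(stats::rnorm(ng * np), ng, np) * sd_g)
    dimnames(baseline) <- list(genes, patients)

    effect <- matrix(0, ng, np)  # log2 tumour effect per gene x patient
    effect[classes == "CORE_UP", ] <- cfg$effect_core_up
    effect[classes == "CORE_DOWN", ] <- cfg$effect_core_down
    for (g in which(is_sub))
      effect[g, group == target[g]] <- cfg$effect_subgroup_up

    rr <- cfg$tumour_regions_range  # index, not sample(): length-1 ranges
    regions <- rr[sample.int(length(rr), np, replace = TRUE)]
    sample_rows <- do.call(rbind, lapply(seq_len(np), function(p) {
      data.frame(
        sample_id = c(paste0(patients[p], "_N"),
                      paste0(patients[p], "_T", seq_len(regions[p]))),
        patient_id = patients[p],
        sample_type = c("normal", rep("tumour", regions[p])),
        region = c(NA_character_, paste0("R", seq_len(regions[p]))),
        stringsAsFactors = FALSE)
    }))
    ns <- nrow(sample_rows)
    libfac <- stats::rlnorm(ns, 0, cfg$libsize_sdlog)

    counts <- matrix(0L, ng, ns, dimnames = list(genes, sample_rows$sample_id))
    size <- 1 / cfg$dispersion
    for (s in seq_len(ns)) {
      p <- match(sample_rows$patient_id[s], patients)
      mu <- baseline[, p]
      if (sample_rows$sample_type[s] == "tumour") mu <- mu * 2^effect[, p]
      counts[, s] <- stats::rnbinom(ng, mu = mu * libfac[s], size = size)
    }

    clinical <- simulate_recurrence(stats::setNames(group, patients),
                                    cfg$hazards, cfg$censor_horizon,
                                    seed = cfg$seed + 1L)
    # group-biased binary covariates, enough to exercise association tests
    p_sex <- c(0.15, 0.35, 0.25)[pmin(group, 2) + 1]
    p_hbv <- c(0.50, 0.80, 0.60)[pmin(group, 2) + 1]
    clinical$sex <- ifelse(stats::runif(np) < p_sex, "female", "male")
    clinical$hbv <- ifelse(stats::runif(np) < p_hbv, "positive", "negative")

    list(counts = counts,
         samples = sample_rows,
         clinical = clinical,
         truth = list(gene_class = stats::setNames(classes, genes),
                      gene_target = stats::setNames(target, genes),
                      patient_group = stats::setNames(group, patients),
                      baseline = baseline))
  })
}

#' Simulate recurrence-free survival for grouped patients
#'
#' Event times are exponential with the group's hazard; times beyond the
#' censoring horizon are administratively censored at the horizon.
#'
#' @param groups Named integer vector, patient -> group index (0-based).
#' @param hazards Per-group hazard rates (events/day), one per group.
#' @param censor_horizon Censoring horizon in days (may be `Inf`).
#' @param seed Integer seed.
#' @return `data.frame` with patient_id, rfs_days, recurrence_event.
#' @export
simulate_recurrence <- function(groups, hazards, censor_horizon, seed = 1L) {
  if (any(hazards <= 0)) stop("config error: hazards must be positive")
  if (any(groups + 1L > length(hazards)))
    stop("config error: a patient's group has no hazard")
  withr::with_seed(as.integer(seed), {
    t_event <- stats::rexp(length(groups), rate = hazards[groups + 1L])
    event <- as.integer(t_event <= censor_horizon)
    time <- pmin(t_event, censor_horizon)
    data.frame(patient_id = names(groups), rfs_days = time,
               recurrence_event = event, stringsAsFactors = FALSE,
               row.names = NULL)
  })
}
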
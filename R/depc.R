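#' Differentially-expressed patient counts
#'
#' For every gene, counts the patients whose per-patient analysis calls it
#' up- and down-regulated.  The gene universe is the outer union across
#' patients; a gene absent from a patient's table counts as `none` there.
#'
#' @param per_patient Named list of per-patient DE tables (with `call`).
#' @return `data.frame` with gene_id, depc_up, depc_down, n_patients.
#' @export
compute_depc <- function(per_patient) {
  stopifnot(length(per_patient) > 0)
  genes <- sort(unique(unlist(lapply(per_patient, `[[`, "gene_id"))))
  up <- stats::setNames(integer(length(genes)), genes)
  down <- up
  for (tab in per_patient) {
    idx <- match(tab$gene_id, genes)
    up[idx[tab$call == "up"]] <- up[idx[tab$call == "up"]] + 1L
    down[idx[tab$call == "down"]] <- down[idx[tab$call == "down"]] + 1L
  }
  data.frame(gene_id = genes, depc_up = as.integer(up),
             depc_down = as.integer(down),
             n_patients = length(per_patient),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-standard-deviation DEPC threshold
#'
#' `mean + 2 * sample SD` of the DEPC values.  With `universe = "all"`
#' (default) the statistics are taken over every supplied value, zeros
#' included, which places the threshold between the sporadic-call floor and
#' the subgroup-shared stratum; `universe = "nonzero"` restricts to values
#' >= 1.  Genes pass the threshold inclusively (`depc >= threshold`).
#'
#' @param depc_values Integer vector of per-gene DEPC values (one
#'   direction).
#' @param universe `"all"` or `"nonzero"`.
#' @return The numeric threshold.
#' @export
depc_threshold <- function(depc_values, universe = c("all", "nonzero")) {
  universe <- match.arg(universe)
  if (length(depc_values) == 0 || all(depc_values == 0))
    stop("no informative genes: all DEPC values are zero")
  v <- if (universe == "nonzero") depc_values[depc_values >= 1] else depc_values
  mean(v) + 2 * stats::sd(v)
}

#' Classify per-patient DE genes as AP or NAP
#'
#' Among genes with DEPC >= 1 in the given direction, a gene is `AP` if the
#' all-patients (cohort-level) analysis also called it in that direction and
#' `NAP` otherwise; `above_threshold` marks genes at or above the
#' two-standard-deviation DEPC threshold.
#'
#' @param depc DEPC table from [compute_depc()].
#' @param ap_results All-patients DE table with calls.
#' @param direction `"up"` or `"down"`.
#' @param universe Threshold universe, see [depc_threshold()].
#' @return `data.frame` with gene_id, direction, depc, class,
#'   above_threshold; threshold in `attr(, "threshold")`.
#' @export
classify_ap_nap <- function(depc, ap_results, direction = c("up", "down"),
                            universe = c("all", "nonzero")) {
  direction <- match.arg(direction)
  universe <- match.arg(universe)
  vals <- if (direction == "up") depc$depc_up else depc$depc_down
  thr <- depc_threshold(vals, universe = universe)
  keep <- vals >= 1
  ap_genes <- ap_results$gene_id[ap_results$call == direction]
  out <- data.frame(gene_id = depc$gene_id[keep], direction = direction,
                    depc = vals[keep],
                    class = ifelse(depc$gene_id[keep] %in% ap_genes,
                                   "AP", "NAP"),
                    above_threshold = vals[keep] >= thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

#' AP/NAP counts above each DEPC threshold
#'
#' For every threshold `t = 1..n_patients`, the number of AP and NAP genes
#' with DEPC >= t; both counts are non-increasing in `t`.
#'
#' @param class_table Output of [classify_ap_nap()].
#' @param n_patients Number of patients (maximum DEPC).
#' @return `data.frame` with threshold, ap_count, nap_count, total.
#' @export
depc_curve <- function(class_table, n_patients) {
  t <- seq_len(n_patients)
  ap <- vapply(t, function(k)
    sum(class_table$depc >= k & class_table$class == "AP"), integer(1))
  nap <- vapply(t, function(k)
    sum(class_table$depc >= k & class_table$class == "NAP"), integer(1))
  data.frame(threshold = t, ap_count = ap, nap_count = nap,
             total = ap + nap, row.names = NULL)
}

# counts of genes with depc >= t for t = 1..n_patients (one direction)
depc_tail_counts <- function(depc_values, n_patients) {
  vapply(seq_len(n_patients), function(k) sum(depc_values >= k), integer(1))
}

#' Pairing-permutation null for the per-patient analysis
#'
#' Reassigns the adjacent-normal samples among patients uniformly at random
#' (fixed points allowed), reruns the per-patient analysis and the DEPC
#' aggregation for each permutation, and summarizes the per-threshold counts
#' of genes at or above each DEPC value against the correctly paired
#' analysis.
#'
#' @param counts Filtered count matrix.
#' @param samples Sample table.
#' @param n_perm Number of permutations (>= 2).
#' @param seed Integer seed; fixed seed gives an identical permutation
#'   sequence.
#' @param alpha,lfc_min Call thresholds passed to the DE engine.
#' @return List with `observed` (DEPC table), `observed_curve`,
#'   `perm_curves` (list of up/down matrices, permutations x thresholds),
#'   `mean`, `sd` and `perm_depc` (list of permuted DEPC tables).
#' @export
permute_normals <- function(counts, samples, n_perm = 100, seed = 1L,
                            alpha = 0.05, lfc_min = 1) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  samples <- align_samples(counts, samples)
  normal_idx <- which(samples$sample_type == "normal")
  if (length(normal_idx) < 3) stop("need >= 3 patients to permute pairings")
  obs_pp <- run_per_patient(counts, samples, alpha = alpha, lfc_min = lfc_min)
  observed <- compute_depc(obs_pp)
  np <- length(obs_pp)
  obs_curve <- data.frame(
    threshold = seq_len(np),
    up = depc_tail_counts(observed$depc_up, np),
    down = depc_tail_counts(observed$depc_down, np))

  perms <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_perm), function(i) sample(length(normal_idx)))
  })
  perm_depc <- vector("list", n_perm)
  up_mat <- matrix(NA_integer_, n_perm, np)
  down_mat <- matrix(NA_integer_, n_perm, np)
  for (i in seq_len(n_perm)) {
    perm_samples <- samples
    perm_samples$patient_id[normal_idx] <-
      samples$patient_id[normal_idx][perms[[i]]]
    pp <- suppressWarnings(
      run_per_patient(counts, perm_samples, alpha = alpha,
                      lfc_min = lfc_min))
    d <- compute_depc(pp)
    perm_depc[[i]] <- d
    up_mat[i, ] <- depc_tail_counts(d$depc_up, np)
    down_mat[i, ] <- depc_tail_counts(d$depc_down, np)
  }
  list(observed = observed,
       observed_curve = obs_curve,
       perm_curves = list(up = up_mat, down = down_mat),
       mean = data.frame(threshold = seq_len(np),
                         up = colMeans(up_mat), down = colMeans(down_mat)),
       sd = data.frame(threshold = seq_len(np),
                       up = apply(up_mat, 2, stats::sd),
                       down = apply(down_mat, 2, stats::sd)),
       perm_depc = perm_depc)
}
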
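# Small fixture builders shared across test files.  Everything is generated
# in code under fixed seeds; no data files.

# minimal count matrix with dimnames
toy_counts <- function(body, genes = NULL, samples = NULL) {
  m <- as.matrix(body)
  storage.mode(m) <- "integer"
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a per-patient DE table from explicit calls
toy_de_table <- function(genes, calls, lfc = NULL) {
  data.frame(gene_id = genes,
             log2fc = lfc %||% ifelse(calls == "up", 2,
                                      ifelse(calls == "down", -2, 0)),
             se = 0.3, pvalue = ifelse(calls == "none", 0.8, 1e-6),
             padj = ifelse(calls == "none", 0.9, 1e-5),
             converged = TRUE, call = calls, stringsAsFactors = FALSE)
}

# two-group sample table: one normal + r tumours per patient
toy_sample_table <- function(n_patients, n_tumour = 2) {
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    pid <- sprintf("P%02d", p)
    data.frame(
      sample_id = c(paste0(pid, "_N"), paste0(pid, "_T", seq_len(n_tumour))),
      patient_id = pid,
      sample_type = c("normal", rep("tumour", n_tumour)),
      region = NA_character_, stringsAsFactors = FALSE)
  }))
}

# categorical matrix with planted row/column blocks
planted_categorical <- function(n_rows, n_cols, n_row_clusters = 3,
                                n_col_clusters = 3, modal_prob = 0.85,
                                seed = 1) {
  withr::with_seed(seed, {
    zr <- sample.int(n_row_clusters, n_rows, replace = TRUE)
    zc <- sample.int(n_col_clusters, n_cols, replace = TRUE)
    # block-separable: no two row clusters (or column clusters) may share
    # an identical modal-category signature, else they are unidentifiable
    repeat {
      modal <- matrix(sample(c(-1L, 0L, 1L), n_row_clusters * n_col_clusters,
                             replace = TRUE),
                      n_row_clusters, n_col_clusters)
      rows_ok <- !anyDuplicated(apply(modal, 1, paste, collapse = ","))
      cols_ok <- !anyDuplicated(apply(modal, 2, paste, collapse = ","))
      if (rows_ok && cols_ok) break
    }
    M <- matrix(0L, n_rows, n_cols,
                dimnames = list(paste0("g", seq_len(n_rows)),
                                paste0("p", seq_len(n_cols))))
    for (i in seq_len(n_rows)) {
      m <- modal[zr[i], zc]
      flip <- runif(n_cols) >= modal_prob
      others <- vapply(m, function(v) sample(setdiff(c(-1L, 0L, 1L), v), 1),
                       integer(1))
      M[i, ] <- ifelse(flip, others, m)
    }
    list(M = M, row_truth = zr, col_truth = zc, modal = modal)
  })
}

# labelled TND container without running the DE pipeline
toy_tnd <- function(X, labels, patients = NULL) {
  structure(list(x = X,
                 instance_id = rownames(X) %||% paste0("i", seq_len(nrow(X))),
                 patient_id = patients %||% paste0("pat", seq_len(nrow(X))),
                 label = labels),
            class = "tnd_matrix")
}
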
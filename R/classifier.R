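#' Tumour-normal-difference feature matrix
#'
#' One instance per tumour sample: the tumour sample's normalized expression
#' minus the patient's adjacent-normal column, restricted to the selected
#' genes.  Training instances inherit the patient's group label.
#'
#' @param norm Normalized expression matrix (genes x samples, log2 scale,
#'   e.g. from [tmm_cpm_log()]).
#' @param samples Sample table covering the columns of `norm`.
#' @param gene_subset Feature genes (rows of `norm`).
#' @param grouping Optional `data.frame(patient_id, group)` supplying labels.
#' @return `tnd_matrix` list: `x` (instances x genes), `instance_id`,
#'   `patient_id`, `label` (factor or NA).
#' @export
build_tnd <- function(norm, samples, gene_subset, grouping = NULL) {
  samples <- validate_sample_table(samples)
  samples <- samples[samples$sample_id %in% colnames(norm), , drop = FALSE]
  miss <- setdiff(gene_subset, rownames(norm))
  if (length(miss) > 0)
    stop("feature genes absent from the matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  tum <- samples[samples$sample_type == "tumour", , drop = FALSE]
  normals <- samples[samples$sample_type == "normal", , drop = FALSE]
  normal_of <- stats::setNames(normals$sample_id, normals$patient_id)
  no_normal <- setdiff(unique(tum$patient_id), names(normal_of))
  if (length(no_normal) > 0)
    stop("no normal sample for patient(s): ",
         paste(no_normal, collapse = ", "))
  X <- t(norm[gene_subset, tum$sample_id, drop = FALSE] -
           norm[gene_subset, normal_of[tum$patient_id], drop = FALSE])
  label <- rep(NA_character_, nrow(X))
  if (!is.null(grouping)) {
    grp <- stats::setNames(as.character(grouping$group), grouping$patient_id)
    label <- unname(grp[tum$patient_id])
  }
  out <- list(x = X, instance_id = tum$sample_id, patient_id = tum$patient_id,
              label = label)
  class(out) <- "tnd_matrix"
  out
}

#' MLP classifier configuration
#'
#' Four hidden linear layers; the first three use Kaiming (He) normal
#' initialization with rectifier activations and the last Xavier uniform
#' initialization with a softmax output.  Training uses stochastic gradient
#' descent with momentum and cross-entropy loss on random 70/30
#' instance-level splits.
#'
#' @param hidden Hidden layer widths (default `c(200, 100, 50)`).
#' @param lr Learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param epochs Training epochs per trial (default 500).
#' @param batch_size Minibatch size (default 32).
#' @param train_fraction Training share of the 7:3 split (default 0.7).
#' @param n_trials Ensemble trials (default 1000).
#' @param split_by_patient Keep all of a patient's instances on one side of
#'   the split (default FALSE: instance-level splits).
#' @return `mlp_config` list.
#' @export
mlp_config <- function(hidden = c(200, 100, 50), lr = 0.01, momentum = 0.9,
                       epochs = 500, batch_size = 32, train_fraction = 0.7,
                       n_trials = 1000, split_by_patient = FALSE) {
  stopifnot(all(hidden > 0), lr > 0, momentum >= 0, epochs > 0,
            batch_size > 0, train_fraction > 0, train_fraction < 1,
            n_trials > 0)
  structure(list(hidden = as.integer(hidden), lr = lr, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction,
                 n_trials = as.integer(n_trials),
                 split_by_patient = isTRUE(split_by_patient)),
            class = "mlp_config")
}

# initialize weights: Kaiming normal on the first three layers, Xavier
# uniform on the output layer; zero biases
mlp_init <- function(d_in, hidden, k) {
  dims <- c(d_in, hidden, k)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1]
    if (l < length(W)) {
      W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
                       fan_in, fan_out)
    } else {
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                       fan_in, fan_out)
    }
    b[[l]] <- numeric(fan_out)
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  a <- list()
  h <- X
  nl <- length(par$W)
  for (l in seq_len(nl - 1)) {
    h <- sweep(h %*% par$W[[l]], 2, par$b[[l]], "+")
    h[h < 0] <- 0
    a[[l]] <- h
  }
  logits <- sweep(h %*% par$W[[nl]], 2, par$b[[nl]], "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(activations = a, probs = probs)
}

# one SGD-with-momentum epoch over shuffled minibatches
mlp_epoch <- function(par, vel, X, y_onehot, cfg) {
  n <- nrow(X)
  idx <- sample.int(n)
  nl <- length(par$W)
  for (start in seq(1, n, by = cfg$batch_size)) {
    bi <- idx[start:min(start + cfg$batch_size - 1, n)]
    Xb <- X[bi, , drop = FALSE]
    fw <- mlp_forward(par, Xb)
    delta <- (fw$probs - y_onehot[bi, , drop = FALSE]) / length(bi)
    for (l in nl:1) {
      input <- if (l == 1) Xb else fw$activations[[l - 1]]
      gW <- crossprod(input, delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- delta %*% t(par$W[[l]])
        delta[fw$activations[[l - 1]] <= 0] <- 0
      }
      vel$W[[l]] <- cfg$momentum * vel$W[[l]] + gW
      vel$b[[l]] <- cfg$momentum * vel$b[[l]] + gb
      par$W[[l]] <- par$W[[l]] - cfg$lr * vel$W[[l]]
      par$b[[l]] <- par$b[[l]] - cfg$lr * vel$b[[l]]
    }
  }
  list(par = par, vel = vel)
}

mlp_fit <- function(X, y, k, cfg) {
  par <- mlp_init(ncol(X), cfg$hidden, k)
  vel <- list(W = lapply(par$W, function(w) w * 0),
              b = lapply(par$b, function(v) v * 0))
  y_onehot <- matrix(0, nrow(X), k)
  y_onehot[cbind(seq_len(nrow(X)), y)] <- 1
  for (ep in seq_len(cfg$epochs)) {
    st <- mlp_epoch(par, vel, X, y_onehot, cfg)
    par <- st$par; vel <- st$vel
  }
  par
}

mlp_predict <- function(par, X) max.col(mlp_forward(par, X)$probs,
                                        ties.method = "first")

#' Train and evaluate one MLP trial
#'
#' Random 70/30 split of the labelled instances, 500-epoch SGD training, and
#' argmax-softmax predictions on the held-out instances.  Splits leaving
#' fewer than two classes in the training set are resampled.
#'
#' @param tnd Labelled `tnd_matrix` from [build_tnd()].
#' @param config [mlp_config()].
#' @param trial_seed Integer seed for the split, initialization and batch
#'   order.
#' @return List with `model`, `test_idx`, `predictions` (on the test split),
#'   `accuracy` and the label `levels`.
#' @export
train_trial <- function(tnd, config = mlp_config(), trial_seed = 1L) {
  stopifnot(inherits(tnd, "tnd_matrix"), !anyNA(tnd$label))
  lv <- sort(unique(tnd$label))
  y <- match(tnd$label, lv)
  n <- nrow(tnd$x)
  withr::with_seed(as.integer(trial_seed), {
    for (attempt in 1:100) {
      if (config$split_by_patient) {
        pats <- unique(tnd$patient_id)
        tr_p <- sample(pats, max(1, round(config$train_fraction * length(pats))))
        tr <- which(tnd$patient_id %in% tr_p)
      } else {
        tr <- sample.int(n, max(2, round(config$train_fraction * n)))
      }
      if (length(unique(y[tr])) >= 2 && length(tr) < n) break
    }
    te <- setdiff(seq_len(n), tr)
    par <- mlp_fit(tnd$x[tr, , drop = FALSE], y[tr], length(lv), config)
    pred <- mlp_predict(par, tnd$x[te, , drop = FALSE])
    list(model = par, test_idx = te, predictions = lv[pred],
         accuracy = mean(lv[pred] == tnd$label[te]), levels = lv)
  })
}

#' Trial ensemble: train-cohort accuracies and predict-cohort label counts
#'
#' Repeats [train_trial()] `n_trials` times on fresh splits of the training
#' cohort, records each trial's held-out accuracy, and accumulates every
#' trial's predicted label for each instance of the unlabelled predict
#' cohort.
#'
#' @param tnd_train Labelled `tnd_matrix`.
#' @param tnd_predict `tnd_matrix` with the identical feature genes (same
#'   order); labels ignored.
#' @param config [mlp_config()].
#' @param seed Integer seed; trial seeds are derived from it.
#' @return List with `accuracy` (length `n_trials`), `counts` (predict
#'   instances x groups), `levels`, `n_trials`.
#' @export
run_trials <- function(tnd_train, tnd_predict, config = mlp_config(),
                       seed = 1L) {
  if (!identical(colnames(tnd_train$x), colnames(tnd_predict$x)))
    stop("train and predict feature spaces differ")
  lv <- sort(unique(tnd_train$label))
  counts <- matrix(0L, nrow(tnd_predict$x), length(lv),
                   dimnames = list(tnd_predict$instance_id, lv))
  acc <- numeric(config$n_trials)
  for (t in seq_len(config$n_trials)) {
    tr <- train_trial(tnd_train, config, trial_seed = seed * 1000L + t)
    acc[t] <- tr$accuracy
    pred <- mlp_predict(tr$model, tnd_predict$x)
    counts[cbind(seq_len(nrow(counts)), pred)] <-
      counts[cbind(seq_len(nrow(counts)), pred)] + 1L
  }
  list(accuracy = acc, counts = counts, levels = lv,
       n_trials = config$n_trials)
}

#' Aggregate per-trial predictions into final labels
#'
#' For each instance, tests the observed label counts against the uniform
#' expectation (`n_trials / k` per group) with the chi-square goodness-of-fit
#' test, adjusts across instances by Benjamini-Hochberg, and assigns the
#' label with the highest standardized residual when the adjusted p-value is
#' below `fdr_alpha`; otherwise the instance stays `unassigned`.  Residual
#' ties resolve to the lowest group index.
#'
#' @param counts Instances x groups matrix of predicted-label counts.
#' @param n_trials Number of trials the counts sum to.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return `data.frame` with instance_id, the per-group counts, p, fdr,
#'   label.
#' @export
aggregate_predictions <- function(counts, n_trials, fdr_alpha = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("instance", seq_len(nrow(counts)))
  k <- ncol(counts)
  stopifnot(all(abs(rowSums(counts) - n_trials) < 1e-9))
  expected <- rep(n_trials / k, k)
  tests <- apply(counts, 1, function(o) chisq_gof(o, expected))
  p <- vapply(tests, `[[`, numeric(1), "p")
  fdr <- bh_fdr(p)
  label <- vapply(seq_along(tests), function(i) {
    if (fdr[i] < fdr_alpha) {
      r <- tests[[i]]$residuals
      colnames(counts)[which.max(r)]  # which.max: lowest index on ties
    } else "unassigned"
  }, character(1))
  out <- data.frame(instance_id = rownames(counts), counts, p = p, fdr = fdr,
                    label = label, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  out
}

#' Patient-level summary of instance labels
#'
#' Majority vote of assigned instance labels per patient; patients whose
#' instances are all unassigned stay `unassigned`.
#'
#' @param labels Output of [aggregate_predictions()].
#' @param patient_id Patient of each instance (same order as the counts).
#' @return `data.frame` with patient_id, label.
#' @export
patient_labels <- function(labels, patient_id) {
  agg <- tapply(labels$label, patient_id, function(l) {
    l <- l[l != "unassigned"]
    if (length(l) == 0) return("unassigned")
    tt <- sort(table(l), decreasing = TRUE)
    names(tt)[1]
  })
  data.frame(patient_id = names(agg), label = unname(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}
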
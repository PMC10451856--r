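#' Training configuration
#'
#' Defaults follow the momentum-SGD recipe used for this architecture:
#' batch size 16, 50 epochs, starting learning rate 0.004, momentum 0.9,
#' weight decay 0.0001, and a hard cap of 501 optimizer iterations. The
#' epoch budget and the iteration cap are both honored — training stops at
#' whichever is reached first (with full-scale augmented training sets the
#' iteration cap binds well before one epoch completes).
#'
#' @param batch_size Samples per SGD step.
#' @param epochs Maximum passes over the training samples.
#' @param max_iterations Hard cap on optimizer steps.
#' @param lr Learning rate (constant; no decay schedule).
#' @param momentum Classical momentum coefficient.
#' @param weight_decay L2 penalty coefficient applied inside the update.
#' @param loss_weights Per-phase weights of the multi-phase loss; `NULL`
#'   means equal weights. Normalized to sum to 1.
#' @param early_stop_patience Number of consecutive validation evaluations
#'   without improvement before stopping; `Inf` disables early stopping.
#' @param eval_every Validation-evaluation cadence in iterations (the
#'   "learning curve" granularity when an epoch exceeds the iteration cap).
#' @param global_fraction If `NULL` (default), local and global cubes are
#'   mixed uniformly at random, so at the full augmented scale batches are
#'   almost entirely local cubes. If a fraction in `(0, 1)`, every batch is
#'   drawn with that share of global cubes (resampled i.i.d. per
#'   iteration), which matches the global-cube test-time protocol when
#'   training runs are short.
#' @param seed Integer seed for shuffling, dropout and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, epochs = 50L, max_iterations = 501L,
                         lr = 0.004, momentum = 0.9, weight_decay = 1e-4,
                         loss_weights = NULL, early_stop_patience = 5,
                         eval_every = 50L, global_fraction = NULL, seed = 1L) {
  cfg <- list(
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    max_iterations = as.integer(max_iterations), lr = lr, momentum = momentum,
    weight_decay = weight_decay, loss_weights = loss_weights,
    early_stop_patience = early_stop_patience,
    eval_every = as.integer(eval_every),
    global_fraction = global_fraction, seed = as.integer(seed)
  )
  stopifnot(
    cfg$batch_size >= 1, cfg$epochs >= 1, cfg$max_iterations >= 1,
    cfg$lr >= 0, cfg$momentum >= 0, cfg$momentum < 1, cfg$weight_decay >= 0,
    cfg$early_stop_patience > 0, cfg$eval_every >= 1
  )
  if (!is.null(cfg$loss_weights)) stopifnot(all(cfg$loss_weights > 0))
  if (!is.null(cfg$global_fraction)) {
    stopifnot(cfg$global_fraction > 0, cfg$global_fraction < 1)
  }
  structure(cfg, class = "train_config")
}

.norm_weights <- function(loss_weights, n_phases) {
  w <- if (is.null(loss_weights)) rep(1, n_phases) else loss_weights
  if (length(w) != n_phases) {
    stop("need one loss weight per phase (", n_phases, ")")
  }
  w / sum(w)
}

#' Weighted multi-phase classification loss
#'
#' `L = sum_x omega_x * CE_x`: the weighted sum of the per-phase
#' cross-entropies of the phase (auxiliary) heads. Weights are normalized
#' to sum to 1, so with every head at the uninformed point (0.5, 0.5) the
#' loss is exactly `log(2)` regardless of the weights. For a single-phase
#' model this reduces to plain cross-entropy. (During fusion training the
#' fused head's own cross-entropy is added to this with weight 1.)
#'
#' @param phase_logits List (one per phase) of 2 x B logit matrices, or a
#'   single matrix for a single-phase model.
#' @param labels Integer vector of 0/1 labels, length B.
#' @param loss_weights Per-phase weights (`NULL` = equal).
#' @return Scalar loss.
#' @export
multi_phase_loss <- function(phase_logits, labels, loss_weights = NULL) {
  if (!is.list(phase_logits)) phase_logits <- list(phase_logits)
  w <- .norm_weights(loss_weights, length(phase_logits))
  loss <- 0
  for (i in seq_along(phase_logits)) {
    loss <- loss + w[i] * .ce_from_logits(phase_logits[[i]], labels)$loss
  }
  if (!is.finite(loss)) stop("non-finite multi-phase loss")
  loss
}

# Assemble a batch: named list per phase of (4096, 1, B) z-scored cubes,
# plus the label vector, from manifest rows.
.assemble_batch <- function(rows, cache, phases) {
  b <- nrow(rows)
  xs <- lapply(phases, function(ph) {
    x <- array(0, dim = c(4096L, 1L, b))
    for (i in seq_len(b)) {
      x[, 1L, i] <- as.vector(.fetch_cube(
        cache, rows$patient_id[i], rows$kind[i],
        rows$ox[i], rows$oy[i], rows$oz[i], ph
      ))
    }
    x
  })
  names(xs) <- phases
  list(xs = xs, labels = as.integer(rows$label))
}

# Loss and gradient of one batch. Returns list(loss, grads).
.batch_loss_grads <- function(model, xs, labels, loss_weights) {
  phases <- model$config$phases
  fusion <- length(phases) > 1
  fwd <- .network_forward(model, xs, train = TRUE, keep_cache = TRUE)
  w <- .norm_weights(loss_weights, length(phases))
  if (fusion) {
    fused <- .ce_from_logits(fwd$logits, labels)
    loss <- fused$loss
    dphase <- list()
    for (i in seq_along(phases)) {
      aux <- .ce_from_logits(fwd$logits_phase[[phases[i]]], labels)
      loss <- loss + w[i] * aux$loss
      dphase[[phases[i]]] <- w[i] * aux$dlogits
    }
    bwd <- .network_backward(model, fwd, fused$dlogits, dphase)
  } else {
    ce <- .ce_from_logits(fwd$logits, labels)
    loss <- ce$loss
    bwd <- .network_backward(model, fwd, ce$dlogits)
  }
  if (!is.finite(loss)) stop("non-finite training loss")
  list(loss = loss, grads = bwd$grads)
}

# Predict class-1 probability for a set of manifest rows (global cubes),
# in evaluation mode, chunked.
.predict_rows <- function(model, rows, cache, chunk = 32L) {
  phases <- model$config$phases
  n <- nrow(rows)
  probs <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    bt <- .assemble_batch(rows[i:j, ], cache, phases)
    fwd <- .network_forward(model, bt$xs, train = FALSE)
    probs[i:j] <- fwd$prob[2, ]
    i <- j + 1L
  }
  probs
}

#' Train one cross-validation fold
#'
#' Momentum SGD over the fold's training samples (local + global cubes,
#' shuffled each epoch) with the weighted multi-phase loss; the held-out
#' fold's global cubes serve as the validation set. Training stops at the
#' epoch budget, the iteration cap, or when validation loss has not
#' improved for `early_stop_patience` consecutive evaluations; the
#' returned parameters are those of the best validation evaluation.
#'
#' @param dataset A [build_training_dataset()] result.
#' @param cache The matching [prepare_cube_cache()].
#' @param fold Fold index in `0:(n_folds-1)` held out for validation.
#' @param net_config A [network_config()].
#' @param tr_config A [train_config()].
#' @param verbose Print the learning curve as it is produced?
#' @return A `fold_model`: list with `model` (best-validation weights),
#'   `fold`, `curve` (tibble: iteration, train_loss, val_loss, val_auc),
#'   `stopped_at` (iterations used) and `best_val_loss`.
#' @export
train_fold <- function(dataset, cache, fold, net_config, tr_config,
                       verbose = FALSE) {
  stopifnot(inherits(net_config, "network_config"), inherits(tr_config, "train_config"))
  manifest <- dataset$train
  tr_rows <- manifest[manifest$fold != fold, ]
  val_rows <- manifest[manifest$fold == fold & manifest$kind == "global", ]
  if (nrow(val_rows) == 0) stop("fold ", fold, " has no validation patients")
  if (length(unique(val_rows$label)) < 2) {
    stop("validation fold ", fold, " contains a single class")
  }
  phases <- net_config$phases
  w <- .norm_weights(tr_config$loss_weights, length(phases))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.patient_seed(tr_config$seed, 7000L + fold))

  model <- network_init(net_config, seed = .patient_seed(tr_config$seed, 9000L + fold))
  velocity <- .params_zero_like(model$params)

  n_tr <- nrow(tr_rows)
  bs <- tr_config$batch_size
  steps_per_epoch <- ceiling(n_tr / bs)
  iter <- 0L
  best <- list(val_loss = Inf, params = model$params, iter = 0L)
  bad_evals <- 0L
  curve <- list()
  running_loss <- c()
  stopped <- FALSE

  eval_point <- function() {
    val_probs <- .predict_rows(model, val_rows, cache)
    vl <- -mean(log(pmax(ifelse(val_rows$label == 1, val_probs, 1 - val_probs), 1e-12)))
    va <- auc_rank(val_probs, val_rows$label)
    curve[[length(curve) + 1L]] <<- tibble::tibble(
      iteration = iter,
      train_loss = mean(running_loss),
      val_loss = vl, val_auc = va
    )
    running_loss <<- c()
    if (verbose) {
      message(sprintf(
        "iter %4d  train %.4f  val %.4f  val AUC %.3f",
        iter, curve[[length(curve)]]$train_loss, vl, va
      ))
    }
    if (vl < best$val_loss - 1e-9) {
      best <<- list(val_loss = vl, params = model$params, iter = iter)
      bad_evals <<- 0L
    } else {
      bad_evals <<- bad_evals + 1L
    }
    bad_evals >= tr_config$early_stop_patience
  }

  glob_idx <- which(tr_rows$kind == "global")
  loc_idx <- which(tr_rows$kind == "local")
  n_glob <- if (is.null(tr_config$global_fraction)) 0L else {
    max(1L, round(bs * tr_config$global_fraction))
  }
  for (epoch in seq_len(tr_config$epochs)) {
    ord <- sample.int(n_tr)
    for (s in seq_len(steps_per_epoch)) {
      if (n_glob > 0L) {
        take <- c(
          glob_idx[sample.int(length(glob_idx), n_glob, replace = TRUE)],
          loc_idx[sample.int(length(loc_idx), bs - n_glob)]
        )
      } else {
        take <- ord[((s - 1L) * bs + 1L):min(s * bs, n_tr)]
      }
      bt <- .assemble_batch(tr_rows[take, ], cache, phases)
      bg <- .batch_loss_grads(model, bt$xs, bt$labels, tr_config$loss_weights)
      upd <- .sgd_step(model$params, bg$grads, velocity,
        tr_config$lr, tr_config$momentum, tr_config$weight_decay)
      model$params <- upd$p
      velocity <- upd$v
      iter <- iter + 1L
      running_loss <- c(running_loss, bg$loss)
      if (iter %% tr_config$eval_every == 0L) {
        if (eval_point()) stopped <- TRUE
      }
      if (stopped || iter >= tr_config$max_iterations) break
    }
    if (stopped || iter >= tr_config$max_iterations) break
  }
  if (length(running_loss) > 0 || length(curve) == 0) eval_point()

  model$params <- best$params
  structure(
    list(
      model = model, fold = as.integer(fold),
      curve = dplyr::bind_rows(curve),
      stopped_at = iter, best_val_loss = best$val_loss,
      best_iter = best$iter
    ),
    class = "fold_model"
  )
}

#' Train all cross-validation folds
#'
#' @inheritParams train_fold
#' @param folds Which folds to train (default all in the dataset).
#' @return An `mvi_cv` object: list of `fold_models` plus the configs.
#' @export
train_cv <- function(dataset, cache, net_config, tr_config,
                     folds = NULL, verbose = FALSE) {
  if (is.null(folds)) folds <- sort(unique(dataset$train$fold))
  fold_models <- lapply(folds, function(f) {
    train_fold(dataset, cache, f, net_config, tr_config, verbose = verbose)
  })
  structure(
    list(
      fold_models = fold_models,
      net_config = net_config, tr_config = tr_config
    ),
    class = "mvi_cv"
  )
}

#' Ensemble prediction over cross-validation folds
#'
#' Averages the softmax class-1 probabilities of the fold models on each
#' test patient's global cube.
#'
#' @param cv An `mvi_cv` (or list of `fold_model`s).
#' @param rows Manifest rows to score (typically `dataset$test`).
#' @param cache The matching [prepare_cube_cache()].
#' @return Tibble `patient_id`, `label`, `score` (ensemble MVI
#'   probability), plus one `score_fold<k>` column per fold.
#' @export
ensemble_predict <- function(cv, rows, cache) {
  fms <- if (inherits(cv, "mvi_cv")) cv$fold_models else cv
  if (length(fms) == 0) stop("no fold models supplied")
  per_fold <- lapply(fms, function(fm) .predict_rows(fm$model, rows, cache))
  mat <- do.call(cbind, per_fold)
  out <- tibble::tibble(
    patient_id = rows$patient_id,
    label = as.integer(rows$label),
    score = rowMeans(mat)
  )
  for (k in seq_along(per_fold)) {
    out[[paste0("score_fold", fms[[k]]$fold)]] <- per_fold[[k]]
  }
  out
}
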
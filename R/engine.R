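#' Training configuration
#'
#' The adopted optimisation protocol: adaptive-moment (Adam) optimisation at
#' a constant learning rate of 1e-4, mini-batches of 4 slices, up to 150
#' epochs, with the best checkpoint selected on mean test Dice after every
#' epoch.
#'
#' @param learning_rate positive Adam learning rate (default 1e-4).
#' @param batch_size mini-batch size (default 4).
#' @param max_epochs maximum training epochs (default 150).
#' @param seed integer seed covering weight initialisation, data order and
#'   augmentation.
#' @param checkpoint_dir directory for the best checkpoint, or `NULL` to
#'   keep it in memory only.
#' @param augment apply random paired augmentation to training batches
#'   (test slices are never augmented).
#' @param augment_ops which augmentation ops to draw from, see [augment()].
#' @param device compute target; only `"cpu"` is supported.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L, max_epochs = 150L,
                         seed = 1L, checkpoint_dir = NULL, augment = FALSE,
                         augment_ops = c("rotate", "flip", "scale", "contrast", "noise"),
                         device = "cpu") {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    abort_value("`learning_rate` must be positive")
  }
  check_count(batch_size, "batch_size")
  check_count(max_epochs, "max_epochs")
  if (!identical(device, "cpu")) abort_config("only device = \"cpu\" is supported")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed),
         checkpoint_dir = checkpoint_dir, augment = isTRUE(augment),
         augment_ops = augment_ops, device = device),
    class = "train_config"
  )
}

#' Deterministic k-fold split
#'
#' Seeded shuffle followed by round-robin assignment, so every sample lands
#' in exactly one test fold and fold sizes differ by at most one.
#'
#' @param sample_ids character vector of unique ids.
#' @param n_folds number of folds (>= 2; default 5).
#' @param seed shuffle seed.
#' @param groups optional grouping vector aligned with `sample_ids` (e.g.
#'   patient ids): groups are assigned to folds as units, so no group spans
#'   a train/test boundary. Slice-level splitting (the default) matches
#'   practice on slice-annotated collections.
#' @return a `fold_manifest` tibble (`sample_id`, `fold`) with `n_folds` and
#'   `seed` attributes.
#' @export
five_fold_split <- function(sample_ids, n_folds = 5L, seed = 1L, groups = NULL) {
  check_count(n_folds, "n_folds")
  if (n_folds < 2L) abort_value("`n_folds` must be at least 2")
  if (anyDuplicated(sample_ids)) abort_value("`sample_ids` must be unique")
  if (length(sample_ids) < n_folds) {
    abort_value("need at least ", n_folds, " samples for ", n_folds, " folds, got ",
                length(sample_ids))
  }
  if (!is.null(groups)) {
    if (length(groups) != length(sample_ids)) {
      abort_value("`groups` must align with `sample_ids`")
    }
    gids <- unique(groups)
    if (length(gids) < n_folds) {
      abort_value("need at least ", n_folds, " groups for ", n_folds, " folds, got ",
                  length(gids))
    }
    gshuf <- withr::with_seed(seed, sample(gids))
    gfold <- setNames(rep_len(seq_len(n_folds), length(gshuf)), gshuf)
    manifest <- tibble::tibble(
      sample_id = sample_ids,
      fold = as.integer(gfold[as.character(groups)])
    ) |> dplyr::arrange(.data$sample_id)
    attr(manifest, "n_folds") <- as.integer(n_folds)
    attr(manifest, "seed") <- as.integer(seed)
    class(manifest) <- c("fold_manifest", class(manifest))
    return(manifest)
  }
  shuffled <- withr::with_seed(seed, sample(sample_ids))
  manifest <- tibble::tibble(
    sample_id = shuffled,
    fold = rep_len(seq_len(n_folds), length(shuffled))
  ) |> dplyr::arrange(.data$sample_id)
  attr(manifest, "n_folds") <- as.integer(n_folds)
  attr(manifest, "seed") <- as.integer(seed)
  class(manifest) <- c("fold_manifest", class(manifest))
  manifest
}

#' Write / read a fold manifest as JSON
#' @param manifest a [five_fold_split()] result.
#' @param path JSON file path.
#' @return `path` (write) or the manifest (read).
#' @export
write_fold_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(n_folds = attr(manifest, "n_folds"), seed = attr(manifest, "seed"),
         assignment = setNames(as.list(manifest$fold), manifest$sample_id)),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_fold_manifest
#' @export
read_fold_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  manifest <- tibble::tibble(sample_id = names(j$assignment),
                             fold = as.integer(unlist(j$assignment))) |>
    dplyr::arrange(.data$sample_id)
  attr(manifest, "n_folds") <- as.integer(j$n_folds)
  attr(manifest, "seed") <- as.integer(j$seed)
  class(manifest) <- c("fold_manifest", class(manifest))
  manifest
}

# stack a list of slice_pairs into (1,H,W,B) image and mask tensors
stack_pairs <- function(pairs) {
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  B <- length(pairs)
  x <- array(0, dim = c(1L, H, W, B))
  y <- array(0, dim = c(1L, H, W, B))
  for (i in seq_len(B)) {
    x[1L, , , i] <- pairs[[i]]$image
    y[1L, , , i] <- pairs[[i]]$mask
  }
  list(x = x, y = y)
}

# batched inference: list of probability matrices, one per pair
predict_prob_pairs <- function(model, pairs, chunk = 8L) {
  dims <- vapply(pairs, function(p) paste(dim(p$image), collapse = "x"), "")
  if (length(unique(dims)) > 1L) chunk <- 1L # mixed sizes: no batching
  out <- vector("list", length(pairs))
  for (start in seq(1L, length(pairs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(pairs))
    tb <- stack_pairs(pairs[idx])
    y <- ag_val(forward(model, tb$x, training = FALSE))
    for (j in seq_along(idx)) out[[idx[j]]] <- matrix(y[1L, , , j], dim(y)[2], dim(y)[3])
  }
  out
}

default_eval_fn <- function(model, pairs, loss_cfg, threshold) {
  probs <- predict_prob_pairs(model, pairs)
  per <- purrr::map2_dfr(pairs, probs, function(pr, p) {
    row <- metrics_from_counts(confusion(binarize(p, threshold), pr$mask),
                               slice_id = pr$slice_id)
    row$loss <- total_loss(as.numeric(pr$mask), as.numeric(p), loss_cfg)
    row
  })
  list(mean_dice = mean(per$dice), test_loss = mean(per$loss),
       per_slice = dplyr::select(per, -"loss"))
}

#' Train the network on one fold
#'
#' Mini-batch Adam optimisation of the hybrid BCE + Dice objective; after
#' each epoch the test slices are scored and a strictly better mean test
#' Dice overwrites the saved best checkpoint. The returned model carries the
#' best (not last) weights. Training is fully seeded: weight initialisation,
#' batch order and augmentation all derive from `train_cfg$seed`.
#'
#' @param train_pairs,test_pairs non-empty lists of `slice_pair`.
#' @param model_cfg a [model_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param eval_fn test-set scorer `function(model, pairs)` returning at
#'   least `mean_dice` and `test_loss`; the default computes the full metric
#'   suite. Injectable so the checkpoint-selection rule can be audited with
#'   a scripted evaluator.
#' @return list with `model` (best weights), `log` (tibble: epoch,
#'   train_loss, test_loss, test_dice), `best_epoch`, `best_dice`,
#'   `checkpoint_path` (or `NULL`), and `consumed_ids` (ids seen by gradient
#'   steps, for leakage audits).
#' @export
train_fold <- function(train_pairs, test_pairs,
                       model_cfg = model_config(), loss_cfg = loss_config(),
                       train_cfg = train_config(), eval_fn = NULL) {
  if (length(train_pairs) == 0L || length(test_pairs) == 0L) {
    abort_value("`train_pairs` and `test_pairs` must be non-empty")
  }
  if (is.null(eval_fn)) {
    eval_fn <- function(model, pairs) {
      default_eval_fn(model, pairs, loss_cfg, model_cfg$output_threshold)
    }
  }
  set.seed(train_cfg$seed)
  model <- hemo_net(model_cfg)
  params <- parameters(model)
  opt <- new_adam(params, lr = train_cfg$learning_rate)
  n <- length(train_pairs)
  log <- vector("list", train_cfg$max_epochs)
  best_dice <- -Inf
  best_epoch <- NA_integer_
  best_state <- NULL
  checkpoint_path <- NULL
  consumed <- character()

  for (epoch in seq_len(train_cfg$max_epochs)) {
    order <- sample.int(n)
    batch_losses <- numeric()
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- order[start:min(start + train_cfg$batch_size - 1L, n)]
      batch <- train_pairs[idx]
      if (train_cfg$augment) {
        batch <- lapply(batch, augment, ops = train_cfg$augment_ops)
      }
      consumed <- union(consumed, vapply(batch, `[[`, "", "slice_id"))
      tb <- stack_pairs(batch)
      loss_val <- NA_real_
      with_tape({
        p <- forward(model, tb$x, training = TRUE)
        loss <- ag_hybrid_loss(p, tb$y, loss_cfg)
        loss_val <- ag_val(loss)
        if (!is.finite(loss_val)) {
          abort_value("non-finite loss at epoch ", epoch, ", batch starting at ", start)
        }
        ag_backward(loss)
      })
      opt$step()
      zero_grads(params)
      batch_losses <- c(batch_losses, loss_val)
    }
    ev <- eval_fn(model, test_pairs)
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(batch_losses),
      test_loss = ev$test_loss, test_dice = ev$mean_dice
    )
    if (ev$mean_dice > best_dice) {
      best_dice <- ev$mean_dice
      best_epoch <- epoch
      best_state <- module_state(model)
      if (!is.null(train_cfg$checkpoint_dir)) {
        checkpoint_path <- file.path(train_cfg$checkpoint_dir, "best_checkpoint.rds")
        save_checkpoint(model, checkpoint_path)
      }
    }
  }
  load_module_state(model, best_state)
  structure(
    list(model = model, log = dplyr::bind_rows(log), best_epoch = best_epoch,
         best_dice = best_dice, checkpoint_path = checkpoint_path,
         consumed_ids = consumed),
    class = "train_result"
  )
}

#' Evaluate a model (or checkpoint) on slice pairs
#'
#' Forward pass, thresholding, confusion counting and metric aggregation per
#' slice; no parameters are updated.
#'
#' @param model an `hs_hemo_net` module or a checkpoint file path.
#' @param pairs list of `slice_pair`.
#' @param threshold binarisation threshold (default from the model config).
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, pairs, threshold = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!inherits(model, "hs_hemo_net")) abort_config("`model` must be an hs_hemo_net or checkpoint path")
  if (length(pairs) == 0L) abort_value("`pairs` must be non-empty")
  threshold <- threshold %||% model$cfg$output_threshold
  probs <- predict_prob_pairs(model, pairs)
  per <- purrr::map2_dfr(pairs, probs, function(pr, p) {
    metrics_from_counts(confusion(binarize(p, threshold), pr$mask),
                        slice_id = pr$slice_id)
  })
  aggregate_metrics(per)
}

#' Cross-validate over a fold manifest
#'
#' For each fold, trains on the complement and evaluates on the fold, so
#' every sample is test-scored exactly once; per-fold reports and the pooled
#' per-slice aggregate are returned. Fold `k` trains with seed
#' `train_cfg$seed + k`.
#'
#' @param pairs list of `slice_pair` covering the manifest.
#' @param manifest a [five_fold_split()] result over the pair ids.
#' @param model_cfg,loss_cfg,train_cfg configurations as in [train_fold()].
#' @return list with `fold_reports` (list of `metrics_report`), `pooled`
#'   (`metrics_report` over all slices), `logs` (per-fold train logs) and
#'   `results` (per-fold `train_result`s).
#' @export
cross_validate <- function(pairs, manifest, model_cfg = model_config(),
                           loss_cfg = loss_config(), train_cfg = train_config()) {
  ids <- vapply(pairs, `[[`, "", "slice_id")
  if (!setequal(ids, manifest$sample_id)) {
    abort_value("manifest ids do not match the provided pairs")
  }
  n_folds <- attr(manifest, "n_folds")
  fold_of <- setNames(manifest$fold, manifest$sample_id)
  fold_reports <- vector("list", n_folds)
  logs <- vector("list", n_folds)
  results <- vector("list", n_folds)
  per_rows <- list()
  for (k in seq_len(n_folds)) {
    test_idx <- which(fold_of[ids] == k)
    cfg_k <- train_cfg
    cfg_k$seed <- train_cfg$seed + k
    res <- train_fold(pairs[-test_idx], pairs[test_idx],
                      model_cfg, loss_cfg, cfg_k)
    rep_k <- evaluate(res$model, pairs[test_idx])
    fold_reports[[k]] <- rep_k
    logs[[k]] <- res$log
    results[[k]] <- res
    per_rows[[k]] <- rep_k$per_slice
  }
  list(fold_reports = fold_reports,
       pooled = aggregate_metrics(dplyr::bind_rows(per_rows)),
       logs = logs, results = results)
}
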
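# Dataset handling and the training/evaluation pipeline.
#
# A DTI dataset is a plain data frame with columns `smiles`, `sequence`,
# `label` (0/1), optionally `binding_sites` (comma-separated 1-based residue
# positions for annotated samples) and, after splitting, `split` with values
# train/valid/test.

#' Drop samples whose SMILES cannot be parsed
#'
#' @param samples DTI data frame with a `smiles` column.
#' @param quiet Suppress the dropped-count message.
#' @return The data frame restricted to chemically parseable SMILES.
#' @export
filter_invalid_smiles <- function(samples, quiet = FALSE) {
  if (nrow(samples) == 0L) return(samples)
  ok <- smiles_is_valid(samples$smiles)
  if (!quiet && any(!ok)) {
    message(sum(!ok), " sample(s) removed: SMILES not parseable")
  }
  samples[ok, , drop = FALSE]
}

#' Split a DTI dataset and balance training negatives
#'
#' Positive samples are partitioned into training, validation and test sets at
#' the given ratio (floor for validation and test, remainder to training).
#' Training negatives are then down-sampled to exactly the number of training
#' positives; all remaining negatives go to validation and test, divided in
#' proportion to the validation:test ratio elements. Test sets therefore keep
#' their natural negative skew.
#'
#' @param samples DTI data frame (columns `smiles`, `sequence`, `label`).
#' @param ratios Length-3 positive split ratio (default `c(7, 1, 2)`).
#' @param seed RNG seed making the split reproducible.
#' @return The data frame with an added `split` column.
#' @export
split_dataset <- function(samples, ratios = c(7, 1, 2), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0))
  pos <- which(samples$label == 1)
  neg <- which(samples$label == 0)
  if (length(pos) == 0L) stop("dataset has no positive samples")
  set.seed(seed)
  pos <- sample(pos)
  neg <- sample(neg)
  n <- length(pos)
  n_valid <- floor(n * ratios[2L] / sum(ratios))
  n_test <- floor(n * ratios[3L] / sum(ratios))
  n_train <- n - n_valid - n_test
  split <- rep(NA_character_, nrow(samples))
  split[pos[seq_len(n_train)]] <- "train"
  if (n_valid > 0L) split[pos[n_train + seq_len(n_valid)]] <- "valid"
  if (n_test > 0L) split[pos[n_train + n_valid + seq_len(n_test)]] <- "test"
  n_train_neg <- min(n_train, length(neg))
  if (n_train_neg > 0L) split[neg[seq_len(n_train_neg)]] <- "train"
  rest <- neg[setdiff(seq_along(neg), seq_len(n_train_neg))]
  if (length(rest) > 0L) {
    vt <- ratios[2L] + ratios[3L]
    n_valid_neg <- if (vt > 0) floor(length(rest) * ratios[2L] / vt) else 0L
    split[rest[seq_len(n_valid_neg)]] <- "valid"
    if (length(rest) > n_valid_neg)
      split[rest[(n_valid_neg + 1L):length(rest)]] <- "test"
  }
  samples$split <- split
  samples
}

# rows usable by a scheme (SELFIES schemes skip unconvertible SMILES)
scheme_usable <- function(samples, scheme) {
  if (!grepl("selfies", scheme)) return(rep(TRUE, nrow(samples)))
  vapply(samples$smiles, function(s) {
    !inherits(tryCatch(selfies_encode(s), error = identity), "error")
  }, logical(1), USE.NAMES = FALSE)
}

#' Train a DTI model
#'
#' Mini-batch Adam training with binary cross-entropy loss. Vocabularies are
#' mined on the training split (unless supplied), loss is logged per epoch,
#' and the returned checkpoint holds the parameters of the epoch with the best
#' validation PRAUC (falling back to the final epoch when the validation split
#' cannot score an AUC).
#'
#' @param dataset Split DTI data frame (see [split_dataset()]).
#' @param arch Architecture name (default `"CA_P"`).
#' @param scheme Encoding scheme (default `"fcs_embed"`).
#' @param max_len_drug,max_len_protein,hidden,heads Model dimensions
#'   (defaults 50, 545, 384, 4).
#' @param lr Learning rate (default 0.001).
#' @param epochs Maximum training epochs (default 50).
#' @param batch_size Mini-batch size (default 128).
#' @param seed Seed covering initialisation, shuffling and dropout.
#' @param min_freq,max_vocab_drug,max_vocab_protein FCS mining controls.
#' @param head_opts Output-head overrides (see [dti_model()]).
#' @param vocabs Optional pre-built vocabulary list (`drug`, `protein`).
#' @param scale,mask_keys Attention options (see [dti_model()]).
#' @param verbose Print per-epoch progress.
#' @return A `dti_checkpoint`: the trained model, per-epoch history, the
#'   configuration, and the best epoch index.
#' @export
train_dti <- function(dataset, arch = "CA_P", scheme = "fcs_embed",
                      max_len_drug = 50L, max_len_protein = 545L,
                      hidden = 384L, heads = 4L, lr = 0.001, epochs = 50L,
                      batch_size = 128L, seed = 1L, min_freq = 5L,
                      max_vocab_drug = 2000L, max_vocab_protein = 10000L,
                      head_opts = list(), vocabs = NULL, scale = "sqrt_d",
                      mask_keys = TRUE, verbose = FALSE) {
  stopifnot("split" %in% names(dataset))
  usable <- scheme_usable(dataset, scheme)
  if (any(!usable)) message(sum(!usable), " sample(s) skipped: SELFIES conversion failed")
  dataset <- dataset[usable, , drop = FALSE]
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "valid")
  if (length(tr) == 0L) stop("empty training split")
  set.seed(seed)
  if (is.null(vocabs)) {
    vocabs <- build_vocabularies(dataset$smiles[tr], dataset$sequence[tr],
                                 scheme, min_freq, max_vocab_drug,
                                 max_vocab_protein)
  }
  model <- dti_model(vocabs$drug, vocabs$protein, arch = arch, scheme = scheme,
                     max_len_drug = max_len_drug, max_len_protein = max_len_protein,
                     hidden = hidden, heads = heads, head_opts = head_opts,
                     scale = scale, mask_keys = mask_keys)
  enc <- model_encode(model, dataset$smiles, dataset$sequence)
  y <- dataset$label
  state <- adam_init(model$params)
  can_validate <- length(va) > 0L && length(unique(y[va])) == 2L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        valid_prauc = numeric(0))
  best <- list(prauc = -Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(epochs)) {
    idx <- sample(tr)
    losses <- numeric(0)
    for (s in split(idx, ceiling(seq_along(idx) / batch_size))) {
      batch <- encode_batch_inputs(model, enc, s)
      fw <- model_forward(model, batch, train = TRUE)
      losses <- c(losses, bce_loss(fw$prob, y[s]))
      grads <- model_backward(model, fw, y[s])
      upd <- adam_step(model$params, grads, state, lr = lr)
      model$params <- upd$params
      state <- upd$state
    }
    vp <- NA_real_
    if (can_validate) {
      vs <- predict(model, enc = enc, idx = va, batch_size = batch_size)
      vp <- pr_auc(vs, y[va])
      if (vp > best$prauc) best <- list(prauc = vp, params = model$params, epoch = ep)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         valid_prauc = vp))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  valid PRAUC %s\n", ep, mean(losses),
                  ifelse(is.na(vp), "-", sprintf("%.4f", vp))))
    }
  }
  if (can_validate) model$params <- best$params else best$epoch <- epochs
  structure(list(
    model = model, history = history, best_epoch = best$epoch,
    config = list(arch = arch, scheme = scheme, heads = heads, lr = lr,
                  epochs = epochs, batch_size = batch_size, seed = seed,
                  max_len_drug = max_len_drug, max_len_protein = max_len_protein,
                  hidden = hidden)
  ), class = "dti_checkpoint")
}

#' @export
print.dti_checkpoint <- function(x, ...) {
  cat(sprintf("<dti_checkpoint> %s, %d epochs (best %d), final loss %.4f\n",
              x$model$arch, nrow(x$history), x$best_epoch,
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Evaluate a checkpoint on one dataset split
#'
#' @param checkpoint A `dti_checkpoint` from [train_dti()].
#' @param dataset Split DTI data frame.
#' @param split Which split to score (default `"test"`).
#' @param threshold Decision threshold for SN/SP/PR/F1.
#' @param batch_size Evaluation batch size.
#' @return Named metric vector from [dti_metrics()].
#' @export
evaluate_dti <- function(checkpoint, dataset, split = "test", threshold = 0.5,
                         batch_size = 64L) {
  usable <- scheme_usable(dataset, checkpoint$model$scheme)
  dataset <- dataset[usable, , drop = FALSE]
  idx <- which(dataset$split == split)
  if (length(idx) == 0L) stop("no samples in split '", split, "'")
  if (length(unique(dataset$label[idx])) < 2L)
    stop("AUC metrics undefined: split '", split, "' has a single class")
  scores <- predict(checkpoint$model, dataset$smiles[idx], dataset$sequence[idx],
                    batch_size = batch_size)
  dti_metrics(scores, dataset$label[idx], threshold)
}

#' Train and evaluate over several independent runs
#'
#' Repeats [train_dti()] + [evaluate_dti()] with seeds `base_seed`,
#' `base_seed + 1`, ... (re-seeding initialisation, shuffling and dropout; the
#' data split is fixed) and averages the metrics.
#'
#' @param dataset Split DTI data frame.
#' @param n_runs Number of runs (default 5).
#' @param base_seed First seed.
#' @param split Evaluation split.
#' @param ... Passed to [train_dti()].
#' @return List with `mean` (averaged metrics), `per_run` (runs x metrics
#'   matrix) and `seeds`.
#' @export
multi_run <- function(dataset, n_runs = 5L, base_seed = 1L, split = "test", ...) {
  stopifnot(n_runs >= 1L)
  seeds <- base_seed + seq_len(n_runs) - 1L
  per_run <- NULL
  for (s in seeds) {
    ck <- train_dti(dataset, seed = s, ...)
    m <- evaluate_dti(ck, dataset, split = split)
    per_run <- rbind(per_run, m)
  }
  rownames(per_run) <- paste0("seed_", seeds)
  list(mean = colMeans(per_run), per_run = per_run, seeds = seeds)
}

#' Save / load a checkpoint
#'
#' Checkpoints are runtime artifacts serialised with `saveRDS()`.
#'
#' @param checkpoint A `dti_checkpoint`.
#' @param path File path (conventionally `.rds`).
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "dti_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("cannot read checkpoint: no such file: ", path)
  ck <- readRDS(path)
  if (!inherits(ck, "dti_checkpoint")) stop("not a dti_checkpoint: ", path)
  ck
}
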
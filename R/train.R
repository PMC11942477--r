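# AdamW optimizer and task training loops.

adamw_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.05,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       clip_norm = 1) {
  # eps acts as a floor on the denominator: raising it turns coordinates
  # with vanishing gradients into proportionally small steps instead of
  # full +/- lr drift, which matters at these small widths
  if (is.finite(clip_norm) && clip_norm > 0) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gnorm > clip_norm)
      grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m; state$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    # decoupled weight decay on weight matrices, not biases / gains
    if (is.matrix(params[[nm]])) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

featurize_for_model <- function(model, seqs, rules, normalize = TRUE) {
  stacks <- featurize_sequences(seqs, L = model$cfg$L, rules = rules,
                                normalize = normalize)
  patch_input(stacks, model$cfg$patch_size)
}

log_line <- function(path, rec) {
  if (is.null(path)) return(invisible())
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
}

#' Train the classification model
#'
#' Mini-batch AdamW training of the full dual-modality classifier (sequence
#' encoder, vision encoder, fusion blocks, classification head) on labeled
#' sequences, with a held-out validation split, per-epoch accuracy logging
#' and optional early stopping once a target validation accuracy is
#' reached.  All randomness (split, shuffling, dropout) is governed by
#' `seed`.
#'
#' @param model A [duet_model()] with task `"classify"`.
#' @param data Data frame with columns `seq` and `label`.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param lr_decay Multiplicative per-epoch learning-rate decay factor.
#' @param warmup_steps Linear learning-rate warm-up over this many
#'   optimizer steps.
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param val_fraction Held-out fraction for validation.
#' @param seed Integer seed.
#' @param stop_acc Early-stopping validation accuracy (NULL = never).
#' @param clip_norm Global gradient-norm clip (Inf disables).
#' @param adam_eps Adam denominator floor; larger values damp the drift
#'   of near-zero-gradient coordinates.
#' @param rules [pair_rules()] used for featurization.
#' @param log_path Optional path for line-delimited JSON epoch logs.
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` (including `label_levels`) and a
#'   `history` data frame (epoch, train_loss, val_acc).
#' @export
train_classifier <- function(model, data, epochs = 20L, batch_size = 16L,
                             lr = 1e-3, weight_decay = 0.05,
                             lr_decay = 1, warmup_steps = 50L,
                             val_fraction = 0.2, seed = 1L,
                             stop_acc = NULL, clip_norm = 1, adam_eps = 1e-8,
                             rules = pair_rules(), log_path = NULL,
                             verbose = FALSE) {
  stopifnot(model$task == "classify", all(c("seq", "label") %in% names(data)))
  levels <- sort(unique(data$label))
  if (length(levels) != model$n_classes)
    stop("data has ", length(levels), " classes but the model head has ",
         model$n_classes)
  y <- match(data$label, levels)
  model$label_levels <- levels
  ids_all <- prepare_ids(model, data$seq)
  n <- nrow(data)
  # featurization is input-independent of the parameters, so the patch
  # inputs are computed once and sliced per batch (falling back to
  # per-batch computation when the cache would be too large)
  rows <- as.integer((model$cfg$L / model$cfg$patch_size)^2)
  cache_ok <- n * rows * 24 * model$cfg$patch_size^2 <= 4e7
  X0_all <- if (cache_ok) featurize_for_model(model, data$seq, rules)
  get_X0 <- function(idx) {
    if (cache_ok)
      X0_all[rep((idx - 1L) * rows, each = rows) + seq_len(rows), , drop = FALSE]
    else featurize_for_model(model, data$seq[idx], rules)
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc = numeric(0))
  with_seed(seed, {
    perm <- sample.int(n)
    n_val <- max(1L, round(n * val_fraction))
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    state <- adamw_new()
    step <- 0L
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * lr_decay^(ep - 1)
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        tape <- new_tape(model)
        Tn <- fwd_sequence(model, tape, ids_all[bi, , drop = FALSE],
                           training = TRUE)
        Vn <- fwd_vision(model, tape, get_X0(bi), length(bi),
                         training = TRUE)$vl
        fu <- fwd_fusion(model, tape, Tn, Vn, length(bi), training = TRUE)
        logits <- fwd_classify(model, tape, fu$T, fu$V, length(bi))
        loss <- ad_ce_logits(logits, y[bi])
        ad_backward(loss)
        step <- step + 1L
        lr_t <- if (step <= warmup_steps) lr_ep * step / warmup_steps else lr_ep
        model$params <- adamw_step(model$params, collect_grads(tape), state,
                                   lr_t, weight_decay, eps = adam_eps,
                                   clip_norm = clip_norm)
        losses <- c(losses, loss$value)
      }
      val_p <- matrix(0, length(val_idx), model$n_classes)
      for (v0 in seq(1L, length(val_idx), by = 32L)) {
        vi <- val_idx[v0:min(v0 + 31L, length(val_idx))]
        tape <- new_tape(model)
        Tn <- fwd_sequence(model, tape, ids_all[vi, , drop = FALSE])
        Vn <- fwd_vision(model, tape, get_X0(vi), length(vi))$vl
        fu <- fwd_fusion(model, tape, Tn, Vn, length(vi))
        z <- fwd_classify(model, tape, fu$T, fu$V, length(vi))$value
        pz <- exp(z - apply(z, 1L, max))
        val_p[v0:(v0 + length(vi) - 1L), ] <- pz / rowSums(pz)
      }
      val_acc <- mean(max.col(val_p) == y[val_idx])
      history[nrow(history) + 1L, ] <- list(ep, mean(losses), val_acc)
      log_line(log_path, list(epoch = ep, train_loss = mean(losses),
                              val_acc = val_acc, seed = seed))
      if (verbose) message(sprintf("epoch %d  loss %.4f  val_acc %.3f",
                                   ep, mean(losses), val_acc))
      gc(FALSE)
      if (!is.null(stop_acc) && val_acc >= stop_acc) break
    }
  })
  list(model = model, history = history)
}

predict_classifier_ids <- function(model, ids, seqs, rules,
                                   batch_size = 32L) {
  n <- nrow(ids)
  out <- matrix(0, n, model$n_classes)
  for (b0 in seq(1L, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, n)
    tape <- new_tape(model)
    X0 <- featurize_for_model(model, seqs[bi], rules)
    Tn <- fwd_sequence(model, tape, ids[bi, , drop = FALSE])
    Vn <- fwd_vision(model, tape, X0, length(bi))$vl
    fu <- fwd_fusion(model, tape, Tn, Vn, length(bi))
    z <- fwd_classify(model, tape, fu$T, fu$V, length(bi))$value
    p <- exp(z - apply(z, 1L, max))
    out[bi, ] <- p / rowSums(p)
  }
  colnames(out) <- model$label_levels
  out
}

#' Predict class probabilities
#'
#' @param model A trained classification [duet_model()].
#' @param seqs Character vector of sequences.
#' @param rules [pair_rules()] used for featurization.
#' @return `n x n_classes` probability matrix (columns named by label).
#' @export
predict_classifier <- function(model, seqs, rules = pair_rules()) {
  predict_classifier_ids(model, prepare_ids(model, seqs), seqs, rules)
}

#' Train the secondary-structure model
#'
#' Mini-batch AdamW training of the U-Net structure head on
#' (sequence, pair-matrix) records, with binary cross-entropy on the
#' contact logits.  Because true pairs are a sparse minority of the L^2
#' cells, positives are up-weighted by the batch negative:positive ratio
#' by default.
#'
#' @param model A [duet_model()] with task `"rss"`.
#' @param data List of records, each with `seq` and `pairs` (L x L matrix).
#' @param pos_weight Positive-class weight; `"auto"` uses the batch
#'   negative:positive count ratio.
#' @inheritParams train_classifier
#' @return List with the trained `model` and a `history` data frame
#'   (epoch, train_loss, val_f1).
#' @export
train_rss <- function(model, data, epochs = 10L, batch_size = 4L, lr = 1e-3,
                      weight_decay = 0.05, val_fraction = 0.2, seed = 1L,
                      pos_weight = "auto", clip_norm = 1, adam_eps = 1e-8,
                      rules = pair_rules(), log_path = NULL,
                      verbose = FALSE) {
  stopifnot(model$task == "rss")
  n <- length(data)
  seqs <- vapply(data, function(d) unclass(as_rna_sequence(d$seq)), character(1))
  ids_all <- prepare_ids(model, seqs)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_f1 = numeric(0))
  with_seed(seed, {
    perm <- sample.int(n)
    n_val <- max(1L, round(n * val_fraction))
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    state <- adamw_new()
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        tape <- new_tape(model)
        X0 <- featurize_for_model(model, seqs[bi], rules)
        logits <- fwd_rss(model, tape, X0, ids_all[bi, , drop = FALSE],
                          length(bi), training = TRUE)
        tgt <- unlist(lapply(bi, function(i) as.vector(t(data[[i]]$pairs))))
        pw <- if (identical(pos_weight, "auto")) {
          np <- sum(tgt)
          if (np > 0) (length(tgt) - np) / np else 1
        } else pos_weight
        loss <- ad_bce_logits(logits, tgt, pw)
        ad_backward(loss)
        model$params <- adamw_step(model$params, collect_grads(tape), state,
                                   lr, weight_decay, eps = adam_eps,
                                   clip_norm = clip_norm)
        losses <- c(losses, loss$value)
      }
      f1s <- vapply(val_idx, function(i) {
        pm <- predict_rss_ids(model, ids_all[i, , drop = FALSE], seqs[i], rules)
        unname(ppv_sen_f1(pair_confusion(pm, data[[i]]$pairs))["F1"])
      }, numeric(1))
      history[nrow(history) + 1L, ] <- list(ep, mean(losses), mean(f1s))
      log_line(log_path, list(epoch = ep, train_loss = mean(losses),
                              val_f1 = mean(f1s), seed = seed))
      if (verbose) message(sprintf("epoch %d  loss %.4f  val_f1 %.3f",
                                   ep, mean(losses), mean(f1s)))
    }
  })
  list(model = model, history = history)
}

predict_rss_ids <- function(model, ids, seq, rules) {
  tape <- new_tape(model)
  X0 <- featurize_for_model(model, seq, rules)
  logits <- fwd_rss(model, tape, X0, ids, 1L)
  pm <- matrix(as.vector(logits$value), model$cfg$L, model$cfg$L, byrow = TRUE)
  pm <- 1 / (1 + exp(-pm))
  (pm + t(pm)) / 2
}

#' Predict a pair-probability matrix
#'
#' Featurizes the sequence, runs the structure head and returns the
#' symmetrized sigmoid probability map.
#'
#' @param model A trained structure [duet_model()].
#' @param seq A sequence.
#' @param rules [pair_rules()] used for featurization.
#' @return Symmetric L x L probability matrix.
#' @export
predict_rss <- function(model, seq, rules = pair_rules()) {
  predict_rss_ids(model, prepare_ids(model, seq),
                  unclass(as_rna_sequence(seq)), rules)
}

#' Save / load a model
#'
#' Models are plain R lists of numeric arrays and serialize with `saveRDS`;
#' the index cache is dropped on save and rebuilt lazily.
#'
#' @param model A [duet_model()].
#' @param path File path.
#' @export
save_model <- function(model, path) {
  model$cache <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  model$cache <- new.env(parent = emptyenv())
  model
}
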
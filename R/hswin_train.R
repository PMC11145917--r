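# Training loop for the hybrid 3D Swin transformer: voxel cross-entropy plus
# soft-Dice loss (equal weights), AdamW, deterministic under a fixed seed on
# a single thread. Patches with an all-background mask fall back to the
# cross-entropy term alone (the Dice term is undefined on empty masks).

DICE_EPS <- 1e-6
POS_WEIGHT_CAP <- 50

# foreground class weight balancing the extreme voxel imbalance of sparse
# spot masks; "auto" uses the batch background/foreground ratio, capped
resolve_pos_weight <- function(pos_weight, y) {
  if (!identical(pos_weight, "auto")) return(pos_weight)
  n_pos <- sum(y == 1)
  if (n_pos == 0) return(1)
  min(POS_WEIGHT_CAP, max(1, (length(y) - n_pos) / n_pos))
}

seg_loss <- function(logits, y, B, nvox, pos_weight = "auto") {
  n <- nrow(logits)
  pw <- resolve_pos_weight(pos_weight, y)
  w <- ifelse(y == 1, pw, 1)
  w <- w / sum(w)
  probs <- softmax_rows(logits)
  ce <- -sum(w * log(probs[cbind(seq_len(n), y + 1L)] + 1e-12))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  dlog <- (probs - onehot) * w
  # per-patch soft Dice on the foreground probability
  dprob_fg <- numeric(n)
  dice_terms <- numeric(0)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * nvox + seq_len(nvox)
    g <- y[rows]
    if (sum(g) == 0) next
    pf <- probs[rows, 2]
    I <- sum(pf * g)
    den <- sum(pf) + sum(g) + DICE_EPS
    D <- 2 * I / den
    dice_terms <- c(dice_terms, 1 - D)
    # d(1-D)/dpf = -(2 g / den - 2 I / den^2)
    dprob_fg[rows] <- -(2 * g / den - 2 * I / den^2)
  }
  loss_dice <- 0
  if (length(dice_terms) > 0) {
    loss_dice <- mean(dice_terms)
    dprob_fg <- dprob_fg / length(dice_terms)
    # back through softmax: dlogit = p * (dprob - rowSums(dprob * p))
    dprob <- cbind(0, dprob_fg)
    s <- rowSums(dprob * probs)
    dlog <- dlog + probs * (dprob - s)
  }
  list(loss = ce + loss_dice, ce = ce, dice_loss = loss_dice, dlogits = dlog)
}

micro_dice <- function(model, pairs, batch_size) {
  tp <- fp <- fn <- 0
  i <- 1L
  while (i <= length(pairs)) {
    idx <- seq.int(i, min(i + batch_size - 1L, length(pairs)))
    xs <- lapply(pairs[idx], function(p) p$image_norm)
    logits <- fast_forward(model, xs)
    nvox <- prod(dim(xs[[1]]))
    for (k in seq_along(idx)) {
      rows <- (k - 1L) * nvox + seq_len(nvox)
      pred <- (logits[rows, 2] > logits[rows, 1]) * 1
      g <- as.vector(pairs[[idx[k]]]$mask)
      tp <- tp + sum(pred == 1 & g == 1)
      fp <- fp + sum(pred == 1 & g == 0)
      fn <- fn + sum(pred == 0 & g == 1)
    }
    i <- i + batch_size
  }
  if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

#' Train the segmentation network
#'
#' Splits the patch pairs into disjoint train/validation sets by patch id
#' (seeded), min-max normalizes every image patch, and optimizes voxel
#' cross-entropy + soft Dice with AdamW. Validation Dice (micro-averaged
#' over voxels, argmax segmentation) is computed every epoch and the best
#' checkpointed weights are restored at the end.
#'
#' @param model an [build_model()] network (mutated in place).
#' @param pairs training pairs from [build_training_set()] (`$pairs`), each
#'   with `image` and `mask` arrays of equal shape.
#' @param epochs,lr,batch_size,weight_decay optimizer settings.
#' @param val_frac held-out fraction (at least one patch).
#' @param seed seed controlling the split, shuffling and any dropout.
#' @param verbose print per-epoch progress to stderr.
#' @return a `train_report`: `history` data frame (epoch, loss, ce,
#'   dice_loss, val_dice), `best_epoch`, `best_val_dice`, `n_train`,
#'   `n_val`, `seed` and the hyperparameter echo.
#' @export
train_model <- function(model, pairs, epochs = 20L, lr = 1e-4,
                        batch_size = 8L, val_frac = 0.2, seed = 1L,
                        weight_decay = 0.01, verbose = FALSE) {
  stopifnot(length(pairs) >= 2)
  if (any(vapply(pairs, function(p) sum(p$mask) == 0, logical(1))))
    warning("training set contains all-background masks; Dice term skipped for those patches")
  for (i in seq_along(pairs)) pairs[[i]]$image_norm <- minmax_norm(pairs[[i]]$image)
  nvox <- prod(dim(pairs[[1]]$image))
  report_env <- new.env()
  with_seed(seed, {
    n <- length(pairs)
    n_val <- max(1L, as.integer(round(val_frac * n)))
    val_idx <- sort(sample.int(n, n_val))
    train_idx <- setdiff(seq_len(n), val_idx)
    stopifnot(length(train_idx) >= 1)
    opt <- adamw_init(model$params)
    hist <- data.frame(epoch = integer(0), loss = numeric(0), ce = numeric(0),
                       dice_loss = numeric(0), val_dice = numeric(0))
    best <- list(dice = -Inf, params = model$params, epoch = 0L)
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      ep_loss <- ep_ce <- ep_dl <- 0
      n_batches <- 0L
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[seq.int(i, min(i + batch_size - 1L, length(ord)))]
        xs <- lapply(pairs[idx], function(p) p$image_norm)
        y <- unlist(lapply(pairs[idx], function(p) as.vector(p$mask)),
                    use.names = FALSE)
        if (model$cfg$dropout == 0) {
          # single-precision fused pass (reference double path used when
          # dropout is active, which the fast core does not implement)
          ls <- fast_step(model, xs, y)
          grads <- ls$grads
        } else {
          fw <- hswin_forward(model, xs, train = TRUE)
          ls <- seg_loss(fw$logits, y, length(idx), nvox)
          grads <- hswin_backward(model, ls$dlogits, fw$cache)
        }
        st <- adamw_step(model$params, grads, opt, lr, weight_decay)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + ls$loss
        ep_ce <- ep_ce + ls$ce
        ep_dl <- ep_dl + ls$dice_loss
        n_batches <- n_batches + 1L
        i <- i + batch_size
      }
      vd <- micro_dice(model, pairs[val_idx], batch_size)
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = ep_loss / n_batches, ce = ep_ce / n_batches,
        dice_loss = ep_dl / n_batches, val_dice = vd))
      if (vd > best$dice) best <- list(dice = vd, params = model$params,
                                       epoch = ep)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f, val Dice %.4f",
                        ep, epochs, ep_loss / n_batches, vd))
    }
    model$params <- best$params
    report_env$report <- structure(list(
      history = hist, best_epoch = best$epoch, best_val_dice = best$dice,
      n_train = length(train_idx), n_val = n_val, seed = seed,
      hyper = list(epochs = epochs, lr = lr, batch_size = batch_size,
                   weight_decay = weight_decay, val_frac = val_frac)),
      class = "train_report")
  })
  report_env$report
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epochs (%d train / %d val patches): best val Dice %.4f at epoch %d\n",
              nrow(x$history), x$n_train, x$n_val, x$best_val_dice, x$best_epoch))
  invisible(x)
}

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' The checkpoint records the weights plus the full configuration and seed
#' for provenance; loading rebuilds the model and restores the weights, so
#' forward outputs are bitwise identical across a save/load round trip.
#'
#' @param model an `hswin3d` model.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = CHECKPOINT_VERSION, cfg = model$cfg,
               params = model$params, seed = model$cfg$seed), path)
  invisible(path)
}

#' @param expected_cfg optionally, an [hswin3d_config()] the checkpoint must
#'   match (architecture fields compared; mismatches are an explicit error).
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expected_cfg = NULL) {
  if (!file.exists(path)) stop("model checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!is.null(expected_cfg)) {
    for (f in c("embed_dim", "token_patch", "window", "depths", "heads",
                "num_classes", "in_channels", "hybrid", "fused_channels",
                "conv_channels", "dilation_rates"))
      if (!identical(unname(unlist(ck$cfg[[f]])), unname(unlist(expected_cfg[[f]]))))
        stop("checkpoint config mismatch on '", f, "'")
  }
  model <- build_model(ck$cfg)
  model$params <- ck$params
  model
}
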
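# Training schedule, Adam optimizer, and the six evaluation metrics.

#' Training configuration
#'
#' Default values follow the reference schedule: 100 epochs, batch size
#' 32, Adam with base learning rate 0.001 and weight decay 1e-5, linear
#' warm-up from 10% of the base rate over the first 10 epochs, and a
#' reduce-on-plateau rule multiplying the rate by 0.7 after 5 consecutive
#' epochs without validation improvement. Dropout 0.2 on the head.
#'
#' @param epochs,batch_size,base_lr,weight_decay,warmup_epochs,
#'   warmup_start_fraction,plateau_factor,plateau_patience,dropout,seed
#'   schedule settings.
#' @param stop_at_train_acc optional early-stop threshold on training
#'   accuracy (NULL disables).
#' @return list of settings.
#' @export
trainConfig <- function(epochs = 100L, batch_size = 32L, base_lr = 1e-3,
                        weight_decay = 1e-5, warmup_epochs = 10L,
                        warmup_start_fraction = 0.1, plateau_factor = 0.7,
                        plateau_patience = 5L, dropout = 0.2, seed = 1L,
                        stop_at_train_acc = NULL) {
  stopifnot(epochs > 0, batch_size > 0, base_lr > 0,
            warmup_start_fraction > 0, warmup_start_fraction <= 1)
  list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    base_lr = base_lr, weight_decay = weight_decay,
    warmup_epochs = as.integer(warmup_epochs),
    warmup_start_fraction = warmup_start_fraction,
    plateau_factor = plateau_factor,
    plateau_patience = as.integer(plateau_patience),
    dropout = dropout, seed = as.integer(seed),
    stop_at_train_acc = stop_at_train_acc
  )
}

#' Warm-up learning rate at an epoch
#'
#' Linear ramp from \code{warmup_start_fraction * base_lr} at epoch 0 to
#' \code{base_lr} at epoch \code{warmup_epochs}; constant afterwards
#' (plateau decays are applied on top, see [plateauStep()]).
#'
#' @param epoch zero-based epoch index.
#' @param cfg configuration from [trainConfig()].
#' @return learning rate.
#' @export
lrAtEpoch <- function(epoch, cfg) {
  w <- cfg$warmup_epochs
  s <- cfg$warmup_start_fraction
  if (epoch >= w) return(cfg$base_lr)
  cfg$base_lr * (s + (1 - s) * epoch / w)
}

#' Reduce-on-plateau decay over a validation history
#'
#' Scans the validation-loss history in order; after
#' \code{plateau_patience} consecutive epochs with no improvement over the
#' best loss seen, the learning rate is multiplied by
#' \code{plateau_factor} and the patience counter resets (it also resets
#' on every improvement).
#'
#' @param history numeric vector of per-epoch validation losses.
#' @param lr learning rate before applying the rule.
#' @param cfg configuration from [trainConfig()].
#' @return decayed learning rate.
#' @export
plateauStep <- function(history, lr, cfg = trainConfig()) {
  best <- Inf
  bad <- 0L
  decays <- 0L
  for (loss in history) {
    if (loss < best) {
      best <- loss
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$plateau_patience) {
        decays <- decays + 1L
        bad <- 0L
      }
    }
  }
  lr * cfg$plateau_factor^decays
}

.adamInit <- function(P, names) {
  list(
    m = stats::setNames(lapply(names, function(nm) P[[nm]] * 0), names),
    v = stats::setNames(lapply(names, function(nm) P[[nm]] * 0), names),
    t = 0L
  )
}

.adamUpdate <- function(P, grads, state, lr, weightDecay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weightDecay * P[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(P = P, state = state)
}

#' Train the inhibitor classifier
#'
#' Mini-batch Adam training of the full model against one fixed protein
#' graph. Shuffling, dropout and initialization all derive from the
#' configured seed, so two runs with the same inputs and seed produce
#' bit-identical logs. The checkpoint with the best validation loss is
#' retained.
#'
#' @param ligandsTrain,ligandsVal lists of [MolecularGraph-class] objects.
#' @param labelsTrain,labelsVal 0/1 numeric labels.
#' @param protein a [ProteinGraph-class].
#' @param cfg configuration from [trainConfig()].
#' @param stats atom-feature normalization statistics of the training
#'   corpus (stored in the returned model).
#' @param params optional pre-initialized parameter list; by default
#'   initialized from \code{cfg$seed}.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (an [InhibitorClassifier-class], best
#'   validation checkpoint), \code{log} (per-epoch data.frame: epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc) and \code{final_params}.
#' @export
trainModel <- function(ligandsTrain, labelsTrain, ligandsVal, labelsVal,
                       protein, cfg = trainConfig(), stats = list(),
                       params = NULL, verbose = FALSE) {
  if (!length(ligandsTrain)) stop("empty training split")
  set.seed(cfg$seed)
  P <- if (is.null(params)) initModelParams(cfg$seed) else params
  learnable <- .learnableNames(P)
  opt <- .adamInit(P, learnable)
  Xp <- nodeFeatures(protein)
  edgesP <- protein@edges
  n <- length(ligandsTrain)
  aggTrain <- lapply(ligandsTrain, function(g) {
    .ligandAggregators(g@edges, atomCount(g))
  })
  aggVal <- lapply(ligandsVal, function(g) {
    .ligandAggregators(g@edges, atomCount(g))
  })
  bestVal <- Inf
  bestP <- P
  valHistory <- numeric(0)
  bad <- 0L
  decays <- 0L
  logRows <- list()
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lrAtEpoch(epoch, cfg) * cfg$plateau_factor^decays
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epochLoss <- 0
    trainProbs <- numeric(n)
    for (b in batches) {
      st <- .trainStep(ligandsTrain[b], labelsTrain[b], Xp, edgesP, P,
                       dropoutRate = cfg$dropout, aggregators = aggTrain[b])
      upd <- .adamUpdate(P, st$grads, opt, lr, cfg$weight_decay)
      P <- upd$P
      opt <- upd$state
      P$head.bn_rmean <- st$bn_rmean
      P$head.bn_rvar <- st$bn_rvar
      epochLoss <- epochLoss + st$loss * length(b)
      trainProbs[b] <- st$probs
    }
    epochLoss <- epochLoss / n
    trainAcc <- mean((trainProbs >= 0.5) == (labelsTrain == 1))
    if (length(ligandsVal)) {
      protFwd <- .proteinFwd(Xp, edgesP, P)
      valProbs <- .scoreBatch(ligandsVal, protFwd, P, aggregators = aggVal)
      valLoss <- bceLoss(valProbs, labelsVal)
      valAcc <- mean((valProbs >= 0.5) == (labelsVal == 1))
    } else {
      valLoss <- epochLoss
      valAcc <- trainAcc
    }
    valHistory <- c(valHistory, valLoss)
    if (valLoss < bestVal) {
      bestVal <- valLoss
      bestP <- P
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$plateau_patience) {
        decays <- decays + 1L
        bad <- 0L
      }
    }
    logRows[[length(logRows) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = epochLoss, train_acc = trainAcc,
      val_loss = valLoss, val_acc = valAcc
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
        epoch, lr, epochLoss, trainAcc, valLoss, valAcc
      ))
    }
    if (!is.null(cfg$stop_at_train_acc) &&
        trainAcc >= cfg$stop_at_train_acc) break
  }
  model <- new("InhibitorClassifier",
    params = bestP, normStats = stats, config = cfg
  )
  list(model = model, log = do.call(rbind, logRows), final_params = P)
}

#' Confusion counts at a threshold
#'
#' @param labels 0/1 labels.
#' @param probs predicted probabilities.
#' @param threshold decision threshold (predicted positive iff prob >=
#'   threshold; default 0.5).
#' @return list with tp, tn, fp, fn.
#' @export
confusionCounts <- function(labels, probs, threshold = 0.5) {
  pred <- probs >= threshold
  pos <- labels == 1
  list(
    tp = sum(pred & pos), tn = sum(!pred & !pos),
    fp = sum(pred & !pos), fn = sum(!pred & pos)
  )
}

#' The six classification metrics
#'
#' Accuracy, precision, recall, F1, Matthews correlation coefficient and
#' ROC AUC. Precision, recall and MCC return 0 on a zero denominator; AUC
#' uses the rank statistic (equivalent to the probability that a positive
#' outranks a negative, ties counted half) and returns 0.5 when either
#' class is absent.
#'
#' @param counts confusion counts from [confusionCounts()].
#' @param labels 0/1 labels (for AUC).
#' @param probs predicted probabilities (for AUC).
#' @return list with accuracy, precision, recall, f1, mcc, auc.
#' @export
classificationMetrics <- function(counts, labels, probs) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  accuracy <- if (total > 0) (tp + tn) / total else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  pos <- labels == 1
  npos <- sum(pos)
  nneg <- sum(!pos)
  auc <- if (npos > 0 && nneg > 0) {
    r <- rank(probs)
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  } else 0.5
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, mcc = mcc, auc = auc)
}
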
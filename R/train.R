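# Training: binary cross-entropy on the sigmoid output, Adam with L2
# weight decay. Gradients are accumulated sample by sample (sequences have
# unequal lengths, so there is no tensor batching; a "batch" is a gradient
# accumulation window).

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(P, G, A, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- if (exists(".t", envir = A, inherits = FALSE)) get(".t", envir = A) else 0L
  t <- t + 1L
  assign(".t", t, envir = A)
  for (nm in ls(G)) {
    g <- get(nm, envir = G)
    th <- p_get(P, nm)
    if (wd > 0) g <- g + wd * th
    mk <- paste0(nm, ".m"); vk <- paste0(nm, ".v")
    m <- if (exists(mk, envir = A, inherits = FALSE)) get(mk, envir = A) else g * 0
    v <- if (exists(vk, envir = A, inherits = FALSE)) get(vk, envir = A) else g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    assign(mk, m, envir = A); assign(vk, v, envir = A)
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    p_set(P, nm, th - lr * mh / (sqrt(vh) + eps))
  }
  invisible(NULL)
}

bce_loss <- function(prob, y, eps = 1e-12) {
  -(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Train an ASYM model
#'
#' @param model An [asym_model()]; updated in place (parameters live in an
#'   environment) and also returned.
#' @param samples List of samples, each a list with elements `audio`
#'   (`T x F_a` matrix or `NULL`), `video`, and `label` (0/1).
#' @param epochs,lr,weight_decay,batch_size Optimization protocol;
#'   defaults come from the model's configuration (Adam, the profile's
#'   learning rate, L2 weight decay).
#' @param val_samples Optional held-out list evaluated after each epoch.
#' @param early_stop_acc Optional validation-accuracy threshold: training
#'   stops early (within the epoch budget) once the held-out accuracy
#'   reaches it.
#' @param early_stop_min_epochs Earliest epoch at which the early stop may
#'   trigger (small validation sets saturate noisily).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return The model, with a `history` data frame attached
#'   (`model$history` via attribute).
#' @export
asym_train <- function(model, samples, epochs = NULL, lr = NULL,
                       weight_decay = NULL, batch_size = NULL,
                       val_samples = NULL, early_stop_acc = NULL,
                       early_stop_min_epochs = 1L, seed = 1L,
                       verbose = FALSE) {
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(lr)) lr <- cfg$lr
  if (is.null(weight_decay)) weight_decay <- cfg$weight_decay
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  A <- adam_state()
  set.seed(seed)
  n <- length(samples)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + batch_size - 1L, n)]
      G <- new.env(parent = emptyenv())
      for (j in idx) {
        s <- samples[[j]]
        fw <- asym_forward_cache(model, s$audio, s$video, training = TRUE)
        ep_loss <- ep_loss + bce_loss(fw$prob, s$label)
        dlogit <- (fw$prob - s$label) / length(idx)
        asym_backward(model, fw$cache, dlogit, G)
      }
      adam_step(model$P, G, A, lr, weight_decay)
      i <- i + batch_size
    }
    va <- NA_real_
    if (!is.null(val_samples)) {
      pr <- asym_predict_many(model, val_samples)
      va <- mean(pr$label == vapply(val_samples, `[[`, numeric(1L), "label"))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n, val_acc = va))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f%s", ep, ep_loss / n,
                      if (is.na(va)) "" else sprintf("  val_acc %.3f", va)))
    }
    if (!is.null(early_stop_acc) && !is.na(va) && va >= early_stop_acc &&
        ep >= early_stop_min_epochs) break
  }
  model$history <- hist
  model
}

#' Predict on a list of samples
#' @param model An `asym_model`.
#' @param samples List of samples (as in [asym_train()]).
#' @return Data frame with columns `prob`, `label`.
#' @export
asym_predict_many <- function(model, samples) {
  probs <- vapply(samples, function(s) {
    asym_predict(model, s$audio, s$video)$prob
  }, numeric(1L))
  data.frame(prob = probs, label = as.integer(probs >= 0.5))
}
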
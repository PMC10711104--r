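# Training loop: Adam on the composite Dice + boundary loss, gradient
# accumulation over mini-batches, per-epoch train/val bookkeeping.

#' Train a segmentation model
#'
#' One epoch is a full traversal of the training set.  Gradients are
#' accumulated over `batch_size` samples before each Adam step (learning
#' rate `lr`, default 1e-3).  Ground-truth signed distance maps for the
#' boundary term are computed once per mask and cached for all epochs.
#'
#' @param model An `acunet_model` from [build_acunet()].
#' @param dataset List of `list(image=, mask=)` samples; masks are integer
#'   matrices valued in `0..C-1` with the spatial size of the images.
#' @param epochs Number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size Samples per optimiser step.
#' @param loss `"dice"`, `"boundary"` or `"dice_boundary"`.
#' @param boundary_weight Weight of the boundary term in the composite.
#' @param seed Integer seed controlling epoch shuffling; the caller's RNG
#'   state is restored on exit.
#' @param val Optional validation sample list; per-epoch val loss recorded.
#' @param verbose Print one structured line per epoch
#'   (`epoch <e> train_loss <x> [val_loss <y>]`).
#' @param beta2 Adam second-moment decay.  The default 0.999 remembers
#'   ~1000 steps; in short runs a rare-class channel that saturates early
#'   keeps an inflated second moment and cannot recover, so desk-scale
#'   runs benefit from 0.99.
#' @param lr_schedule `"constant"` keeps `lr` throughout; `"cosine"`
#'   anneals it to zero over the run (`lr` is the initial rate).  Cosine
#'   decay tames the late-phase noise of small-batch Adam steps.
#' @param lsuv Run the variance-scaling initialisation ([lsuv_init()]) on
#'   the first training image before the first step (default `TRUE`);
#'   plain VGG-style stacks are strongly init-seed sensitive without it.
#' @param prior_bias Initialise the head bias to the log class priors of
#'   the training masks before the first step (default `FALSE`).  With the
#'   severe background/foreground imbalance of plant scenes, a zero-bias
#'   start makes "predict background everywhere" the steepest early
#'   descent direction for every supported loss; once the softmax
#'   saturates there, gradients die.  Starting at the priors removes that
#'   direction at initialisation (the standard remedy for foreground
#'   collapse in class-imbalanced dense prediction).
#' @return The model, invisibly; training history in `model$history`
#'   (data frame with one row per epoch).
#' @export
train <- function(model, dataset, epochs = 10L, lr = 1e-3,
                  batch_size = 4L, loss = c("dice_boundary", "dice",
                                            "boundary"),
                  boundary_weight = 1, seed = 1L, val = NULL,
                  verbose = FALSE, lsuv = TRUE, prior_bias = FALSE,
                  lr_schedule = c("constant", "cosine"), beta2 = 0.999) {
  lr_schedule <- match.arg(lr_schedule)
  loss <- match.arg(loss)
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  C <- model$config$num_classes
  for (s in dataset) {
    if (!identical(dim(s$image)[1:2], dim(s$mask)))
      stop("image/mask shape mismatch", call. = FALSE)
    if (any(!s$mask %in% 0:(C - 1L)))
      stop("mask values outside 0..C-1", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  if (lsuv) lsuv_init(model, dataset[[1]]$image)
  if (prior_bias && !is.null(model$head$b)) {
    counts <- numeric(C)
    for (s in dataset)
      counts <- counts + tabulate(s$mask + 1L, C)
    model$head$b <- log(counts / sum(counts) + 1e-8)
  }
  # distance maps depend only on the ground truth: compute once, cache
  sdms <- if (loss != "dice")
    lapply(dataset, function(s) boundary_distance_maps(s$mask, C))
  else vector("list", length(dataset))
  model_adam_init(model)
  model_zero_grads(model)
  total_steps <- epochs * ceiling(length(dataset) / batch_size)
  step_no <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample(length(dataset))
    losses <- numeric(length(ord))
    in_batch <- 0L
    for (t in seq_along(ord)) {
      i <- ord[t]
      s <- dataset[[i]]
      probs <- predict_probs(model, s$image, train = TRUE)
      lg <- loss_and_grad(probs, s$mask, loss, boundary_weight,
                          sdm = sdms[[i]])
      losses[t] <- lg$value
      nb <- min(batch_size, length(ord) - (t - in_batch - 1L))
      dlog <- dlogits_from_dprobs(probs, lg$grad / nb)
      backward_logits(model, dlog)
      in_batch <- in_batch + 1L
      if (in_batch == batch_size || t == length(ord)) {
        step_no <- step_no + 1L
        lr_t <- if (lr_schedule == "cosine")
          lr * 0.5 * (1 + cos(pi * (step_no - 1L) / total_steps))
        else lr
        model_adam_step(model, lr_t, beta2 = beta2)
        model_zero_grads(model)
        in_batch <- 0L
      }
    }
    vl <- NA_real_
    if (!is.null(val)) {
      vl <- mean(vapply(val, function(s) {
        probs <- predict_probs(model, s$image)
        loss_and_grad(probs, s$mask, loss, boundary_weight)$value
      }, numeric(1)))
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = mean(losses), val_loss = vl))
    if (verbose)
      cat(sprintf("epoch %d train_loss %.6f%s\n", ep, mean(losses),
                  if (is.na(vl)) "" else sprintf(" val_loss %.6f", vl)))
  }
  model_drop_caches(model)
  model$history <- history
  invisible(model)
}
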
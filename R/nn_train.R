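#' Training hyperparameters
#'
#' The settings shared by all deep models: AdamW (beta1 0.9, beta2
#' 0.999) with weight decay 0.001, initial learning rate 0.001 decayed
#' exponentially by gamma = 0.99 per epoch, 10 epochs of 500 images in
#' batches of 32 with per-batch class balancing, rotation/flip
#' augmentation, and stochastic weight averaging over the last two
#' epochs.
#'
#' @param initial_lr,lr_decay_gamma,adam_beta1,adam_beta2,weight_decay
#'   Optimizer settings.
#' @param epochs,images_per_epoch,batch_size Sampling schedule.
#' @param swa_last_epochs Number of trailing end-of-epoch snapshots
#'   averaged by stochastic weight averaging.
#' @param rotation_limit_deg Max absolute rotation augmentation (deg).
#' @param flip_prob Probability of each of horizontal/vertical flip.
#' @param seed Integer seed controlling initialization order, batch
#'   composition, augmentation draws and dropout.
#' @return Object of class `training_hyperparameters`.
#' @export
training_hyperparameters <- function(initial_lr = 0.001,
                                     lr_decay_gamma = 0.99,
                                     adam_beta1 = 0.9, adam_beta2 = 0.999,
                                     weight_decay = 0.001,
                                     epochs = 10L, images_per_epoch = 500L,
                                     batch_size = 32L, swa_last_epochs = 2L,
                                     rotation_limit_deg = 180,
                                     flip_prob = 0.5, seed = 1L) {
  rates <- c(initial_lr, lr_decay_gamma, adam_beta1, adam_beta2)
  if (any(rates <= 0 | rates > 1)) stop("rates must lie in (0, 1]")
  if (epochs < swa_last_epochs)
    stop("epochs must be >= swa_last_epochs")
  if (batch_size %% 2L != 0L)
    stop("batch_size must be even for two-class balancing")
  structure(list(initial_lr = initial_lr, lr_decay_gamma = lr_decay_gamma,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 images_per_epoch = as.integer(images_per_epoch),
                 batch_size = as.integer(batch_size),
                 swa_last_epochs = as.integer(swa_last_epochs),
                 rotation_limit_deg = rotation_limit_deg,
                 flip_prob = flip_prob, seed = as.integer(seed)),
            class = "training_hyperparameters")
}

#' Learning rate entering an epoch
#' @param hp [training_hyperparameters()].
#' @param epoch 0-indexed epoch number.
#' @return `initial_lr * lr_decay_gamma^epoch`.
#' @export
epoch_learning_rate <- function(hp, epoch) {
  hp$initial_lr * hp$lr_decay_gamma^epoch
}

## ---- augmentation ----------------------------------------------------

#' Rotate an image stack about its center (bilinear, zero fill)
#'
#' @param x Array `H x W x C`.
#' @param angle_deg Rotation angle in degrees.
#' @return Rotated array of the same shape. `angle_deg = 0` is an exact
#'   identity.
#' @export
rotate_bilinear <- function(x, angle_deg) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  a <- angle_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  di <- rep(seq_len(H) - ci, times = W)
  dj <- rep(seq_len(W) - cj, each = H)
  sr <- ci + cos(a) * di - sin(a) * dj
  sc <- cj + sin(a) * di + cos(a) * dj
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  m <- matrix(x, H * W, d[3L])
  out <- matrix(0, H * W, d[3L])
  corner <- function(rr, cc, w) {
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W & w > 0
    if (!any(ok)) return(invisible(NULL))
    idx <- (cc[ok] - 1) * H + rr[ok]
    out[ok, ] <<- out[ok, , drop = FALSE] +
      w[ok] * m[idx, , drop = FALSE]
    invisible(NULL)
  }
  corner(r0,     c0,     (1 - fr) * (1 - fc))
  corner(r0 + 1, c0,     fr * (1 - fc))
  corner(r0,     c0 + 1, (1 - fr) * fc)
  corner(r0 + 1, c0 + 1, fr * fc)
  array(out, d)
}

flip_horizontal <- function(x) x[, dim(x)[2L]:1L, , drop = FALSE]
flip_vertical <- function(x) x[dim(x)[1L]:1L, , , drop = FALSE]

augment_array <- function(data, mask, hp) {
  angle <- stats::runif(1L, -hp$rotation_limit_deg, hp$rotation_limit_deg)
  do_h <- stats::runif(1L) < hp$flip_prob
  do_v <- stats::runif(1L) < hp$flip_prob
  mask3 <- array(mask * 1.0, c(dim(mask), 1L))
  if (angle != 0) {
    data <- rotate_bilinear(data, angle)
    mask3 <- rotate_bilinear(mask3, angle)
  }
  if (do_h) { data <- flip_horizontal(data); mask3 <- flip_horizontal(mask3) }
  if (do_v) { data <- flip_vertical(data); mask3 <- flip_vertical(mask3) }
  mask_out <- mask3[, , 1L] >= 0.5
  data[array(!mask_out, dim = dim(data))] <- 0
  list(data = data, mask = mask_out)
}

#' Randomly rotate and flip a model input
#'
#' Uniform rotation in `[-rotation_limit, +rotation_limit]` degrees about
#' the image center (bilinear, zero fill), then horizontal and vertical
#' flips each with probability `flip_prob`. The mask is transformed with
#' the same geometry (re-thresholded at 0.5 after rotation) and the data
#' re-zeroed outside it. Draws come from R's global random stream.
#'
#' @param input A [model_input_cube()].
#' @param hp [training_hyperparameters()].
#' @return Augmented [model_input_cube()].
#' @export
augment_sample <- function(input, hp = training_hyperparameters()) {
  stopifnot(inherits(input, "model_input_cube"))
  aug <- augment_array(input$data, input$mask, hp)
  out <- model_input_cube(aug$data, aug$mask, input$patient_id,
                          input$sites, input$modality)
  out$wavelengths <- input$wavelengths
  out
}

## ---- balanced batches ------------------------------------------------

make_class_queue <- function(idx) {
  pool <- sample(idx)
  pos <- 0L
  function(k) {
    out <- integer(0)
    while (k > 0L) {
      avail <- length(pool) - pos
      if (avail == 0L) { pool <<- sample(idx); pos <<- 0L; avail <- length(pool) }
      take <- min(k, avail)
      out <- c(out, pool[pos + seq_len(take)])
      pos <<- pos + take
      k <- k - take
    }
    out
  }
}

#' Balanced batch indices for one epoch
#'
#' Yields `images_per_epoch` samples as full batches of `batch_size`
#' plus one remainder batch, each with exactly equal class counts:
#' 500 images in batches of 32 give 15 batches of 16 + 16 and one of
#' 10 + 10. Each class is drawn without replacement from a shuffled
#' queue that reshuffles when exhausted, so the minority class is
#' oversampled (drawn with replacement across the epoch) while majority
#' samples are not repeated until all have been seen.
#'
#' @param labels Integer 0/1 vector over the training samples.
#' @param hp [training_hyperparameters()].
#' @return List of integer index vectors (one per batch).
#' @export
balanced_batch_iterator <- function(labels, hp = training_hyperparameters()) {
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present in the training set")
  qp <- make_class_queue(pos); qn <- make_class_queue(neg)
  n_full <- hp$images_per_epoch %/% hp$batch_size
  rem <- hp$images_per_epoch - n_full * hp$batch_size
  if (rem %% 2L != 0L) stop("remainder batch cannot be class-balanced")
  sizes <- c(rep(hp$batch_size, n_full), if (rem > 0L) rem)
  lapply(sizes, function(b) sample(c(qp(b %/% 2L), qn(b %/% 2L))))
}

## ---- optimizer -------------------------------------------------------

new_adam_state <- function(nodes) {
  lapply(nodes, function(nd) {
    if (nd$type == "resblock") {
      list(main = new_adam_state(nd$main),
           shortcut = if (!is.null(nd$shortcut)) new_adam_state(nd$shortcut))
    } else {
      st <- list()
      for (nm in node_param_names(nd))
        st[[nm]] <- list(m = 0 * nd[[nm]], v = 0 * nd[[nm]])
      st
    }
  })
}

adamw_update <- function(nodes, grads, state, lr, hp, t) {
  b1 <- hp$adam_beta1; b2 <- hp$adam_beta2; eps <- 1e-8
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (nd$type == "resblock") {
      up <- adamw_update(nd$main, g$main, state[[i]]$main, lr, hp, t)
      nodes[[i]]$main <- up$nodes; state[[i]]$main <- up$state
      if (!is.null(nd$shortcut) && !is.null(g$shortcut)) {
        up <- adamw_update(nd$shortcut, g$shortcut, state[[i]]$shortcut,
                           lr, hp, t)
        nodes[[i]]$shortcut <- up$nodes; state[[i]]$shortcut <- up$state
      }
    } else {
      for (nm in names(g)) {
        gr <- g[[nm]]
        st <- state[[i]][[nm]]
        st$m <- b1 * st$m + (1 - b1) * gr
        st$v <- b2 * st$v + (1 - b2) * gr^2
        mhat <- st$m / (1 - b1^t)
        vhat <- st$v / (1 - b2^t)
        p <- nd[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        ## decoupled weight decay on weight matrices only
        if (nm == "W") p <- p - lr * hp$weight_decay * nd[[nm]]
        nodes[[i]][[nm]] <- p
        state[[i]][[nm]] <- st
      }
    }
  }
  list(nodes = nodes, state = state)
}

## ---- training loop ---------------------------------------------------

assemble_batch <- function(data, idx, hp, augment) {
  out <- list()
  if (!is.null(data$images)) {
    d <- dim(data$images)
    xb <- array(0, c(d[1:3], length(idx)))
    for (k in seq_along(idx)) {
      xi <- data$images[, , , idx[k], drop = FALSE]
      dim(xi) <- d[1:3]
      if (augment) {
        mk <- if (!is.null(data$masks)) data$masks[, , idx[k]]
              else matrix(TRUE, d[1L], d[2L])
        xi <- augment_array(xi, mk, hp)$data
      }
      xb[, , , k] <- xi
    }
    out$images <- xb
  }
  if (!is.null(data$clinical))
    out$clinical <- data$clinical[idx, , drop = FALSE]
  out
}

#' Train a deep classifier
#'
#' Minimizes softmax cross-entropy with AdamW under the exponential
#' per-epoch learning-rate schedule, class-balanced oversampled batches
#' and rotation/flip augmentation. After the final epoch the weights are
#' replaced by the arithmetic mean of the end-of-epoch snapshots of the
#' last `swa_last_epochs` epochs (stochastic weight averaging) and the
#' batch-normalization statistics are re-estimated with one pass over
#' the training data. Fully reproducible given `hp$seed`
#' (single-threaded).
#'
#' @param model A model from [build_image_model()] or
#'   [build_fusion_model()].
#' @param data List with `images` (array `H x W x C x N`, optional),
#'   `masks` (array `H x W x N`, optional, used by augmentation) and/or
#'   `clinical` (matrix `N x F`).
#' @param labels Integer 0/1 vector of length N.
#' @param hp [training_hyperparameters()].
#' @param augment Apply augmentation to image batches (default TRUE).
#' @return The trained model; epoch losses in `$train_log`.
#' @export
train_classifier <- function(model, data, labels, hp = training_hyperparameters(),
                             augment = TRUE) {
  stopifnot(inherits(model, "sepsishsi_model"))
  set.seed(hp$seed)
  branches <- model_branches(model)
  for (br in branches) model[[br]] <- set_params(model[[br]],
                                                 collect_params(model[[br]]))
  state <- lapply(stats::setNames(branches, branches),
                  function(br) new_adam_state(model[[br]]))
  t <- 0L
  snapshots <- list()
  losses <- numeric(hp$epochs)
  for (epoch in seq_len(hp$epochs) - 1L) {
    lr <- epoch_learning_rate(hp, epoch)
    batches <- balanced_batch_iterator(labels, hp)
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      batch <- assemble_batch(data, idx, hp, augment)
      fw <- model_forward(model, batch, "train")
      model <- fw$model
      ls <- softmax_xent(fw$logits, labels[idx])
      if (!is.finite(ls$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", batch ", bi)
      ep_loss <- ep_loss + ls$loss * length(idx)
      grads <- model_backward(model, fw$caches, ls$dlogits)
      t <- t + 1L
      for (br in branches) {
        gb <- grads[[grad_branch_name(model, br)]]
        up <- adamw_update(model[[br]], gb, state[[br]], lr, hp, t)
        model[[br]] <- up$nodes
        state[[br]] <- up$state
      }
    }
    losses[epoch + 1L] <- ep_loss / hp$images_per_epoch
    snap <- lapply(stats::setNames(branches, branches),
                   function(br) collect_params(model[[br]]))
    snapshots <- c(snapshots, list(snap))
    if (length(snapshots) > hp$swa_last_epochs)
      snapshots <- snapshots[-1L]
  }
  ## stochastic weight averaging + batch-norm re-estimation
  if (length(snapshots) > 1L) {
    for (br in branches) {
      avg <- average_param_trees(lapply(snapshots, `[[`, br))
      model[[br]] <- set_params(model[[br]], avg)
      model[[br]] <- reset_bn_accumulators(model[[br]])
    }
    n <- length(labels)
    starts <- seq(1L, n, by = hp$batch_size)
    for (s in starts) {
      idx <- s:min(s + hp$batch_size - 1L, n)
      if (length(idx) < 2L) next
      batch <- assemble_batch(data, idx, hp, augment = FALSE)
      fw <- model_forward(model, batch, "bn_est")
      model <- fw$model
    }
    for (br in branches)
      model[[br]] <- finalize_bn_accumulators(model[[br]])
  }
  model$train_log <- losses
  model
}

#' Predict logits and positive-class probabilities
#'
#' @param model A trained deep model or random-forest model.
#' @param data As in [train_classifier()] (deep models) or a feature
#'   matrix (random forest).
#' @param ... Unused.
#' @return List with `logits` (N x 2, absent for random forests where
#'   votes play that role) and `prob` (positive-class probability).
#' @export
predict_scores <- function(model, data, ...) UseMethod("predict_scores")

#' @export
predict_scores.sepsishsi_model <- function(model, data, ...) {
  n <- if (!is.null(data$images)) dim(data$images)[4L]
       else nrow(data$clinical)
  logits <- matrix(NA_real_, n, 2L)
  starts <- seq(1L, n, by = 64L)
  for (s in starts) {
    idx <- s:min(s + 63L, n)
    batch <- assemble_batch(data, idx, training_hyperparameters(),
                            augment = FALSE)
    fw <- model_forward(model, batch, "eval")
    logits[idx, ] <- fw$logits
  }
  e <- exp(logits - apply(logits, 1L, max))
  list(logits = logits, prob = (e / rowSums(e))[, 2L])
}
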
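## Sequential-graph interpreter over the layer set in nn_layers.R, plus
## the model builders: a small residual CNN for image inputs, the
## fully-connected clinical encoder, and the multimodal fusion model.

## ---- interpreter -----------------------------------------------------

run_seq <- function(nodes, x, mode = c("train", "eval", "bn_est")) {
  mode <- match.arg(mode)
  training <- mode != "eval"
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    res <- switch(nd$type,
      conv = conv_forward(nd, x),
      bn2d = {
        m <- bn2d_reshape(x)
        core <- bn_core_forward(nd, m, training)
        if (mode == "train")
          nodes[[i]] <- bn_update_running(nodes[[i]], core$cache$mu,
                                          core$cache$va)
        if (mode == "bn_est")
          nodes[[i]] <- bn_accumulate(nodes[[i]], core$cache$mu,
                                      core$cache$va, core$cache$n)
        list(y = bn2d_unshape(core$y, dim(x)),
             cache = c(core$cache, list(in_dim = dim(x))))
      },
      bn1d = {
        core <- bn_core_forward(nd, x, training)
        if (mode == "train")
          nodes[[i]] <- bn_update_running(nodes[[i]], core$cache$mu,
                                          core$cache$va)
        if (mode == "bn_est")
          nodes[[i]] <- bn_accumulate(nodes[[i]], core$cache$mu,
                                      core$cache$va, core$cache$n)
        core
      },
      relu = relu_forward(x),
      elu = elu_forward(nd, x),
      dropout = dropout_forward(nd, x, mode == "train"),
      maxpool = maxpool_forward(nd, x),
      avgpool2 = avgpool2_forward(x),
      gap = gap_forward(x),
      linear = linear_forward(nd, x),
      resblock = {
        main <- run_seq(nd$main, x, mode)
        nodes[[i]]$main <- main$nodes
        if (is.null(nd$shortcut)) {
          sc_y <- x; sc_cache <- NULL
        } else {
          sc <- run_seq(nd$shortcut, x, mode)
          nodes[[i]]$shortcut <- sc$nodes
          sc_y <- sc$y; sc_cache <- sc$caches
        }
        summ <- main$y + sc_y
        list(y = pmax(summ, 0),
             cache = list(main = main$caches, shortcut = sc_cache,
                          relu_mask = summ > 0))
      },
      stop("unknown node type: ", nd$type))
    x <- res$y
    caches[[i]] <- res$cache
  }
  list(y = x, caches = caches, nodes = nodes)
}

back_seq <- function(nodes, caches, dy) {
  grads <- vector("list", length(nodes))
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]; ch <- caches[[i]]
    switch(nd$type,
      conv = {
        r <- conv_backward(nd, ch, dy); dy <- r$dx; grads[[i]] <- r$grads
      },
      bn2d = {
        r <- bn_core_backward(nd, ch, bn2d_reshape(dy))
        dy <- bn2d_unshape(r$dx, ch$in_dim); grads[[i]] <- r$grads
      },
      bn1d = {
        r <- bn_core_backward(nd, ch, dy); dy <- r$dx; grads[[i]] <- r$grads
      },
      relu = { dy <- relu_backward(ch, dy) },
      elu = { dy <- elu_backward(nd, ch, dy) },
      dropout = { dy <- dropout_backward(nd, ch, dy) },
      maxpool = { dy <- maxpool_backward(nd, ch, dy) },
      avgpool2 = { dy <- avgpool2_backward(ch, dy) },
      gap = { dy <- gap_backward(ch, dy) },
      linear = {
        r <- linear_backward(nd, ch, dy); dy <- r$dx; grads[[i]] <- r$grads
      },
      resblock = {
        dsum <- dy * ch$relu_mask
        main <- back_seq(nd$main, ch$main, dsum)
        g <- list(main = main$grads)
        if (is.null(nd$shortcut)) {
          dy <- main$dx + dsum
        } else {
          sc <- back_seq(nd$shortcut, ch$shortcut, dsum)
          g$shortcut <- sc$grads
          dy <- main$dx + sc$dx
        }
        grads[[i]] <- g
      },
      stop("unknown node type: ", nd$type))
  }
  list(dx = dy, grads = grads)
}

## ---- parameter-tree utilities ---------------------------------------

node_param_names <- function(nd) {
  switch(nd$type,
         conv = "W", linear = c("W", "b"), bn2d = , bn1d = c("gamma", "beta"),
         character(0))
}

collect_params <- function(nodes) {
  lapply(nodes, function(nd) {
    if (nd$type == "resblock") {
      list(main = collect_params(nd$main),
           shortcut = if (!is.null(nd$shortcut)) collect_params(nd$shortcut))
    } else nd[node_param_names(nd)]
  })
}

set_params <- function(nodes, params) {
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "resblock") {
      nodes[[i]]$main <- set_params(nodes[[i]]$main, params[[i]]$main)
      if (!is.null(nodes[[i]]$shortcut))
        nodes[[i]]$shortcut <- set_params(nodes[[i]]$shortcut,
                                          params[[i]]$shortcut)
    } else {
      for (nm in node_param_names(nodes[[i]]))
        nodes[[i]][[nm]] <- params[[i]][[nm]]
    }
  }
  nodes
}

average_param_trees <- function(trees) {
  avg <- function(xs) {
    if (is.list(xs[[1L]])) {
      out <- vector("list", length(xs[[1L]]))
      names(out) <- names(xs[[1L]])
      for (j in seq_along(xs[[1L]])) {
        if (is.null(xs[[1L]][[j]])) next
        out[[j]] <- avg(lapply(xs, `[[`, j))
      }
      out
    } else Reduce(`+`, xs) / length(xs)
  }
  avg(trees)
}

reset_bn_accumulators <- function(nodes) {
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "resblock") {
      nodes[[i]]$main <- reset_bn_accumulators(nodes[[i]]$main)
      if (!is.null(nodes[[i]]$shortcut))
        nodes[[i]]$shortcut <- reset_bn_accumulators(nodes[[i]]$shortcut)
    } else if (nodes[[i]]$type %in% c("bn2d", "bn1d")) {
      nodes[[i]]$acc_n <- NULL
      nodes[[i]]$acc_mean <- NULL
      nodes[[i]]$acc_m2 <- NULL
    }
  }
  nodes
}

finalize_bn_accumulators <- function(nodes) {
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "resblock") {
      nodes[[i]]$main <- finalize_bn_accumulators(nodes[[i]]$main)
      if (!is.null(nodes[[i]]$shortcut))
        nodes[[i]]$shortcut <- finalize_bn_accumulators(nodes[[i]]$shortcut)
    } else if (nodes[[i]]$type %in% c("bn2d", "bn1d")) {
      nodes[[i]] <- bn_finalize_accumulation(nodes[[i]])
    }
  }
  nodes
}

## ---- builders --------------------------------------------------------

scaled_width <- function(w, scale) max(4L, as.integer(round(w * scale)))

basic_block <- function(in_ch, out_ch, stride) {
  main <- list(make_conv(in_ch, out_ch, 3L, stride, 1L), make_bn2d(out_ch),
               make_relu(), make_conv(out_ch, out_ch, 3L, 1L, 1L),
               make_bn2d(out_ch))
  shortcut <- NULL
  if (stride != 1L || in_ch != out_ch) {
    ## "d"-variant downsampling: average pool, then 1x1 convolution
    shortcut <- list()
    if (stride != 1L) shortcut <- c(shortcut, list(make_avgpool2()))
    shortcut <- c(shortcut, list(make_conv(in_ch, out_ch, 1L, 1L, 0L),
                                 make_bn2d(out_ch)))
  }
  list(type = "resblock", main = main, shortcut = shortcut)
}

make_bn2d <- function(ch) { l <- make_bn(ch); l$type <- "bn2d"; l }
make_bn1d <- function(ch) { l <- make_bn(ch); l$type <- "bn1d"; l }

#' Image model configuration
#'
#' @param in_channels Input channel count (100 HSI, 200 stacked HSI,
#'   4 TPI, 3 RGB).
#' @param width_scale Multiplier on the reference stage widths
#'   (32/32/64 stem, 64/128/256/512 stages); desk-scale runs use 0.25.
#' @param bottleneck_dim Bottleneck feature size (10, matching the
#'   clinical head).
#' @param n_classes Number of output logits.
#' @return Config list.
#' @export
image_model_config <- function(in_channels = 100L, width_scale = 1,
                               bottleneck_dim = 10L, n_classes = 2L) {
  stopifnot(in_channels >= 1L, width_scale > 0, bottleneck_dim >= 1L)
  list(in_channels = as.integer(in_channels), width_scale = width_scale,
       bottleneck_dim = as.integer(bottleneck_dim),
       n_classes = as.integer(n_classes))
}

#' Build the residual image classifier
#'
#' A 14-layer-class residual CNN: a deep stem of three 3x3 convolutions
#' (the first with stride 2) with batch normalization and ReLU, a 3x3/2
#' max pool, four stages of one basic residual block each (stride-2
#' transitions with average-pool + 1x1-convolution shortcut
#' downsampling, the "d" variant), global average pooling, a linear
#' bottleneck of size `bottleneck_dim` with batch normalization, and a
#' linear classification head. Weights are He-initialized from R's
#' global random stream (use `seed` for reproducible builds).
#'
#' @param cfg An [image_model_config()].
#' @param seed Optional integer; when given, `set.seed(seed)` is applied
#'   before initialization.
#' @return Model object (`kind = "image"`) with `trunk` (through the
#'   bottleneck batch norm) and `head` node lists.
#' @export
build_image_model <- function(cfg = image_model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ws <- cfg$width_scale
  c1 <- scaled_width(32L, ws); c2 <- scaled_width(64L, ws)
  st <- vapply(c(64L, 128L, 256L, 512L), scaled_width, integer(1), scale = ws)
  trunk <- list(
    make_conv(cfg$in_channels, c1, 3L, 2L, 1L), make_bn2d(c1), make_relu(),
    make_conv(c1, c1, 3L, 1L, 1L), make_bn2d(c1), make_relu(),
    make_conv(c1, c2, 3L, 1L, 1L), make_bn2d(c2), make_relu(),
    make_maxpool(3L, 2L, 1L),
    basic_block(c2, st[1L], 1L),
    basic_block(st[1L], st[2L], 2L),
    basic_block(st[2L], st[3L], 2L),
    basic_block(st[3L], st[4L], 2L),
    make_gap(),
    make_linear(st[4L], cfg$bottleneck_dim),
    make_bn1d(cfg$bottleneck_dim)
  )
  head <- list(make_relu(),
               make_linear(cfg$bottleneck_dim, cfg$n_classes))
  structure(list(kind = "image", trunk = trunk, head = head, config = cfg),
            class = "sepsishsi_model")
}

#' Fusion model configuration
#'
#' @param clinical_hidden Widths of the two fully connected clinical
#'   blocks (fixed to 50, 30 unless overridden).
#' @param clinical_head Clinical head size (10, matching the image
#'   bottleneck).
#' @param dropout_rate Dropout probability in the clinical and fused
#'   blocks.
#' @param fused_hidden Width of the post-concatenation block.
#' @return Config list.
#' @export
fusion_model_config <- function(clinical_hidden = c(50L, 30L),
                                clinical_head = 10L, dropout_rate = 0.1,
                                fused_hidden = 20L) {
  stopifnot(length(clinical_hidden) == 2L, clinical_head >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  list(clinical_hidden = as.integer(clinical_hidden),
       clinical_head = as.integer(clinical_head),
       dropout_rate = dropout_rate, fused_hidden = as.integer(fused_hidden))
}

clinical_encoder_nodes <- function(n_features, fcfg) {
  h <- fcfg$clinical_hidden
  list(
    ## block 1: linear, batch norm, ELU, dropout
    make_linear(n_features, h[1L]), make_bn1d(h[1L]), make_elu(),
    make_dropout(fcfg$dropout_rate),
    ## block 2
    make_linear(h[1L], h[2L]), make_bn1d(h[2L]), make_elu(),
    make_dropout(fcfg$dropout_rate),
    ## linear head to the bottleneck size, then bottleneck batch norm
    make_linear(h[2L], fcfg$clinical_head), make_bn1d(fcfg$clinical_head)
  )
}

#' Build the clinical tabular encoder
#'
#' Two fully connected blocks (linear, batch normalization, exponential
#' linear unit, dropout; widths 50 and 30) followed by a linear head of
#' size 10 and its batch normalization.
#'
#' @param n_features Number of input features (33 for the 1h tier,
#'   45 for 10h).
#' @param fcfg A [fusion_model_config()].
#' @param seed Optional init seed.
#' @return Model object (`kind = "clinical_encoder"`).
#' @export
build_clinical_submodel <- function(n_features, fcfg = fusion_model_config(),
                                    seed = NULL) {
  stopifnot(n_features >= 1L)
  if (!is.null(seed)) set.seed(seed)
  structure(list(kind = "clinical_encoder",
                 nodes = clinical_encoder_nodes(n_features, fcfg),
                 config = fcfg, n_features = n_features),
            class = "sepsishsi_model")
}

#' Build the multimodal fusion classifier
#'
#' The image trunk (through its 10-dim bottleneck batch norm) and the
#' clinical encoder (through its 10-dim head batch norm) are
#' concatenated to 20 features and passed through one fully connected
#' block (default width 20) and a 2-logit head.
#'
#' @param icfg An [image_model_config()].
#' @param fcfg A [fusion_model_config()].
#' @param n_features Clinical feature count.
#' @param seed Optional init seed.
#' @return Model object (`kind = "fusion"`).
#' @export
build_fusion_model <- function(icfg = image_model_config(),
                               fcfg = fusion_model_config(),
                               n_features = 33L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  image <- build_image_model(icfg)
  concat_dim <- icfg$bottleneck_dim + fcfg$clinical_head
  fused <- list(
    make_linear(concat_dim, fcfg$fused_hidden),
    make_bn1d(fcfg$fused_hidden), make_elu(),
    make_dropout(fcfg$dropout_rate),
    make_linear(fcfg$fused_hidden, icfg$n_classes)
  )
  structure(list(kind = "fusion", image_trunk = image$trunk,
                 clinical = clinical_encoder_nodes(n_features, fcfg),
                 fused = fused, config = list(image = icfg, fusion = fcfg),
                 n_features = n_features),
            class = "sepsishsi_model")
}

## ---- whole-model forward / backward ---------------------------------

model_forward <- function(model, batch, mode = "eval") {
  if (model$kind == "image") {
    tr <- run_seq(model$trunk, batch$images, mode)
    hd <- run_seq(model$head, tr$y, mode)
    model$trunk <- tr$nodes; model$head <- hd$nodes
    list(logits = hd$y, model = model,
         caches = list(trunk = tr$caches, head = hd$caches))
  } else if (model$kind == "fusion") {
    tr <- run_seq(model$image_trunk, batch$images, mode)
    cl <- run_seq(model$clinical, batch$clinical, mode)
    fu <- run_seq(model$fused, cbind(tr$y, cl$y), mode)
    model$image_trunk <- tr$nodes; model$clinical <- cl$nodes
    model$fused <- fu$nodes
    list(logits = fu$y, model = model,
         caches = list(trunk = tr$caches, clinical = cl$caches,
                       fused = fu$caches, img_dim = ncol(tr$y)))
  } else stop("cannot run forward on kind ", model$kind)
}

model_backward <- function(model, caches, dlogits) {
  if (model$kind == "image") {
    hd <- back_seq(model$head, caches$head, dlogits)
    tr <- back_seq(model$trunk, caches$trunk, hd$dx)
    list(trunk = tr$grads, head = hd$grads)
  } else {
    fu <- back_seq(model$fused, caches$fused, dlogits)
    k <- caches$img_dim
    tr <- back_seq(model$image_trunk, caches$trunk,
                   fu$dx[, seq_len(k), drop = FALSE])
    cl <- back_seq(model$clinical, caches$clinical,
                   fu$dx[, -seq_len(k), drop = FALSE])
    list(trunk = tr$grads, clinical = cl$grads, fused = fu$grads)
  }
}

model_branches <- function(model) {
  switch(model$kind,
         image = c("trunk", "head"),
         fusion = c("image_trunk", "clinical", "fused"),
         clinical_encoder = "nodes")
}

grad_branch_name <- function(model, branch) {
  ## gradient lists use "trunk" for the fusion image trunk
  if (model$kind == "fusion" && branch == "image_trunk") "trunk" else branch
}
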
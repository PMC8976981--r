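# Network container: a topologically ordered list of nodes (conv / pool /
# upconv / concat) plus a parameter list. Forward caches every node output;
# backward returns gradients with respect to every node's post-activation
# output (the capture contract used by the Grad-CAM and randomization
# modules) together with all parameter gradients.

#' 3-D U-Net architecture specification
#'
#' Three encoder blocks with 2x2x2 max pooling, a bottleneck, three decoder
#' blocks with 2x2x2/stride-2 transposed convolutions and skip concatenation,
#' and a 1x1x1 convolution head. Every convolution is 3x3x3 with stride 1 and
#' padding 1, followed by batch normalization and ReLU; the head is a 1x1x1
#' convolution with batch normalization and no activation (its output is the
#' pre-softmax class score).
#'
#' @param in_channels number of input channels (default 3: T2-like, ADC,
#'   high-b).
#' @param n_classes number of output classes (default 3: background, gland,
#'   tumor).
#' @param base_channels channels of the first encoder block; doubled at each
#'   level. The desk-scale default is 8.
#' @param convs_per_block convolutions per encoder/decoder/bottleneck block.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels = 3L, n_classes = 3L, base_channels = 8L,
                      convs_per_block = 2L) {
  assert_that(in_channels >= 1 && n_classes >= 2 && base_channels >= 1 &&
                convs_per_block >= 1, "spec values must be positive")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 convs_per_block = as.integer(convs_per_block),
                 n_levels = 3L),
            class = "unet_spec")
}

new_conv_node <- function(id, inputs, cin, cout, k = 3L, bn = TRUE,
                          act = "relu") {
  list(id = id, op = "conv", inputs = inputs, k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout), bn = bn, act = act,
       init_sd = sqrt(2 / (k^3 * cin)))
}

new_pool_node <- function(id, inputs) {
  list(id = id, op = "pool", inputs = inputs)
}

new_upconv_node <- function(id, inputs, cin, cout) {
  list(id = id, op = "upconv", inputs = inputs, cin = as.integer(cin),
       cout = as.integer(cout), init_sd = sqrt(2 / cin))
}

new_concat_node <- function(id, inputs) {
  list(id = id, op = "concat", inputs = inputs)
}

init_node_params <- function(node) {
  if (node$op == "conv") {
    nW <- node$k^3 * node$cin
    p <- list(W = matrix(stats::rnorm(nW * node$cout, sd = node$init_sd),
                         nW, node$cout),
              b = numeric(node$cout))
    if (isTRUE(node$bn)) {
      p$gamma <- rep(1, node$cout)
      p$beta <- numeric(node$cout)
      p$r_mean <- numeric(node$cout)
      p$r_var <- rep(1, node$cout)
    }
    p
  } else if (node$op == "upconv") {
    list(W = matrix(stats::rnorm(node$cin * 8 * node$cout, sd = node$init_sd),
                    node$cin, 8 * node$cout),
         b = numeric(node$cout))
  } else {
    NULL
  }
}

new_network <- function(nodes, blocks, block_out, spec, seed, subclass) {
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  params <- with_seed(seed, lapply(nodes, init_node_params))
  structure(list(nodes = nodes, params = params, blocks = blocks,
                 block_out = block_out, spec = spec, seed = as.integer(seed),
                 trained = FALSE, training_log = NULL),
            class = c(subclass, "conv_net3d"))
}

#' Build an (untrained) 3-D U-Net
#'
#' Instantiates the architecture described by [unet_spec] with deterministic
#' He-normal initialization under `seed`. Named blocks are
#' `E1, E2, E3, BL, D1, D2, D3, HEAD`; block outputs (post-activation feature
#' maps) and their gradients are exposed by the forward/backward machinery,
#' which is what the Grad-CAM and randomization modules consume.
#'
#' @param spec a [unet_spec].
#' @param seed integer initialization seed.
#' @return An object of class `c("unet3d", "conv_net3d")`.
#' @export
unet_build <- function(spec = unet_spec(), seed = 1L) {
  assert_that(inherits(spec, "unet_spec"), "spec must be a unet_spec")
  f <- spec$base_channels
  npb <- spec$convs_per_block
  nodes <- list()
  blocks <- list()
  add <- function(node) nodes[[length(nodes) + 1L]] <<- node
  conv_block <- function(prefix, input, cin, cout) {
    ids <- character(npb)
    for (i in seq_len(npb)) {
      id <- sprintf("%s.%d", prefix, i)
      add(new_conv_node(id, input, if (i == 1L) cin else cout, cout))
      input <- id
      ids[i] <- id
    }
    blocks[[prefix]] <<- ids
    input
  }
  e1 <- conv_block("E1", "input", spec$in_channels, f)
  add(new_pool_node("P1", e1))
  e2 <- conv_block("E2", "P1", f, 2L * f)
  add(new_pool_node("P2", e2))
  e3 <- conv_block("E3", "P2", 2L * f, 4L * f)
  add(new_pool_node("P3", e3))
  bl <- conv_block("BL", "P3", 4L * f, 8L * f)
  dec <- function(prefix, below, skip, cin, cout) {
    up <- sprintf("%s.up", prefix)
    cat_id <- sprintf("%s.cat", prefix)
    add(new_upconv_node(up, below, cin, cout))
    add(new_concat_node(cat_id, c(up, skip)))
    last <- conv_block(prefix, cat_id, 2L * cout, cout)
    blocks[[prefix]] <<- c(up, blocks[[prefix]])
    last
  }
  d1 <- dec("D1", bl, e3, 8L * f, 4L * f)
  d2 <- dec("D2", d1, e2, 4L * f, 2L * f)
  d3 <- dec("D3", d2, e1, 2L * f, f)
  add(new_conv_node("HEAD", d3, f, spec$n_classes, k = 1L, bn = TRUE,
                    act = "none"))
  blocks[["HEAD"]] <- "HEAD"
  block_out <- c(E1 = e1, E2 = e2, E3 = e3, BL = bl, D1 = d1, D2 = d2,
                 D3 = d3, HEAD = "HEAD")
  new_network(nodes, blocks, block_out, spec, seed, "unet3d")
}

#' Build a small sequential convolutional network
#'
#' A plain chain of 3x3x3 (or 1x1x1) convolution layers ending in a 1x1x1
#' head that emits pre-softmax class scores. Useful as a transparent,
#' few-parameter network for demonstrating and verifying the Grad-CAM
#' machinery (e.g. against finite differences), since it shares all layer
#' and gradient code with the U-Net.
#'
#' @param in_channels input channels.
#' @param hidden integer vector of channel widths for the hidden conv layers.
#' @param n_classes output classes.
#' @param bn apply batch normalization in hidden layers.
#' @param seed initialization seed.
#' @return An object of class `c("conv_chain", "conv_net3d")` with blocks
#'   `C1..Cn` and `HEAD`.
#' @export
conv_chain <- function(in_channels = 2L, hidden = c(4L), n_classes = 2L,
                       bn = FALSE, seed = 1L) {
  nodes <- list()
  blocks <- list()
  input <- "input"
  cin <- in_channels
  for (i in seq_along(hidden)) {
    id <- sprintf("C%d", i)
    nodes[[length(nodes) + 1L]] <- new_conv_node(id, input, cin, hidden[i],
                                                 k = 3L, bn = bn, act = "relu")
    blocks[[id]] <- id
    input <- id
    cin <- hidden[i]
  }
  nodes[[length(nodes) + 1L]] <- new_conv_node("HEAD", input, cin, n_classes,
                                               k = 1L, bn = FALSE, act = "none")
  blocks[["HEAD"]] <- "HEAD"
  block_out <- c(stats::setNames(names(blocks), names(blocks)))
  spec <- list(in_channels = in_channels, n_classes = n_classes,
               hidden = hidden, n_levels = 0L)
  new_network(nodes, blocks, block_out, spec, seed, "conv_chain")
}

#' Count trainable parameters of a network
#' @param net a `conv_net3d`.
#' @return integer parameter count (conv weights/biases and batch-norm
#'   affine parameters).
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, function(p) {
    if (is.null(p)) return(0L)
    length(p$W) + length(p$b) +
      (if (!is.null(p$gamma)) length(p$gamma) + length(p$beta) else 0L)
  }, 0L))
}

# Forward pass. `x` is an (X,Y,Z,C) array. `override` is a named list of
# node-id -> replacement output used for finite-difference probing.
net_forward <- function(net, x, train = FALSE, override = NULL) {
  d <- dim(x)
  if (net$spec$n_levels > 0L) {
    if (!all(d[1:3] %% 2^net$spec$n_levels == 0)) {
      stop_sx("input shape %s is not divisible by %d per spatial axis",
              paste(d[1:3], collapse = "x"), 2^net$spec$n_levels)
    }
  }
  assert_that(d[4] == net$spec$in_channels,
              "input has %d channels but the network expects %d",
              d[4], net$spec$in_channels)
  out <- list(input = x)
  caches <- list()
  for (node in net$nodes) {
    id <- node$id
    res <- switch(node$op,
      conv = conv_fwd(node, net$params[[id]], out[[node$inputs]], train),
      pool = pool_fwd(out[[node$inputs]]),
      upconv = upconv_fwd(node, net$params[[id]], out[[node$inputs]]),
      concat = concat_fwd(out[[node$inputs[1]]], out[[node$inputs[2]]]))
    out[[id]] <- res$out
    caches[[id]] <- res$cache
    if (!is.null(override) && id %in% names(override)) {
      out[[id]] <- override[[id]]
    }
  }
  list(out = out, caches = caches)
}

# Backward pass from a gradient at the HEAD output. Returns gradients with
# respect to every node output (`gout`) and all parameter gradients
# (`pgrads`). `train` selects batch-statistics (TRUE) vs running-statistics
# (FALSE) batch-norm linearization.
net_backward <- function(net, fw, d_head, train = FALSE, need_pgrads = TRUE) {
  g <- list(HEAD = d_head)
  pgrads <- list()
  for (node in rev(net$nodes)) {
    id <- node$id
    dy <- g[[id]]
    if (is.null(dy)) next
    if (node$op == "conv") {
      r <- conv_bwd(node, net$params[[id]], fw$caches[[id]], dy,
                    fw$out[[id]], train, need_pgrads)
      pgrads[[id]] <- r$pg
      g[[node$inputs]] <- accum(g[[node$inputs]], r$dx)
    } else if (node$op == "pool") {
      g[[node$inputs]] <- accum(g[[node$inputs]], pool_bwd(fw$caches[[id]], dy))
    } else if (node$op == "upconv") {
      r <- upconv_bwd(node, net$params[[id]], fw$caches[[id]], dy, need_pgrads)
      pgrads[[id]] <- r$pg
      g[[node$inputs]] <- accum(g[[node$inputs]], r$dx)
    } else if (node$op == "concat") {
      r <- concat_bwd(fw$caches[[id]], dy)
      g[[node$inputs[1]]] <- accum(g[[node$inputs[1]]], r$da)
      g[[node$inputs[2]]] <- accum(g[[node$inputs[2]]], r$db)
    }
  }
  list(gout = g, pgrads = pgrads)
}

accum <- function(a, b) if (is.null(a)) b else a + b

#' @export
print.conv_net3d <- function(x, ...) {
  cat(sprintf("%s: %d nodes, %d blocks, %s parameters%s\n",
              class(x)[1], length(x$nodes), length(x$blocks),
              format(n_parameters(x), big.mark = ","),
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

#' @export
summary.unet3d <- function(object, ...) {
  cat(sprintf("3-D U-Net | in %d channels, %d classes, base %d, %d conv(s)/block\n",
              object$spec$in_channels, object$spec$n_classes,
              object$spec$base_channels, object$spec$convs_per_block))
  cat(sprintf("parameters: %s | trained: %s\n",
              format(n_parameters(object), big.mark = ","), object$trained))
  if (!is.null(object$training_log)) {
    n <- nrow(object$training_log)
    cat(sprintf("training: %d epochs, loss %.4f -> %.4f\n", n,
                object$training_log$loss[1], object$training_log$loss[n]))
  }
  for (b in names(object$blocks)) {
    cat(sprintf("  %-4s : %s\n", b, paste(object$blocks[[b]], collapse = ", ")))
  }
  invisible(object)
}
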
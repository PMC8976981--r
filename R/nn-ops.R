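# Layer primitives for the 3-D network. Activations are (X, Y, Z, C) arrays;
# convolutions are evaluated as im2col matrix products so the heavy lifting
# runs through BLAS. All layers provide exact reverse-mode backward passes.

BN_EPS <- 1e-5

# Unfold a (X,Y,Z,C) array into a prod(XYZ) x (27*C) matrix for a 3x3x3
# convolution with zero padding 1. Column order: kernel offset major
# (dx fastest, then dy, dz), channel minor within each offset.
im2col3_ref <- function(x) {
  d <- dim(x)
  C <- d[4]
  V <- prod(d[1:3])
  xp <- array(0, c(d[1] + 2, d[2] + 2, d[3] + 2, C))
  xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  cols <- matrix(0, V, 27 * C)
  o <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    o <- o + 1L
    blk <- xp[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3]), ,
              drop = FALSE]
    cols[, ((o - 1L) * C + 1L):(o * C)] <- matrix(blk, V, C)
  }
  cols
}

# Adjoint of im2col3: scatter-add a prod(XYZ) x (27*C) gradient back onto the
# (X,Y,Z,C) input grid.
col2im3_ref <- function(dcols, d) {
  C <- d[4]
  dxp <- array(0, c(d[1] + 2, d[2] + 2, d[3] + 2, C))
  o <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    o <- o + 1L
    ix <- dx + seq_len(d[1]); iy <- dy + seq_len(d[2]); iz <- dz + seq_len(d[3])
    dxp[ix, iy, iz, ] <- dxp[ix, iy, iz, , drop = FALSE] +
      array(dcols[, ((o - 1L) * C + 1L):(o * C)], c(d[1:3], C))
  }
  dxp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), , drop = FALSE]
}

rep_row <- function(v, n) rep(v, each = n)

# conv (k = 3 pad 1, or k = 1) + optional batch norm + optional ReLU.
conv_fwd <- function(node, p, x, train) {
  d <- dim(x)
  V <- prod(d[1:3])
  s <- if (node$k == 3L) conv3_mm_cpp(x, p$W, dim(x)) else
    matrix(x, V, d[4]) %*% p$W
  s <- s + rep_row(p$b, V)
  cache <- list(d = d, x = x)
  if (isTRUE(node$bn)) {
    if (train) {
      mu <- colMeans(s)
      va <- colMeans(s * s) - mu * mu
      va[va < 0] <- 0
      cache$bn_update <- list(mean = mu, var = va)
    } else {
      mu <- p$r_mean
      va <- p$r_var
    }
    istd <- 1 / sqrt(va + BN_EPS)
    xhat <- (s - rep_row(mu, V)) * rep_row(istd, V)
    s <- xhat * rep_row(p$gamma, V) + rep_row(p$beta, V)
    cache$xhat <- xhat
    cache$istd <- istd
  }
  if (identical(node$act, "relu")) s <- pmax(s, 0)
  list(out = array(s, c(d[1:3], node$cout)), cache = cache)
}

conv_bwd <- function(node, p, cache, dy, out, train, need_pgrads = TRUE) {
  d <- cache$d
  V <- prod(d[1:3])
  dy <- matrix(dy, V, node$cout)
  if (identical(node$act, "relu")) dy <- dy * (matrix(out, V, node$cout) > 0)
  pg <- list()
  if (isTRUE(node$bn)) {
    if (need_pgrads) {
      pg$gamma <- colSums(dy * cache$xhat)
      pg$beta <- colSums(dy)
    }
    if (train) {
      dxhat <- dy * rep_row(p$gamma, V)
      ds <- rep_row(cache$istd, V) *
        (dxhat - rep_row(colMeans(dxhat), V) -
           cache$xhat * rep_row(colMeans(dxhat * cache$xhat), V))
    } else {
      ds <- dy * rep_row(p$gamma * cache$istd, V)
    }
  } else {
    ds <- dy
  }
  if (need_pgrads) {
    pg$W <- if (node$k == 3L) conv3_dw_cpp(cache$x, ds, d) else
      crossprod(matrix(cache$x, V, d[4]), ds)
    pg$b <- colSums(ds)
  }
  dx <- if (node$k == 3L) conv3_dx_cpp(ds, p$W, d) else
    array(ds %*% t(p$W), d)
  list(dx = dx, pg = pg)
}

# 2x2x2 max pooling, stride 2.
pool_fwd <- function(x) {
  d <- dim(x)
  assert_that(all(d[1:3] %% 2 == 0), "pooling needs even spatial dimensions")
  a <- x
  dim(a) <- c(2, d[1] / 2, 2, d[2] / 2, 2, d[3] / 2, d[4])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6, 7))
  m <- matrix(a, nrow = 8)
  amax <- max.col(t(m), ties.method = "first")
  out <- array(m[cbind(amax, seq_along(amax))], c(d[1:3] / 2, d[4]))
  list(out = out, cache = list(amax = amax, d = d))
}

pool_bwd <- function(cache, dy) {
  d <- cache$d
  n <- length(cache$amax)
  m <- matrix(0, 8, n)
  m[cbind(cache$amax, seq_len(n))] <- as.numeric(dy)
  a <- array(m, c(2, 2, 2, d[1] / 2, d[2] / 2, d[3] / 2, d[4]))
  a <- aperm(a, c(1, 4, 2, 5, 3, 6, 7))
  dim(a) <- d
  a
}

# Transposed convolution, kernel 2x2x2, stride 2, padding 0 (exact x2
# upsampling). Weight layout: cin x (8 * cout), output-channel minor within
# each of the 8 kernel offsets (dx fastest).
upconv_fwd <- function(node, p, x) {
  d <- dim(x)
  V <- prod(d[1:3])
  M <- matrix(x, V, d[4]) %*% p$W
  a <- array(M, c(d[1:3], node$cout, 2, 2, 2))
  a <- aperm(a, c(5, 1, 6, 2, 7, 3, 4))
  dim(a) <- c(2 * d[1:3], node$cout)
  a <- a + rep_row(p$b, 8 * V)
  list(out = a, cache = list(x = x, d = d))
}

upconv_bwd <- function(node, p, cache, dy, need_pgrads = TRUE) {
  d <- cache$d
  V <- prod(d[1:3])
  a <- dy
  dim(a) <- c(2, d[1], 2, d[2], 2, d[3], node$cout)
  a <- aperm(a, c(2, 4, 6, 7, 1, 3, 5))
  dM <- matrix(a, V, 8 * node$cout)
  pg <- NULL
  if (need_pgrads) {
    pg <- list(W = crossprod(matrix(cache$x, V, d[4]), dM),
               b = rowSums(matrix(colSums(dM), node$cout, 8)))
  }
  dx <- array(dM %*% t(p$W), d)
  list(dx = dx, pg = pg)
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  assert_that(all(da[1:3] == db[1:3]),
              "concat inputs must share spatial dimensions")
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  list(out = out, cache = list(c1 = da[4], c2 = db[4]))
}

concat_bwd <- function(cache, dy) {
  list(da = dy[, , , seq_len(cache$c1), drop = FALSE],
       db = dy[, , , cache$c1 + seq_len(cache$c2), drop = FALSE])
}

# Row-wise numerically stable softmax of a V x C matrix.
softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}
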
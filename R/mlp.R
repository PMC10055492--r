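# Minimal dense-network engine: fully connected stacks with rectified-linear
# hidden units, reverse-mode gradients and SGD-with-momentum updates. Batches
# are rows; all arithmetic is plain BLAS matrix algebra. This is the
# substrate for the three CVAE estimators; it is deliberately small (fixed
# architecture family, no autograd) and exhaustively checked against
# finite-difference gradients in the test suite.

# One dense layer, initialized like a torch Linear layer:
# W, b ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
#' @noRd
initLayer <- function(nin, nout) {
  bd <- 1 / sqrt(nin)
  list(W = matrix(stats::runif(nin * nout, -bd, bd), nin, nout),
       b = stats::runif(nout, -bd, bd))
}

# A stack of dense layers with widths `widths` on top of `nin` inputs.
# The first `nAct` layers get a ReLU; the rest are linear.
#' @noRd
initStack <- function(nin, widths, nAct) {
  dims <- c(nin, widths)
  layers <- lapply(seq_along(widths),
                   function(l) initLayer(dims[l], dims[l + 1]))
  list(layers = layers, nAct = nAct)
}

#' @noRd
stackForward <- function(stack, X) {
  A <- vector("list", length(stack$layers) + 1)
  Z <- vector("list", length(stack$layers))
  A[[1]] <- X
  for (l in seq_along(stack$layers)) {
    ly <- stack$layers[[l]]
    Z[[l]] <- sweep(A[[l]] %*% ly$W, 2, ly$b, "+")
    A[[l + 1]] <- if (l <= stack$nAct) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(A = A, Z = Z, out = A[[length(A)]])
}

# dOut: gradient of the scalar loss wrt the stack output (batch x nout).
# Returns per-layer parameter gradients plus the gradient wrt the input.
#' @noRd
stackBackward <- function(stack, cache, dOut) {
  L <- length(stack$layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- if (l <= stack$nAct) dA * (cache$Z[[l]] > 0) else dA
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(stack$layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

# Encoders have a shared trunk (all-ReLU) and two linear heads emitting the
# latent mean and log-variance.
#' @noRd
initEncoder <- function(nin, widths, K) {
  list(trunk = initStack(nin, widths, nAct = length(widths)),
       muHead = initLayer(widths[length(widths)], K),
       lvHead = initLayer(widths[length(widths)], K))
}

#' @noRd
encoderForward <- function(enc, X) {
  tc <- stackForward(enc$trunk, X)
  H <- tc$out
  list(trunk = tc,
       mu = sweep(H %*% enc$muHead$W, 2, enc$muHead$b, "+"),
       lv = sweep(H %*% enc$lvHead$W, 2, enc$lvHead$b, "+"))
}

#' @noRd
encoderBackward <- function(enc, cache, dMu, dLv) {
  H <- cache$trunk$out
  gMu <- list(W = crossprod(H, dMu), b = colSums(dMu))
  gLv <- list(W = crossprod(H, dLv), b = colSums(dLv))
  dH <- dMu %*% t(enc$muHead$W) + dLv %*% t(enc$lvHead$W)
  tb <- stackBackward(enc$trunk, cache$trunk, dH)
  list(trunk = tb$grads, muHead = gMu, lvHead = gLv, dX = tb$dX)
}

# --- SGD with momentum ----------------------------------------------------
# Velocity buffers mirror the gradient structures returned by stackBackward
# (list of per-layer W/b) and encoderBackward (trunk/muHead/lvHead).
# Update rule (torch convention): v <- momentum*v + g ; p <- p - lr*v.

#' @noRd
zeroGradStack <- function(stack) {
  lapply(stack$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
}

#' @noRd
zeroGradEncoder <- function(enc) {
  list(trunk = zeroGradStack(enc$trunk),
       muHead = list(W = enc$muHead$W * 0, b = enc$muHead$b * 0),
       lvHead = list(W = enc$lvHead$W * 0, b = enc$lvHead$b * 0))
}

#' @noRd
updateLayer <- function(ly, g, v, lr, momentum) {
  v$W <- momentum * v$W + g$W
  v$b <- momentum * v$b + g$b
  list(layer = list(W = ly$W - lr * v$W, b = ly$b - lr * v$b), v = v)
}

#' @noRd
updateStack <- function(stack, grads, vel, lr, momentum) {
  for (l in seq_along(stack$layers)) {
    u <- updateLayer(stack$layers[[l]], grads[[l]], vel[[l]], lr, momentum)
    stack$layers[[l]] <- u$layer
    vel[[l]] <- u$v
  }
  list(net = stack, v = vel)
}

#' @noRd
updateEncoder <- function(enc, grads, vel, lr, momentum) {
  u <- updateStack(enc$trunk, grads$trunk, vel$trunk, lr, momentum)
  enc$trunk <- u$net; vel$trunk <- u$v
  for (h in c("muHead", "lvHead")) {
    u <- updateLayer(enc[[h]], grads[[h]], vel[[h]], lr, momentum)
    enc[[h]] <- u$layer
    vel[[h]] <- u$v
  }
  list(net = enc, v = vel)
}
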
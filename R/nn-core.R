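# Minimal feed-forward network machinery in base R matrix code.
# Forward passes return caches consumed by the matching backward passes;
# gradients are analytic and are verified against central differences in the
# test suite.

# He-uniform initialization for a dense layer.
.initDense <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
       b = numeric(nout))
}

#' Initialize a feed-forward embedding network
#'
#' Dense layers with ReLU between them (linear output layer) and optional
#' inverted dropout after each hidden activation.
#'
#' @param dims integer vector of layer widths, input first, e.g.
#'   `c(1544, 512, 256)`
#' @param seed integer RNG seed
#' @return list of dense layers (`W`, `b`)
#' @export
mlpInit <- function(dims, seed = 1L) {
  stopifnot(length(dims) >= 2L)
  withSeed(seed, lapply(seq_len(length(dims) - 1L), function(i)
    .initDense(dims[i], dims[i + 1L])))
}

# Forward pass. dropout > 0 only during training (inverted dropout; masks
# drawn from the current RNG stream). Returns list(out, cache).
mlpForward <- function(params, X, dropout = 0) {
  L <- length(params)
  cache <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    Z <- A %*% params[[i]]$W
    Z <- sweep(Z, 2, params[[i]]$b, "+")
    ci <- list(A_in = A)
    if (i < L) {
      H <- Z * (Z > 0)                      # ReLU
      ci$relu_mask <- Z > 0
      if (dropout > 0) {
        keep <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
        H <- H * keep / (1 - dropout)
        ci$drop_mask <- keep
        ci$dropout <- dropout
      }
      A <- H
    } else {
      A <- Z
    }
    cache[[i]] <- ci
  }
  list(out = A, cache = cache)
}

# Backward pass: dOut is dLoss/dOutput. Returns list(grads, dX).
mlpBackward <- function(params, cache, dOut) {
  L <- length(params)
  grads <- vector("list", L)
  dA <- dOut
  for (i in rev(seq_len(L))) {
    ci <- cache[[i]]
    dZ <- dA
    if (i < L) {
      if (!is.null(ci$drop_mask)) dZ <- dZ * ci$drop_mask / (1 - ci$dropout)
      dZ <- dZ * ci$relu_mask
    }
    grads[[i]] <- list(W = crossprod(ci$A_in, dZ), b = colSums(dZ))
    dA <- dZ %*% t(params[[i]]$W)
  }
  list(grads = grads, dX = dA)
}

# ---- Adam optimizer over arbitrarily nested lists of numeric arrays ----

.zerosLike <- function(p) {
  if (is.list(p)) lapply(p, .zerosLike) else p * 0
}

adamInit <- function(params) {
  list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)
}

# Elementwise Adam update; params and grads share structure.
adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Sum two grad structures (for accumulating over a batch of tasks).
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(.addGrads, a, b, SIMPLIFY = FALSE))
  a + b
}

.scaleGrads <- function(g, s) {
  if (is.list(g)) return(lapply(g, .scaleGrads, s = s))
  g * s
}
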
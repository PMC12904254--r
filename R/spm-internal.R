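## Internal neural machinery for the selection probabilistic model.
##
## The trunk f_theta is a fully connected ReLU network on one-hot encoded
## sequences. With affine per-round heads f_r = a_r f + b_r (a_r >= 0) and
## the model-propagated round distribution q_r = q_{r-1} e^{f_r} / Z_r,
## the round-r multinomial probabilities collapse to
##   p_r = softmax( log q0 + A_r f ),   A_r = sum_{s<=r} a_s,
## because b_r and the per-round normalizers are constant across sequences
## and cancel in the softmax. Only the cumulative slopes A_r are likelihood-
## identified; b_r is fixed afterwards by the zero-mean gauge.

.oneHot <- function(scheme, sequences) {
  li <- .seqToLetterIdx(scheme, sequences)
  p <- ncol(li); q <- length(schemeAlphabet(scheme))
  X <- matrix(0, nrow(li), p * q)
  for (j in seq_len(p))
    X[cbind(seq_len(nrow(li)), (j - 1L) * q + li[, j])] <- 1
  X
}

.nnInit <- function(dIn, hidden, seed) {
  dims <- c(dIn, hidden, 1L)
  .withSeed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      ## He initialization for ReLU stacks
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    list(W = W, b = b)
  })
}

## forward / backward passes; drop = list(units = list of dropped-unit
## index vectors (1-based), scale = 1/keep) for unit dropout shared
## across the batch (appropriate for full-batch training), or NULL at
## inference. The heavy lifting lives in the Rcpp kernels.
.nnForward <- function(par, X, drop = NULL) {
  du <- if (is.null(drop)) list() else
    lapply(drop$units, function(u) as.integer(u) - 1L)
  sc <- if (is.null(drop)) 1 else drop$scale
  r <- .mlpForwardCpp(par$W, par$b, X, du, sc)
  r$f <- as.numeric(r$f)
  r
}

.nnBackward <- function(par, X, fw, g, drop = NULL) {
  du <- if (is.null(drop)) list() else
    lapply(drop$units, function(u) as.integer(u) - 1L)
  sc <- if (is.null(drop)) 1 else drop$scale
  gr <- .mlpBackwardCpp(par$W, X, fw$H, g, du, sc)
  gr$b <- lapply(gr$b, as.numeric)
  gr
}

.logSumExp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## Full-batch loss and gradient of the SPM objective.
## cm: counts matrix (n x R) already masked for training; logq0: length n.
.spmLossGrad <- function(par, alpha, X, logq0, cm, weightDecay,
                         drop = NULL, wantGrad = TRUE) {
  fw <- .nnForward(par, X, drop)
  f <- fw$f
  a <- .softplus(alpha)
  A <- cumsum(a)
  R <- ncol(cm)
  loss <- 0
  gf <- numeric(length(f))
  dA <- numeric(R)
  P <- matrix(0, length(f), R)
  for (r in seq_len(R)) {
    logits <- logq0 + A[r] * f
    lse <- .logSumExp(logits)
    logp <- logits - lse
    loss <- loss - sum(cm[, r] * logp)
    p <- exp(logp)
    P[, r] <- p
    Tr <- sum(cm[, r])
    resid <- Tr * p - cm[, r]
    gf <- gf + A[r] * resid
    dA[r] <- sum(resid * f)
  }
  if (weightDecay > 0)
    loss <- loss + weightDecay / 2 *
      sum(vapply(par$W, function(w) sum(w^2), 0))
  if (!wantGrad)
    return(list(loss = loss, f = f, P = P))
  gpar <- .nnBackward(par, X, fw, gf, drop)
  if (weightDecay > 0)
    for (l in seq_along(gpar$W))
      gpar$W[[l]] <- gpar$W[[l]] + weightDecay * par$W[[l]]
  ## d loss / d a_s = sum_{r >= s} dA_r ; chain through softplus
  ga <- rev(cumsum(rev(dA))) * stats::plogis(alpha)
  list(loss = loss, grad = gpar, galpha = ga, f = f, P = P)
}

## Adam optimizer state over a flat list of arrays
.adamInit <- function(shapes) {
  list(m = lapply(shapes, function(s) array(0, dim = dim(s) %||% length(s))),
       v = lapply(shapes, function(s) array(0, dim = dim(s) %||% length(s))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
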
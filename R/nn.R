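# Minimal feed-forward engine: 1-D valid convolutions, max-pooling, dropout,
# dense layers, softmax cross-entropy, Adam. Inputs are n x d matrices
# treated as length-d single-channel sequences. Everything is plain matrix
# algebra so a fixed seed gives bit-reproducible fits.
#
# Spatial activations are stored as (n * len) x channels matrices with row
# index (p - 1) * n + i for sample i at position p. In that layout the
# im2col gather for a valid convolution is a contiguous row block per
# kernel offset, and flattening to the dense layers is a plain dim change
# (both column-major orders coincide), so no array permutes are needed.

nn_new <- function(layers, input_len, n_out, seed) {
  len <- input_len; ch <- 1L
  params <- list()
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "conv1d") {
        fan_in <- l$kernel * ch
        sd0 <- sqrt(2 / fan_in)
        params[[i]] <- list(W = matrix(stats::rnorm(fan_in * l$filters, 0, sd0),
                                       fan_in, l$filters),
                            b = numeric(l$filters))
        len <- len - l$kernel + 1L; ch <- l$filters
        if (len < 1) abort_config("conv1d output length < 1")
      } else if (l$type == "maxpool") {
        len <- len %/% l$pool
        if (len < 1) abort_config("maxpool output length < 1")
      } else if (l$type == "flatten") {
        len <- len * ch; ch <- 1L
      } else if (l$type == "dense") {
        if (ch != 1L) abort_config("dense layer needs flattened input")
        sd0 <- sqrt(2 / len)
        params[[i]] <- list(W = matrix(stats::rnorm(len * l$units, 0, sd0),
                                       len, l$units),
                            b = numeric(l$units))
        len <- l$units
      } else if (l$type != "dropout") {
        abort_config("unknown layer type: %s", l$type)
      }
    }
  })
  if (len != n_out) abort_config("last layer has %d units, expected %d",
                                 len, n_out)
  structure(list(layers = layers, params = params, input_len = input_len,
                 n_out = n_out, seed = seed), class = "radrehab_nn")
}

nn_forward_ref <- function(net, X, training = FALSE) {
  n <- nrow(X)
  A <- X                    # (n * len) x ch with len-major rows, ch = 1
  len <- ncol(X); ch <- 1L
  dim(A) <- c(n * len, 1L)
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv1d") {
      lenp <- len - l$kernel + 1L
      M <- matrix(0, n * lenp, l$kernel * ch)
      for (c0 in seq_len(ch)) for (j in seq_len(l$kernel))
        M[, (c0 - 1L) * l$kernel + j] <-
          A[((j - 1L) * n + 1L):((j - 1L + lenp) * n), c0]
      Z <- M %*% net$params[[i]]$W
      Z <- Z + rep(net$params[[i]]$b, each = nrow(Z))
      relu_mask <- Z > 0
      Z[!relu_mask] <- 0
      caches[[i]] <- list(M = M, relu = relu_mask, in_len = len, in_ch = ch)
      A <- Z; len <- lenp; ch <- l$filters
    } else if (l$type == "maxpool") {
      p <- l$pool
      lenp <- len %/% p
      # rows of output position q come from input positions (q-1)p + o
      base <- rep.int((seq_len(lenp) - 1L) * p * n, rep.int(n, lenp)) +
        rep.int(seq_len(n), lenp)
      out <- matrix(-Inf, n * lenp, ch)
      arg <- matrix(1L, n * lenp, ch)
      for (o in seq_len(p)) {
        slice <- A[base + (o - 1L) * n, , drop = FALSE]
        upd <- slice > out
        out[upd] <- slice[upd]
        arg[upd] <- o
      }
      caches[[i]] <- list(arg = arg, base = base, in_len = len, in_ch = ch)
      A <- out; len <- lenp
    } else if (l$type == "flatten") {
      caches[[i]] <- list(in_len = len, in_ch = ch)
      dim(A) <- c(n * len * ch, 1L)
      len <- len * ch; ch <- 1L
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- (matrix(stats::runif(length(A)), nrow(A), ncol(A)) >=
                   l$rate) / (1 - l$rate)
        A <- A * mask
        caches[[i]] <- list(mask = mask)
      } else caches[[i]] <- list(mask = NULL)
    } else if (l$type == "dense") {
      Xm <- A
      dim(Xm) <- c(n, len)
      Z <- Xm %*% net$params[[i]]$W
      Z <- Z + rep(net$params[[i]]$b, each = n)
      if (identical(l$act, "relu")) {
        relu_mask <- Z > 0
        Z[!relu_mask] <- 0
        caches[[i]] <- list(X = Xm, relu = relu_mask)
      } else if (identical(l$act, "softmax")) {
        Z <- Z - apply(Z, 1, max)
        E <- exp(Z)
        Z <- E / rowSums(E)
        caches[[i]] <- list(X = Xm)
      } else {
        caches[[i]] <- list(X = Xm)
      }
      A <- Z
      dim(A) <- c(n * l$units, 1L)
      len <- l$units
    }
  }
  out <- A
  dim(out) <- c(n, net$n_out)
  list(out = out, caches = caches, n = n)
}

# dOut: gradient at the network output, (P - Y)/n for softmax + CE.
nn_backward_ref <- function(net, fw, dOut) {
  n <- fw$n
  grads <- vector("list", length(net$layers))
  dA <- dOut
  dim(dA) <- c(n * ncol(dOut), 1L)
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- fw$caches[[i]]
    if (l$type == "dense") {
      dZ <- matrix(dA, n, length(dA) / n)
      if (identical(l$act, "relu")) dZ <- dZ * cache$relu
      grads[[i]] <- list(W = crossprod(cache$X, dZ), b = colSums(dZ))
      dX <- dZ %*% t(net$params[[i]]$W)
      dA <- dX
      dim(dA) <- c(length(dX), 1L)
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) dA <- dA * cache$mask
    } else if (l$type == "flatten") {
      dim(dA) <- c(n * cache$in_len, cache$in_ch)
    } else if (l$type == "maxpool") {
      p <- l$pool
      ch <- cache$in_ch
      dIn <- matrix(0, n * cache$in_len, ch)
      for (o in seq_len(p)) {
        sel <- cache$arg == o
        rows <- cache$base + (o - 1L) * n
        for (c0 in seq_len(ch)) {
          hit <- sel[, c0]
          dIn[rows[hit], c0] <- dIn[rows[hit], c0] + dA[hit, c0]
        }
      }
      dA <- dIn
    } else if (l$type == "conv1d") {
      dZ <- dA
      dim(dZ) <- dim(cache$relu)
      dZ <- dZ * cache$relu
      grads[[i]] <- list(W = crossprod(cache$M, dZ), b = colSums(dZ))
      dM <- dZ %*% t(net$params[[i]]$W)
      lenp <- nrow(dZ) / n
      dIn <- matrix(0, n * cache$in_len, cache$in_ch)
      for (c0 in seq_len(cache$in_ch)) for (j in seq_len(l$kernel)) {
        rows <- ((j - 1L) * n + 1L):((j - 1L + lenp) * n)
        dIn[rows, c0] <- dIn[rows, c0] + dM[, (c0 - 1L) * l$kernel + j]
      }
      dA <- dIn
    }
  }
  grads
}

# Mini-batch Adam on softmax cross-entropy. The loop runs in compiled code
# (src/nn.cpp); shuffling and dropout draw from R's RNG, so the fit is a
# pure function of (net, data, schedule) under with_seed().
nn_fit <- function(net, X, y_idx, epochs = 50L, batch_size = 128L,
                   lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  with_seed(net$seed + 1L, {
    net$params <- cpp_nn_fit(net$layers, net$params, X,
                             as.integer(y_idx), net$n_out,
                             as.integer(epochs), as.integer(batch_size),
                             lr, beta1, beta2, eps)
  })
  net
}

nn_predict_proba <- function(net, X) {
  cpp_nn_forward(net$layers, net$params, X, net$n_out)
}
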
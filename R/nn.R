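## Internals of the shallow feedforward network (6 -> 5 -> 3 by default):
## tanh hidden layer, linear output, trained by Levenberg-Marquardt on the
## full least-squares objective (with a BFGS fallback). The network is
## small (53 parameters at default size) so the normal equations are cheap
## and LM converges in a few dozen iterations.

nn_init <- function(n_in, n_hidden, n_out, seed) {
  with_seed(seed, {
    list(W1 = matrix(rnorm(n_hidden * n_in, 0, 0.5), n_hidden, n_in),
         b1 = rnorm(n_hidden, 0, 0.1),
         W2 = matrix(rnorm(n_out * n_hidden, 0, 0.5), n_out, n_hidden),
         b2 = rnorm(n_out, 0, 0.1))
  })
}

nn_pack <- function(w) c(as.vector(w$W1), w$b1, as.vector(w$W2), w$b2)

nn_unpack <- function(theta, n_in, n_hidden, n_out) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(n_hidden * n_in)], n_hidden, n_in)
  i <- i + n_hidden * n_in
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  W2 <- matrix(theta[i + seq_len(n_out * n_hidden)], n_out, n_hidden)
  i <- i + n_out * n_hidden
  b2 <- theta[i + seq_len(n_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# forward pass; X is n x n_in, returns list(H = n x n_hidden, Y = n x n_out)
nn_forward <- function(w, X) {
  H <- tanh(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  Y <- sweep(H %*% t(w$W2), 2, w$b2, "+")
  list(H = H, Y = Y)
}

# residual vector (stacked by output) and Jacobian of residuals wrt params
nn_residual_jacobian <- function(w, X, T) {
  n <- nrow(X); n_in <- ncol(X)
  n_hidden <- nrow(w$W1); n_out <- nrow(w$W2)
  fw <- nn_forward(w, X)
  R <- fw$Y - T
  dH <- 1 - fw$H^2
  npar <- n_hidden * n_in + n_hidden + n_out * n_hidden + n_out
  J <- matrix(0, n * n_out, npar)
  for (k in seq_len(n_out)) {
    rows <- (k - 1) * n + seq_len(n)
    G <- sweep(dH, 2, w$W2[k, ], "*")          # n x n_hidden
    # W1 block (columns ordered as as.vector(W1): hidden fast, input slow)
    for (m in seq_len(n_in)) {
      cols <- (m - 1) * n_hidden + seq_len(n_hidden)
      J[rows, cols] <- G * X[, m]
    }
    off <- n_hidden * n_in
    J[rows, off + seq_len(n_hidden)] <- G      # b1 block
    off <- off + n_hidden
    # W2 block (as.vector(W2): output fast, hidden slow)
    for (j in seq_len(n_hidden)) {
      J[rows, off + (j - 1) * n_out + k] <- fw$H[, j]
    }
    off <- off + n_out * n_hidden
    J[rows, off + k] <- 1                      # b2 block
  }
  list(r = as.vector(R), J = J, sse = sum(R^2))
}

nn_sse <- function(w, X, T) {
  R <- nn_forward(w, X)$Y - T
  sum(R^2)
}

# Levenberg-Marquardt with validation-based early stopping. Returns the
# weights with the lowest validation SSE seen.
nn_train_lm <- function(w, Xtr, Ttr, Xval, Tval,
                        max_epochs = 200, patience = 20,
                        lambda0 = 1e-2, tol = 1e-12) {
  n_in <- ncol(Xtr); n_hidden <- nrow(w$W1); n_out <- nrow(w$W2)
  theta <- nn_pack(w)
  lambda <- lambda0
  best_val <- nn_sse(w, Xval, Tval)
  best_theta <- theta
  stall <- 0
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    w <- nn_unpack(theta, n_in, n_hidden, n_out)
    rj <- nn_residual_jacobian(w, Xtr, Ttr)
    if (!is.finite(rj$sse)) {
      abort(sprintf("training diverged at epoch %d: non-finite loss", epoch))
    }
    JtJ <- crossprod(rj$J)
    Jtr <- crossprod(rj$J, rj$r)
    # Marquardt scaling with a floor: parameters whose Jacobian column is
    # (near-)null — e.g. weights on a constant feature — still need real
    # damping or the normal equations become ill-conditioned
    dscale <- pmax(diag(JtJ), 1e-6 * mean(diag(JtJ)) + 1e-12)
    improved <- FALSE
    for (try in 1:30) {
      A <- JtJ + lambda * diag(dscale)
      step <- tryCatch(solve(A, Jtr), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- theta - as.vector(step)
      wc <- nn_unpack(cand, n_in, n_hidden, n_out)
      sse_c <- nn_sse(wc, Xtr, Ttr)
      if (is.finite(sse_c) && sse_c < rj$sse) {
        theta <- cand
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved) break
    wnew <- nn_unpack(theta, n_in, n_hidden, n_out)
    val <- nn_sse(wnew, Xval, Tval)
    history <- c(history, val)
    if (val < best_val - tol * max(best_val, 1)) {
      best_val <- val
      best_theta <- theta
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
    if (rj$sse - nn_sse(wnew, Xtr, Ttr) < tol * max(rj$sse, 1)) break
  }
  list(weights = nn_unpack(best_theta, n_in, n_hidden, n_out),
       val_sse = best_val, epochs = length(history), val_history = history)
}

# BFGS fallback on the same objective (training loss), validation used only
# to select between the final and intermediate iterates is not available;
# the fitted weights are returned directly.
nn_train_bfgs <- function(w, Xtr, Ttr, Xval, Tval, max_epochs = 500) {
  n_in <- ncol(Xtr); n_hidden <- nrow(w$W1); n_out <- nrow(w$W2)
  fn <- function(theta) {
    nn_sse(nn_unpack(theta, n_in, n_hidden, n_out), Xtr, Ttr)
  }
  gr <- function(theta) {
    ww <- nn_unpack(theta, n_in, n_hidden, n_out)
    rj <- nn_residual_jacobian(ww, Xtr, Ttr)
    2 * as.vector(crossprod(rj$J, rj$r))
  }
  o <- stats::optim(nn_pack(w), fn, gr, method = "BFGS",
                    control = list(maxit = max_epochs, reltol = 1e-12))
  ww <- nn_unpack(o$par, n_in, n_hidden, n_out)
  list(weights = ww, val_sse = nn_sse(ww, Xval, Tval),
       epochs = o$counts[1], val_history = numeric(0))
}
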
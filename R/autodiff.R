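# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; each node holds its value, the
# ids of its parents and a backward closure mapping the output gradient to
# parent gradients. ad_backward() seeds the terminal (scalar) node with 1
# and sweeps the tape in reverse, accumulating gradients. This is the
# engine behind the dual-branch sequence networks; correctness is pinned
# by numerical gradient checks in the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 4096L)
  e$n <- 0L
  e
}

ad_push <- function(tape, value, parents = NULL, back = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node <- list(id = n, value = value,
               pids = if (is.null(parents)) integer(0)
                      else vapply(parents, `[[`, 0L, "id"),
               back = back)
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

ad_leaf <- function(tape, value) ad_push(tape, value)

ad_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in root$id:1) {
    g <- grads[[i]]
    node <- tape$nodes[[i]]
    if (is.null(g) || is.null(node$back)) next
    pg <- node$back(g)
    for (k in seq_along(node$pids)) {
      if (is.null(pg[[k]])) next
      pid <- node$pids[k]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]] else grads[[pid]] + pg[[k]]
    }
  }
  grads
}

ad_mm <- function(tape, a, b) {
  A <- a$value; B <- b$value
  ad_push(tape, A %*% B, list(a, b),
          function(g) list(g %*% t(B), t(A) %*% g))
}

# a %*% t(b)
ad_mm_nt <- function(tape, a, b) {
  A <- a$value; B <- b$value
  ad_push(tape, A %*% t(B), list(a, b),
          function(g) list(g %*% B, t(g) %*% A))
}

# elementwise add; b may be a 1-row bias broadcast over rows of a
ad_add <- function(tape, a, b) {
  A <- a$value; B <- b$value
  bias <- nrow(B) == 1L && nrow(A) > 1L
  val <- if (bias) A + rep(B, each = nrow(A)) else A + B
  ad_push(tape, val, list(a, b),
          function(g) list(g, if (bias) matrix(colSums(g), 1) else g))
}

ad_mul <- function(tape, a, b) {
  A <- a$value; B <- b$value
  ad_push(tape, A * B, list(a, b), function(g) list(g * B, g * A))
}

ad_scale <- function(tape, a, s) {
  ad_push(tape, a$value * s, list(a), function(g) list(g * s))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_push(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_push(tape, v, list(a), function(g) list(g * (1 - v^2)))
}

ad_relu <- function(tape, a) {
  v <- pmax(a$value, 0)
  m <- a$value > 0
  ad_push(tape, v, list(a), function(g) list(g * m))
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(x) ncol(x$value), 0L)
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  ad_push(tape, do.call(cbind, lapply(nodes, `[[`, "value")), nodes,
          function(g) {
            lapply(seq_along(nodes), function(k) {
              g[, starts[k]:ends[k], drop = FALSE]
            })
          })
}

ad_cols <- function(tape, a, idx) {
  nc <- ncol(a$value); nr <- nrow(a$value)
  ad_push(tape, a$value[, idx, drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, nr, nc)
            out[, idx] <- g
            list(out)
          })
}

# gather rows of a parameter/embedding matrix by (possibly repeated) index
ad_gather <- function(tape, a, idx) {
  V <- nrow(a$value); d <- ncol(a$value)
  ad_push(tape, a$value[idx, , drop = FALSE], list(a),
          function(g) {
            agg <- rowsum(g, group = idx)
            out <- matrix(0, V, d)
            out[as.integer(rownames(agg)), ] <- agg
            list(out)
          })
}

# tile a T-row matrix m times (positional embeddings for a flat batch)
ad_tile_rows <- function(tape, a, m) {
  Tlen <- nrow(a$value)
  idx <- rep(seq_len(Tlen), times = m)
  ad_push(tape, a$value[idx, , drop = FALSE], list(a),
          function(g) list(rowsum(g, group = idx)))
}

ad_dropout <- function(tape, a, p, train = TRUE) {
  if (!train || p <= 0) return(a)
  mask <- matrix((runif(length(a$value)) >= p) / (1 - p),
                 nrow(a$value), ncol(a$value))
  ad_push(tape, a$value * mask, list(a), function(g) list(g * mask))
}

ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  X <- x$value
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sdv <- sqrt(v + eps)
  xhat <- xc / sdv
  gamma_v <- gamma$value  # 1 x d
  val <- xhat * rep(gamma_v, each = nrow(X)) + rep(beta$value, each = nrow(X))
  ad_push(tape, val, list(x, gamma, beta),
          function(g) {
            gh <- g * rep(gamma_v, each = nrow(g))
            m1 <- rowMeans(gh)
            m2 <- rowMeans(gh * xhat)
            gx <- (gh - m1 - xhat * m2) / sdv
            list(gx, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
          })
}

# scaled-dot self-attention for a flat (m*T) x d batch; loops samples
# internally in both passes (single tape node). mask is an m x T 0/1
# matrix marking real tokens; padded keys are excluded and padded query
# rows zeroed.
ad_attention <- function(tape, q, k, v, m, Tlen, mask) {
  d <- ncol(q$value)
  scale <- 1 / sqrt(d)
  Q <- q$value; K <- k$value; V <- v$value
  O <- matrix(0, m * Tlen, d)
  A_list <- vector("list", m)
  for (i in seq_len(m)) {
    rows <- ((i - 1) * Tlen + 1):(i * Tlen)
    km <- mask[i, ]
    S <- (Q[rows, , drop = FALSE] %*% t(K[rows, , drop = FALSE])) * scale
    S <- S + rep((1 - km) * -1e9, each = Tlen)
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    A_list[[i]] <- A
    O[rows, ] <- (A %*% V[rows, , drop = FALSE]) * km
  }
  ad_push(tape, O, list(q, k, v),
          function(g) {
            gQ <- matrix(0, m * Tlen, d)
            gK <- gQ; gV <- gQ
            for (i in seq_len(m)) {
              rows <- ((i - 1) * Tlen + 1):(i * Tlen)
              km <- mask[i, ]
              A <- A_list[[i]]
              go <- g[rows, , drop = FALSE] * km
              gA <- go %*% t(V[rows, , drop = FALSE])
              gV[rows, ] <- t(A) %*% go
              gS <- (gA - rowSums(gA * A)) * A
              gQ[rows, ] <- (gS %*% K[rows, , drop = FALSE]) * scale
              gK[rows, ] <- (t(gS) %*% Q[rows, , drop = FALSE]) * scale
            }
            list(gQ, gK, gV)
          })
}

# reshape a flat (m*T) x d token matrix into m x (T*d) per-sample rows
ad_flatten_tokens <- function(tape, x, m, Tlen) {
  d <- ncol(x$value)
  val <- matrix(as.vector(t(x$value)), m, Tlen * d, byrow = TRUE)
  ad_push(tape, val, list(x),
          function(g) list(matrix(as.vector(t(g)), m * Tlen, d, byrow = TRUE)))
}

# mean binary cross-entropy over all entries, on logits (numerically
# stable softplus form); y is the 0/1 one-hot target matrix
ad_bce_logits <- function(tape, z, y) {
  Z <- z$value
  sp <- pmax(Z, 0) + log1p(exp(-abs(Z)))
  val <- matrix(mean(sp - Z * y), 1, 1)
  ad_push(tape, val, list(z),
          function(g) list(g[1] * (1 / (1 + exp(-Z)) - y) / length(Z)))
}

# mean categorical cross-entropy on logits (softmax form)
ad_ce_logits <- function(tape, z, y) {
  Z <- z$value
  zmax <- apply(Z, 1, max)
  lse <- zmax + log(rowSums(exp(Z - zmax)))
  val <- matrix(mean(lse - rowSums(Z * y)), 1, 1)
  sm <- exp(Z - lse)
  ad_push(tape, val, list(z),
          function(g) list(g[1] * (sm - y) / nrow(Z)))
}
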
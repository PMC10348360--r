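## Reverse-mode automatic differentiation over dense matrices.
##
## The encoder, the distance encoder and all four self-supervised losses are
## trained with gradients computed on a tape of matrix operations.  Nodes are
## environments (mutable gradient slots); the tape records creation order,
## which is a valid topological order for the backward sweep.  Only nodes
## reachable from a parameter accumulate gradients.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, parents = list(), back = NULL, req = NA) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$back <- back
  if (is.na(req)) {
    req <- FALSE
    for (p in parents) if (p$req) { req <- TRUE; break }
  }
  nd$req <- req
  nd$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_const <- function(tape, x) ad_node(tape, as_mat(x), req = FALSE)
ad_param <- function(tape, x) ad_node(tape, as_mat(x), req = TRUE)

as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

## accumulate gradient g into node nd (no-op for non-parameter subgraphs)
ad_acc <- function(nd, g) {
  if (!nd$req) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

## Backward sweep from a scalar (1x1) node.
ad_backward <- function(tape, node) {
  stopifnot(length(node$val) == 1L)
  node$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$back) && !is.null(nd$grad) && nd$req) nd$back(nd$grad)
  }
  invisible(NULL)
}

## ---- primitive operations ----

ad_mm <- function(x, y) {
  nd <- ad_node(tape_of(x, y), x$val %*% y$val, list(x, y))
  nd$back <- function(g) {
    ad_acc(x, g %*% t(y$val))
    ad_acc(y, t(x$val) %*% g)
  }
  nd
}

## all ops find the tape through an attribute-free global: we instead pass the
## tape implicitly by storing it on each node at creation time
tape_of <- function(...) {
  for (nd in list(...)) if (!is.null(nd$tape)) return(nd$tape)
  stop("no tape found")
}

ad_add <- function(x, y) {
  nd <- ad_node(tape_of(x, y), x$val + y$val, list(x, y))
  nd$back <- function(g) { ad_acc(x, g); ad_acc(y, g) }
  nd
}

ad_sub <- function(x, y) {
  nd <- ad_node(tape_of(x, y), x$val - y$val, list(x, y))
  nd$back <- function(g) { ad_acc(x, g); ad_acc(y, -g) }
  nd
}

## add a 1xk bias row to every row of an n x k matrix
ad_add_rowvec <- function(x, b) {
  v <- x$val
  nd <- ad_node(tape_of(x, b), v + matrix(b$val, nrow(v), ncol(v), byrow = TRUE), list(x, b))
  nd$back <- function(g) {
    ad_acc(x, g)
    ad_acc(b, matrix(colSums(g), 1L))
  }
  nd
}

ad_mul <- function(x, y) {
  nd <- ad_node(tape_of(x, y), x$val * y$val, list(x, y))
  nd$back <- function(g) { ad_acc(x, g * y$val); ad_acc(y, g * x$val) }
  nd
}

ad_scale <- function(x, k) {
  nd <- ad_node(tape_of(x), x$val * k, list(x))
  nd$back <- function(g) ad_acc(x, g * k)
  nd
}

## elementwise multiply by a constant matrix (masks, dropout)
ad_mul_const <- function(x, C) {
  nd <- ad_node(tape_of(x), x$val * C, list(x))
  nd$back <- function(g) ad_acc(x, g * C)
  nd
}

ad_add_const <- function(x, C) {
  nd <- ad_node(tape_of(x), x$val + C, list(x))
  nd$back <- function(g) ad_acc(x, g)
  nd
}

ad_t <- function(x) {
  nd <- ad_node(tape_of(x), t(x$val), list(x))
  nd$back <- function(g) ad_acc(x, t(g))
  nd
}

ad_relu <- function(x) {
  keep <- x$val > 0
  nd <- ad_node(tape_of(x), x$val * keep, list(x))
  nd$back <- function(g) ad_acc(x, g * keep)
  nd
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  nd <- ad_node(tape_of(x), s, list(x))
  nd$back <- function(g) ad_acc(x, g * s * (1 - s))
  nd
}

ad_exp <- function(x) {
  e <- exp(x$val)
  nd <- ad_node(tape_of(x), e, list(x))
  nd$back <- function(g) ad_acc(x, g * e)
  nd
}

ad_log <- function(x, eps = 1e-12) {
  v <- pmax(x$val, eps)
  nd <- ad_node(tape_of(x), log(v), list(x))
  nd$back <- function(g) ad_acc(x, g / v)
  nd
}

ad_sqrt <- function(x, eps = 1e-12) {
  s <- sqrt(pmax(x$val, eps))
  nd <- ad_node(tape_of(x), s, list(x))
  nd$back <- function(g) ad_acc(x, g / (2 * pmax(s, sqrt(eps))))
  nd
}

ad_square <- function(x) {
  nd <- ad_node(tape_of(x), x$val^2, list(x))
  nd$back <- function(g) ad_acc(x, 2 * g * x$val)
  nd
}

ad_sum <- function(x) {
  nd <- ad_node(tape_of(x), matrix(sum(x$val), 1L, 1L), list(x))
  nd$back <- function(g) ad_acc(x, matrix(g[1L], nrow(x$val), ncol(x$val)))
  nd
}

ad_mean <- function(x) {
  n <- length(x$val)
  nd <- ad_node(tape_of(x), matrix(mean(x$val), 1L, 1L), list(x))
  nd$back <- function(g) ad_acc(x, matrix(g[1L] / n, nrow(x$val), ncol(x$val)))
  nd
}

ad_rowsums <- function(x) {
  nd <- ad_node(tape_of(x), matrix(rowSums(x$val), ncol = 1L), list(x))
  nd$back <- function(g) ad_acc(x, matrix(g, nrow(x$val), ncol(x$val)))
  nd
}

## gather rows; backward scatter-adds
ad_rows <- function(x, idx) {
  nd <- ad_node(tape_of(x), x$val[idx, , drop = FALSE], list(x))
  nd$back <- function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    for (r in seq_along(idx)) gx[idx[r], ] <- gx[idx[r], ] + g[r, ]
    ad_acc(x, gx)
  }
  nd
}

ad_cols <- function(x, idx) {
  nd <- ad_node(tape_of(x), x$val[, idx, drop = FALSE], list(x))
  nd$back <- function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[, idx] <- g
    ad_acc(x, gx)
  }
  nd
}

ad_cbind <- function(x, y) {
  kx <- ncol(x$val)
  nd <- ad_node(tape_of(x, y), cbind(x$val, y$val), list(x, y))
  nd$back <- function(g) {
    ad_acc(x, g[, seq_len(kx), drop = FALSE])
    ad_acc(y, g[, -seq_len(kx), drop = FALSE])
  }
  nd
}

ad_div <- function(x, y, eps = 1e-12) {
  yv <- y$val
  yv[abs(yv) < eps] <- eps
  nd <- ad_node(tape_of(x, y), x$val / yv, list(x, y))
  nd$back <- function(g) {
    ad_acc(x, g / yv)
    ad_acc(y, -g * x$val / yv^2)
  }
  nd
}

ad_reshape <- function(x, nr, nc) {
  nr0 <- nrow(x$val); nc0 <- ncol(x$val)
  nd <- ad_node(tape_of(x), matrix(x$val, nr, nc), list(x))
  nd$back <- function(g) ad_acc(x, matrix(g, nr0, nc0))
  nd
}

## row-wise softmax with an optional 0/1 validity mask; fully masked rows -> 0
ad_rowsoftmax <- function(x, mask = NULL) {
  v <- x$val
  if (!is.null(mask)) v <- ifelse(mask > 0, v, -Inf)
  mx <- apply(v, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(v - mx)
  e[!is.finite(e)] <- 0
  rs <- rowSums(e)
  s <- e / ifelse(rs > 0, rs, 1)
  nd <- ad_node(tape_of(x), s, list(x))
  nd$back <- function(g) {
    dot <- rowSums(g * s)
    ad_acc(x, s * (g - dot))
  }
  nd
}

## row-wise layer normalization with learned gain/bias (1 x k each)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$val
  k <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gam <- matrix(gamma$val, nrow(v), k, byrow = TRUE)
  out <- xhat * gam + matrix(beta$val, nrow(v), k, byrow = TRUE)
  nd <- ad_node(tape_of(x, gamma, beta), out, list(x, gamma, beta))
  nd$back <- function(g) {
    ad_acc(gamma, matrix(colSums(g * xhat), 1L))
    ad_acc(beta, matrix(colSums(g), 1L))
    gx <- g * gam
    ## d/dx of (x - mu) * istd, standard layer-norm backward
    gv <- istd * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    ad_acc(x, gv)
  }
  nd
}

## row-wise 3-vector cross product on n x 3 matrices
ad_cross3 <- function(u, v) {
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nd <- ad_node(tape_of(u, v), cr(u$val, v$val), list(u, v))
  ## <g, du x v> = <v x g, du>;  <g, u x dv> = <g x u, dv>
  nd$back <- function(g) {
    ad_acc(u, cr(v$val, g))
    ad_acc(v, cr(g, u$val))
  }
  nd
}

ad_atan2 <- function(y, x) {
  nd <- ad_node(tape_of(y, x), atan2(y$val, x$val), list(y, x))
  nd$back <- function(g) {
    den <- y$val^2 + x$val^2
    den[den < 1e-18] <- 1e-18
    ad_acc(y, g * x$val / den)
    ad_acc(x, -g * y$val / den)
  }
  nd
}

## arc-cosine with clamping away from the branch points
ad_acos <- function(x, eps = 1e-7) {
  xc <- pmin(pmax(x$val, -1 + eps), 1 - eps)
  nd <- ad_node(tape_of(x), acos(xc), list(x))
  nd$back <- function(g) ad_acc(x, -g / sqrt(1 - xc^2))
  nd
}

## mean cross-entropy over rows of a logits matrix against integer labels
ad_cross_entropy <- function(logits, labels) {
  v <- logits$val
  m <- nrow(v)
  mx <- apply(v, 1L, max)
  e <- exp(v - mx)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(m), labels)]
  nd <- ad_node(tape_of(logits), matrix(-mean(log(pmax(picked, 1e-12))), 1L, 1L), list(logits))
  nd$back <- function(g) {
    gy <- p
    gy[cbind(seq_len(m), labels)] <- gy[cbind(seq_len(m), labels)] - 1
    ad_acc(logits, g[1L] * gy / m)
  }
  nd
}

## ---- parameter plumbing ----

## Wrap a named list of matrices as parameter nodes on a tape.
ad_wrap_params <- function(tape, params) {
  out <- lapply(params, function(w) ad_param(tape, w))
  out
}

## Collect gradients from wrapped parameter nodes (zero where unused).
ad_collect_grads <- function(pnodes) {
  lapply(pnodes, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad
  })
}
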
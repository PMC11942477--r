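# Minimal reverse-mode automatic differentiation over base-R matrices.
#
# Nodes are environments carrying a value, their parent nodes and a
# backward closure mapping the incoming gradient to per-parent gradients.
# The graph is rebuilt on every forward pass; ad_backward() topologically
# sorts it and accumulates gradients into the leaves.  Heavy inner loops
# (batched attention) live in C++; everything else is plain matrix algebra
# so each op's backward is a few lines and independently checkable against
# numerical differentiation.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_node <- function(value, parents = list(), backward = NULL,
                    param_name = NULL) {
  n <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1L
  n$id <- .ad$id
  n$value <- value
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  n$param_name <- param_name
  n$requires <- !is.null(param_name) ||
    any(vapply(parents, function(p) p$requires, logical(1)))
  class(n) <- "ad_node"
  n
}

nd <- function(x) if (inherits(x, "ad_node")) x else ad_node(x)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# ---- elementary ops -------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- nd(a); b <- nd(b)
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), crossprod(a$value, g))
  })
}

ad_add <- function(a, b) {
  a <- nd(a); b <- nd(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# x (N x C) + row-vector bias b (length C); rep() instead of sweep() since
# the latter routes through aperm and dominates profile time.
ad_add_bias <- function(x, b) {
  x <- nd(x); b <- nd(b)
  ad_node(x$value + rep(b$value, each = nrow(x$value)), list(x, b),
          function(g) list(g, colSums(g)))
}

ad_linear <- function(x, W, b = NULL) {
  out <- ad_matmul(x, W)
  if (is.null(b)) out else ad_add_bias(out, b)
}

ad_scale <- function(x, s) {
  x <- nd(x)
  ad_node(x$value * s, list(x), function(g) list(g * s))
}

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- nd(x); gamma <- nd(gamma); beta <- nd(beta)
  mu <- rowMeans(x$value)
  xc <- x$value - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(x$value)
  y <- xhat * rep(gamma$value, each = n) + rep(beta$value, each = n)
  ad_node(y, list(x, gamma, beta), function(g) {
    dxhat <- g * rep(gamma$value, each = n)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, colSums(g * xhat), colSums(g))
  })
}

ad_gelu <- function(x) {
  x <- nd(x)
  ph <- stats::pnorm(x$value)
  ad_node(x$value * ph, list(x), function(g) {
    list(g * (ph + x$value * stats::dnorm(x$value)))
  })
}

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

ad_selu <- function(x) {
  x <- nd(x)
  pos <- x$value > 0
  y <- ifelse(pos, SELU_LAMBDA * x$value,
              SELU_LAMBDA * SELU_ALPHA * (exp(pmin(x$value, 0)) - 1))
  dim(y) <- dim(x$value)
  ad_node(y, list(x), function(g) {
    d <- ifelse(pos, SELU_LAMBDA, y + SELU_LAMBDA * SELU_ALPHA)
    dim(d) <- dim(x$value)
    list(g * d)
  })
}

ad_sigmoid <- function(x) {
  x <- nd(x)
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_gather_rows <- function(x, idx) {
  x <- nd(x)
  ad_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(x$value), ncol(x$value))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

ad_slice_cols <- function(x, cols) {
  x <- nd(x)
  ad_node(x$value[, cols, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(x$value), ncol(x$value))
    out[, cols] <- g
    list(out)
  })
}

ad_concat_cols <- function(a, b) {
  a <- nd(a); b <- nd(b)
  na <- ncol(a$value)
  ad_node(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, nd)
  nr <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(nr)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(do.call(rbind, lapply(nodes, ad_value)), nodes, function(g) {
    lapply(seq_along(nodes), function(i)
      g[starts[i]:ends[i], , drop = FALSE])
  })
}

# Mean over row groups: rows of x sharing groups[i] are averaged.
ad_group_mean <- function(x, groups, ngroups) {
  x <- nd(x)
  counts <- tabulate(groups, nbins = ngroups)
  s <- rowsum(x$value, groups)
  m <- matrix(0, ngroups, ncol(x$value))
  m[as.integer(rownames(s)), ] <- s
  m <- m / pmax(counts, 1L)
  ad_node(m, list(x), function(g) {
    list(g[groups, , drop = FALSE] / counts[groups])
  })
}

ad_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(nd(x))
  x <- nd(x)
  keep <- (runif(length(x$value)) >= p) / (1 - p)
  dim(keep) <- dim(x$value)
  ad_node(x$value * keep, list(x), function(g) list(g * keep))
}

# ---- batched multi-head attention (C++ core) ------------------------------

# q: (B*nq) x C, k/v: (B*nk) x C, block-major rows; see src/attention.cpp.
# mask: optional nq x nk x nmask array of additive biases with mask_idx
# selecting one slice per block.  record: optional environment; when given,
# the attention cube is appended to record$attn under `name`.
ad_attention <- function(q, k, v, nq, nk, heads, mask = NULL,
                         mask_idx = NULL, record = NULL, name = NULL) {
  q <- nd(q); k <- nd(k); v <- nd(v)
  if (ncol(q$value) != ncol(k$value) || ncol(k$value) != ncol(v$value))
    stop("q, k, v must share the feature dimension")
  if (ncol(q$value) %% heads != 0)
    stop("feature dimension must be divisible by the head count")
  if (is.null(mask)) {
    mask <- array(0, c(0L, 0L, 0L))
    mask_idx <- integer(0)
  }
  fw <- attn_fwd_cpp(q$value, k$value, v$value, nq, nk, heads, mask, mask_idx,
                     want_A = !is.null(record))
  if (!is.null(record)) {
    record$attn <- c(record$attn, setNames(list(fw$A), name))
  }
  ad_node(fw$O, list(q, k, v), function(g) {
    bw <- attn_bwd_cpp(q$value, k$value, v$value, g, nq, nk, heads,
                       mask, mask_idx)
    list(bw$dQ, bw$dK, bw$dV)
  })
}

# ---- losses ---------------------------------------------------------------

# Multi-class cross-entropy on logits; target is an integer class vector.
ad_ce_logits <- function(logits, target) {
  logits <- nd(logits)
  z <- logits$value
  m <- apply(z, 1L, max)
  ez <- exp(z - m)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), target)], 1e-300)))
  node <- ad_node(loss, list(logits), function(g) {
    d <- p
    d[cbind(seq_len(n), target)] <- d[cbind(seq_len(n), target)] - 1
    list(g * d / n)
  })
  node$probs <- p
  node
}

# Binary cross-entropy on logits with optional positive-class weight.
ad_bce_logits <- function(logits, target, pos_weight = 1) {
  logits <- nd(logits)
  z <- as.vector(logits$value)
  t <- as.vector(target)
  p <- 1 / (1 + exp(-z))
  softplus <- function(u) ifelse(u > 30, u, log1p(exp(u)))
  l <- pos_weight * t * softplus(-z) + (1 - t) * softplus(z)
  n <- length(z)
  node <- ad_node(sum(l) / n, list(logits), function(g) {
    d <- pos_weight * t * (p - 1) + (1 - t) * p
    list(matrix(g * d / n, nrow(logits$value), ncol(logits$value)))
  })
  node$probs <- p
  node
}

# ---- backward pass --------------------------------------------------------

ad_backward <- function(loss) {
  # iterative topological sort (post-order DFS)
  topo <- vector("list", 256L)
  nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- fr$node
    key <- as.character(n$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = n, stage = 2L)
      for (p in n$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- n
    }
  }
  loss$grad <- if (is.matrix(loss$value))
    array(1, dim(loss$value)) else 1
  for (i in rev(seq_len(nt))) {
    n <- topo[[i]]
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (!p$requires || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (is.null(n$param_name)) n$grad <- NULL  # free intermediates
  }
  invisible(loss)
}
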
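# Reverse-mode automatic differentiation on a dynamic tape.
#
# Every operation returns a node holding its eagerly computed value plus, for
# each parent that requires gradients, a backward closure. Backward closures
# are written in terms of the same tape operations, so the output of
# dst_grad() is itself differentiable: the second-order gradients needed by
# the Wasserstein gradient penalty fall out of a second dst_grad() call.
#
# Values are plain numeric vectors/matrices/arrays (column-major). Images are
# carried channels-first as (C, H, W, N) arrays so convolution lowers to one
# BLAS matrix product via im2col.

dsenv <- new.env(parent = emptyenv())
dsenv$counter <- 0L

# Nodes are environments: reference semantics keep graph traversal and the
# work stack in dst_grad() free of R's copy-on-share duplication of values.
new_node <- function(value, parents = list(), pbw = list()) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  rg <- FALSE
  for (p in parents) if (p$rg) { rg <- TRUE; break }
  e$rg <- rg
  # constants need no history: prune so constant subgraphs stay O(1)
  e$parents <- if (rg) parents else list()
  e$pbw <- if (rg) pbw else list()
  e$id <- (dsenv$counter <- dsenv$counter + 1L)
  class(e) <- "dstensor"
  e
}

#' @export
print.dstensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<dstensor", if (is.null(d)) paste0("len ", length(x$value)) else
    paste(d, collapse = "x"),
    if (x$rg) "(grad)" else "(const)", ">\n")
  invisible(x)
}

dconst <- function(v) new_node(v)

dparam <- function(v) {
  e <- new_node(v)
  e$rg <- TRUE
  e
}

# a %*% t(b), and t(a) %*% b, as primitives: the backward pass of matrix
# multiplication avoids materializing explicit transposes
d_tcrossprod <- function(a, b) {
  new_node(tcrossprod(a$value, b$value), list(a, b),
           list(function(g) d_matmul(g, b),
                function(g) d_crossprod(g, a)))
}

d_crossprod <- function(a, b) {
  new_node(crossprod(a$value, b$value), list(a, b),
           list(function(g) d_tcrossprod(b, g),
                function(g) d_matmul(a, g)))
}

dval <- function(x) x$value

ddetach <- function(x) dconst(x$value)

.fill_like <- function(v, fill) {
  d <- dim(v)
  if (is.null(d)) rep(fill, length(v)) else array(fill, d)
}

# ---- arithmetic -----------------------------------------------------------

d_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b),
           list(function(g) g, function(g) g))
}

d_sub <- function(a, b) {
  new_node(a$value - b$value, list(a, b),
           list(function(g) g, function(g) d_neg(g)))
}

d_mul <- function(a, b) {
  new_node(a$value * b$value, list(a, b),
           list(function(g) d_mul(g, b), function(g) d_mul(g, a)))
}

d_scale <- function(a, k) {
  new_node(a$value * k, list(a), list(function(g) d_scale(g, k)))
}

d_neg <- function(a) d_scale(a, -1)

d_shift <- function(a, k) {
  new_node(a$value + k, list(a), list(function(g) g))
}

d_square <- function(a) d_mul(a, a)

d_matmul <- function(a, b) {
  new_node(a$value %*% b$value, list(a, b),
           list(function(g) d_tcrossprod(g, b),
                function(g) d_crossprod(a, g)))
}

d_t <- function(a) {
  new_node(t(a$value), list(a), list(function(g) d_t(g)))
}

# ---- reductions / broadcasting -------------------------------------------

d_sum <- function(a) {
  dm <- dim(a$value)
  len <- length(a$value)
  new_node(sum(a$value), list(a),
           list(function(g) d_bfill(g, dm, len)))
}

# broadcast a scalar node to a full shape (adjoint of d_sum)
d_bfill <- function(s, dm, len) {
  v <- if (is.null(dm)) rep(s$value, len) else array(s$value, dm)
  new_node(v, list(s), list(function(g) d_sum(g)))
}

d_mean <- function(a) d_scale(d_sum(a), 1 / length(a$value))

# ---- nonlinearities -------------------------------------------------------

d_relu <- function(a) {
  mask <- (a$value > 0) * 1
  d_maskmul(a, mask)
}

d_lrelu <- function(a, slope = 0.01) {
  fac <- slope + (1 - slope) * (a$value > 0)
  d_maskmul(a, fac)
}

# elementwise product with a constant (non-differentiated) factor
d_maskmul <- function(a, m) {
  new_node(a$value * m, list(a), list(function(g) d_maskmul(g, m)))
}

d_abs <- function(a) {
  d_maskmul(a, sign(a$value))
}

d_tanh <- function(a) {
  n <- new_node(tanh(a$value), list(a), list(NULL))
  if (n$rg) n$pbw[[1]] <- function(g) d_mul(g, d_shift(d_neg(d_square(n)), 1))
  n
}

d_exp <- function(a) {
  n <- new_node(exp(a$value), list(a), list(NULL))
  if (n$rg) n$pbw[[1]] <- function(g) d_mul(g, n)
  n
}

d_recip <- function(a) {
  n <- new_node(1 / a$value, list(a), list(NULL))
  if (n$rg) n$pbw[[1]] <- function(g) d_neg(d_mul(g, d_square(n)))
  n
}

d_log <- function(a) {
  new_node(log(a$value), list(a), list(function(g) d_mul(g, d_recip(a))))
}

d_sqrt <- function(a) {
  n <- new_node(sqrt(a$value), list(a), list(NULL))
  if (n$rg) n$pbw[[1]] <- function(g) d_scale(d_mul(g, d_recip(n)), 0.5)
  n
}

# ---- shape ops ------------------------------------------------------------

d_reshape <- function(a, dm) {
  orig <- dim(a$value)
  len <- length(a$value)
  v <- a$value
  dim(v) <- dm
  new_node(v, list(a), list(function(g) d_reshape(g, orig %||% len)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- convolution lowering --------------------------------------------------

d_im2col <- function(a, C, H, W, N, k, stride, pad) {
  new_node(cpp_im2col(a$value, C, H, W, N, k, stride, pad), list(a),
           list(function(g) d_col2im(g, C, H, W, N, k, stride, pad)))
}

d_col2im <- function(a, C, H, W, N, k, stride, pad) {
  new_node(cpp_col2im(a$value, C, H, W, N, k, stride, pad), list(a),
           list(function(g) d_im2col(g, C, H, W, N, k, stride, pad)))
}

# ---- pooling ---------------------------------------------------------------

d_maxpool2 <- function(a) {
  dm <- dim(a$value)
  r <- cpp_maxpool2(a$value, dm[1], dm[2], dm[3], dm[4])
  idx <- r$idx
  new_node(r$value, list(a),
           list(function(g) d_scatter(g, idx, length(a$value), dm)))
}

d_scatter <- function(a, idx, len, dm) {
  v <- numeric(len)
  v[idx] <- a$value
  dim(v) <- dm
  pooled_dm <- dim(a$value)
  new_node(v, list(a), list(function(g) d_gather(g, idx, pooled_dm)))
}

d_gather <- function(a, idx, dm) {
  orig_len <- length(a$value)
  orig_dm <- dim(a$value)
  v <- a$value[idx]
  dim(v) <- dm
  new_node(v, list(a),
           list(function(g) d_scatter(g, idx, orig_len, orig_dm)))
}

# ---- channel concatenation / slicing (dim 1 of (C,H,W,N) arrays) -----------

d_cat1 <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  ia <- seq_len(da[1]); ib <- da[1] + seq_len(db[1])
  v[ia, , , ] <- a$value
  v[ib, , , ] <- b$value
  new_node(v, list(a, b),
           list(function(g) d_slice1(g, ia), function(g) d_slice1(g, ib)))
}

d_slice1 <- function(a, idx) {
  dm <- dim(a$value)
  v <- a$value[idx, , , , drop = FALSE]
  new_node(v, list(a), list(function(g) d_embed1(g, idx, dm)))
}

d_embed1 <- function(a, idx, dm) {
  v <- array(0, dm)
  v[idx, , , ] <- a$value
  keep <- idx
  new_node(v, list(a), list(function(g) d_slice1(g, keep)))
}

# ---- sample slicing (dim 4 of (C,H,W,N) arrays) -----------------------------

d_slice4 <- function(a, idx) {
  dm <- dim(a$value)
  v <- a$value[, , , idx, drop = FALSE]
  new_node(v, list(a), list(function(g) d_embed4(g, idx, dm)))
}

d_embed4 <- function(a, idx, dm) {
  v <- array(0, dm)
  v[, , , idx] <- a$value
  keep <- idx
  new_node(v, list(a), list(function(g) d_slice4(g, keep)))
}

# ---- gradient --------------------------------------------------------------

#' Reverse-mode gradient of a tape node.
#'
#' Traverses the tape from `out` and returns one gradient node per entry of
#' `wrt`. The returned nodes carry their own history, so they can be fed into
#' further tape operations and differentiated again (used by the gradient
#' penalty).
#'
#' @param out scalar (or seeded) output node.
#' @param wrt list of nodes to differentiate with respect to.
#' @param seed optional seed node matching `out`'s shape; defaults to ones.
#' @return list of gradient nodes aligned with `wrt`.
#' @keywords internal
dst_grad <- function(out, wrt, seed = NULL) {
  stopifnot(inherits(out, "dstensor"))
  # post-order DFS over the requires-grad subgraph
  order <- vector("list", 512L); no <- 0L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  snode <- vector("list", 512L); sidx <- integer(512L); top <- 0L
  push <- function(n) {
    top <<- top + 1L
    if (top > length(snode)) { length(snode) <<- 2L * top; length(sidx) <<- 2L * top }
    snode[[top]] <<- n; sidx[top] <<- 1L
  }
  if (out$rg) {
    push(out)
    assign(as.character(out$id), TRUE, envir = visited)
  }
  while (top > 0L) {
    n <- snode[[top]]
    i <- sidx[top]
    ps <- n$parents
    advanced <- FALSE
    while (i <= length(ps)) {
      p <- ps[[i]]
      i <- i + 1L
      if (p$rg && is.null(visited[[as.character(p$id)]])) {
        sidx[top] <- i
        assign(as.character(p$id), TRUE, envir = visited)
        push(p)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      no <- no + 1L
      if (no > length(order)) length(order) <- 2L * no
      order[[no]] <- n
      top <- top - 1L
    }
  }
  gtab <- new.env(hash = TRUE, parent = emptyenv())
  if (is.null(seed)) seed <- dconst(.fill_like(out$value, 1))
  assign(as.character(out$id), seed, envir = gtab)
  if (no > 0L) for (j in seq(no, 1L)) {
    n <- order[[j]]
    g <- gtab[[as.character(n$id)]]
    if (is.null(g)) next
    ps <- n$parents
    bw <- n$pbw
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!p$rg) next
      fk <- if (k <= length(bw)) bw[[k]] else NULL
      if (is.null(fk)) next
      pg <- fk(g)
      key <- as.character(p$id)
      cur <- gtab[[key]]
      assign(key, if (is.null(cur)) pg else d_add(cur, pg), envir = gtab)
    }
  }
  lapply(wrt, function(w) {
    g <- gtab[[as.character(w$id)]]
    if (is.null(g)) dconst(.fill_like(w$value, 0)) else g
  })
}
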
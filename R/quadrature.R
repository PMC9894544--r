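# Quadrature utilities shared by the growth-model integrals.

.quad_cache <- new.env(parent = emptyenv())

#' Gauss-Legendre nodes and weights on the interval from -1 to 1
#'
#' Golub-Welsch eigenvalue construction on the Jacobi matrix of the Legendre
#' recurrence. Nodes/weights are cached per order.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, each length `n`.
#' @keywords internal
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  stopifnot(n >= 1)
  if (n == 1L) {
    gl <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    gl <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
  }
  assign(key, gl, envir = .quad_cache)
  gl
}

# Rescale cached [-1,1] rule to [a, b] (a, b may be vectors of equal length;
# returns matrices n_intervals x n_nodes).
gl_rescale <- function(a, b, n = 64L) {
  gl <- gauss_legendre(n)
  half <- (b - a) / 2
  mid <- (a + b) / 2
  list(
    x = outer(half, gl$nodes) + mid,
    w = outer(half, gl$weights)
  )
}

# Cumulative Simpson integral of y sampled on a uniform grid x.
# Returns F with F[1] = 0, F[i] = integral from x[1] to x[i].
# Odd panels are closed with a local 3-point Newton-Cotes correction so the
# result is O(h^4) at every grid point, not only even ones.
cum_simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  h <- x[2] - x[1]
  out <- numeric(n)
  # Simpson over pairs of panels
  idx <- seq(3, n, by = 2)
  inc2 <- h / 3 * (y[idx - 2] + 4 * y[idx - 1] + y[idx])
  out[idx] <- cumsum(inc2)
  # odd points: integral to x[i] = integral to x[i-1] (even) + correction
  # using the quadratic through (i-1, i, i+1) when available, else (i-2,i-1,i)
  odd <- seq(2, n, by = 2)
  for (i in odd) {
    if (i + 1 <= n) {
      out[i] <- out[i - 1] + h / 12 * (5 * y[i - 1] + 8 * y[i] - y[i + 1])
    } else {
      out[i] <- out[i - 1] + h / 12 * (-y[i - 2] + 8 * y[i - 1] + 5 * y[i])
    }
  }
  out
}
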
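#' Staging transformation of path-integral bead coordinates
#'
#' Maps bead positions `x_1..x_P` (cyclic, `x_{P+1} = x_1`) to staging
#' variables that diagonalise the harmonic spring term of the discretised
#' path: `u_1 = x_1` and `u_k = x_k - ((k-1) x_{k+1} + x_1)/k` for
#' `k = 2..P`. [inverse_staging()] recovers the beads; the round trip is an
#' identity to machine precision.
#'
#' @param x numeric vector of P bead positions, or a `P x d` matrix
#'   (one column per Cartesian degree of freedom).
#' @return staging coordinates with the same shape.
#' @examples
#' u <- staging_transform(c(0.1, 0.2, 0.3, 0.4))
#' inverse_staging(u)
#' @export
staging_transform <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, staging_transform))
  P <- length(x)
  if (P < 1) stop("shape error: need at least one bead")
  if (P == 1) return(x)
  u <- numeric(P)
  u[1] <- x[1]
  xn <- c(x[-1], x[1])                       # x_{k+1}, cyclic
  k <- 2:P
  u[k] <- x[k] - ((k - 1) * xn[k] + x[1]) / k
  u
}

#' @rdname staging_transform
#' @param u staging coordinates as returned by [staging_transform()].
#' @export
inverse_staging <- function(u) {
  if (is.matrix(u)) return(apply(u, 2, inverse_staging))
  P <- length(u)
  if (P < 1) stop("shape error: need at least one bead")
  if (P == 1) return(u)
  x <- numeric(P)
  x[1] <- u[1]
  x[P] <- u[P] + u[1]                         # x_{P+1} = x_1
  if (P > 2)
    for (k in (P - 1):2)
      x[k] <- u[k] + (k - 1) / k * x[k + 1] + u[1] / k
  x
}
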
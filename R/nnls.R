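#' Non-negative least squares by the Lawson–Hanson active-set method
#'
#' Solves \eqn{\min_{x \ge 0} \|Ax - b\|_2}. The active-set iteration adds
#' the variable with the largest positive dual (gradient) to the passive set,
#' solves the unconstrained subproblem on the passive set by QR, and steps
#' back to the feasible boundary when a passive coefficient would go
#' negative. Finite termination holds for any full-column-rank `A`; a
#' generous global iteration guard protects against numerically degenerate
#' cycling.
#'
#' @param A Numeric matrix (m x n, m >= n).
#' @param b Numeric vector of length m.
#' @return List with `x` (the nonnegative solution), `resid` (b - Ax) and
#'   `deviance` (residual sum of squares).
#' @export
nnls_solve <- function(A, b) {
  stopifnot(is.matrix(A), is.numeric(A), is.numeric(b),
            nrow(A) == length(b))
  n <- ncol(A)
  tol <- 10 * .Machine$double.eps * max(svd(A, nu = 0, nv = 0)$d) *
    (max(dim(A)) + 1)
  x <- numeric(n)
  passive <- logical(n)
  banned <- logical(n)  # vars whose entry made no progress at the current x
  w <- drop(crossprod(A, b))            # dual at x = 0
  max_outer <- 30L * n + 100L
  outer <- 0L
  while (any(!passive & !banned) && any(w[!passive & !banned] > tol)) {
    outer <- outer + 1L
    if (outer > max_outer) {
      stop("nnls_solve failed to converge (degenerate design matrix?)",
           call. = FALSE)
    }
    cand <- which(!passive & !banned)
    im <- cand[which.max(w[cand])]
    passive[im] <- TRUE
    z <- numeric(n)
    z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
    if (z[im] <= tol) {
      # numerically degenerate entry (dual barely positive, e.g. an exact
      # fit): adding it cannot improve the solution at the current x
      passive[im] <- FALSE
      banned[im] <- TRUE
      next
    }
    inner <- 0L
    while (any(z[passive] <= tol)) {
      inner <- inner + 1L
      if (inner > max_outer) {
        stop("nnls_solve failed to converge (inner loop)", call. = FALSE)
      }
      q <- passive & (z <= tol)
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
    }
    x <- z
    banned[] <- FALSE  # solution moved; previously banned vars may re-enter
    w <- drop(crossprod(A, b - A %*% x))
  }
  x[x < 0] <- 0
  r <- b - drop(A %*% x)
  list(x = x, resid = r, deviance = sum(r^2))
}
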
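#' Flipped Legendre-Gauss-Radau collocation nodes and quadrature weights
#'
#' Returns the `d` flipped LGR (Radau IIA) points on the half-open interval
#' (0, 1], i.e. the abscissae that include the right endpoint, together with
#' the associated quadrature weights. The scheme integrates polynomials up to
#' degree `2d - 2` exactly and its weights sum to one.
#'
#' @param d collocation order (number of nodes), an integer >= 1.
#' @return list with `nodes` (strictly increasing, last element 1) and
#'   `weights` (positive, summing to 1).
#' @examples
#' lgr_nodes(3)
#' @export
lgr_nodes <- function(d) {
  if (length(d) != 1L || !is.finite(d) || d < 1 || d != round(d)) {
    stop("collocation order 'd' must be an integer >= 1")
  }
  d <- as.integer(d)
  if (d == 1L) {
    return(list(nodes = 1, weights = 1))
  }
  # Flipped Radau abscissae on [-1, 1] are the roots of P_{d-1}(x) - P_d(x),
  # which include x = 1 (mirror image of the left-Radau roots of P_{d-1}+P_d).
  p_prev <- legendre_coef(d - 1L)
  p_d <- legendre_coef(d)
  coef <- c(p_prev, 0) - p_d # ascending powers, degree d
  roots <- polyroot(coef)
  x <- sort(Re(roots[abs(Im(roots)) < 1e-9]))
  x <- polish_poly_roots(coef, x)
  x[length(x)] <- 1
  nodes <- (x + 1) / 2
  # Weights from moment matching: exactness for monomials of degree < d is
  # sufficient to pin down the d weights (the rule is then exact to 2d-2).
  V <- t(vapply(seq_len(d) - 1L, function(k) nodes^k, numeric(d)))
  m <- 1 / seq_len(d)
  w <- solve(V, m)
  list(nodes = nodes, weights = w)
}

# Coefficients (ascending powers of x) of the Legendre polynomial P_n via
# Bonnet's recursion.
legendre_coef <- function(n) {
  if (n == 0L) return(1)
  if (n == 1L) return(c(0, 1))
  pm2 <- 1
  pm1 <- c(0, 1)
  for (k in 2:n) {
    a <- (2 * k - 1) / k
    b <- (k - 1) / k
    p <- a * c(0, pm1) - b * c(pm2, 0, 0)[seq_len(k + 1)]
    pm2 <- pm1
    pm1 <- p
  }
  pm1
}

# A few Newton steps to polish roots obtained from polyroot().
polish_poly_roots <- function(coef, x) {
  dcoef <- coef[-1] * seq_len(length(coef) - 1L)
  for (i in seq_along(x)) {
    for (it in 1:6) {
      f <- sum(coef * x[i]^(seq_along(coef) - 1L))
      fp <- sum(dcoef * x[i]^(seq_along(dcoef) - 1L))
      if (abs(fp) < .Machine$double.eps) break
      x[i] <- x[i] - f / fp
    }
  }
  x
}

#' Lagrange differentiation matrix
#'
#' Given a set of distinct interpolation nodes (for collocation: the interval
#' start 0 followed by the flipped LGR points), returns the matrix `D` such
#' that for values `y` of a polynomial at `nodes`, `D %*% y` gives its exact
#' derivative at `at` (default: all nodes except the first, i.e. the LGR
#' points). Differentiation is exact for polynomials up to degree
#' `length(nodes) - 1`.
#'
#' @param nodes distinct interpolation nodes.
#' @param at points at which the derivative is evaluated; defaults to
#'   `nodes[-1]`.
#' @return numeric matrix of dimension `length(at)` by `length(nodes)`.
#' @export
lagrange_differentiation <- function(nodes, at = nodes[-1]) {
  n <- length(nodes)
  if (n < 2L) stop("need at least two nodes")
  if (min(diff(sort(nodes))) < 1e-12) stop("nodes must be distinct")
  # Barycentric weights
  wb <- vapply(seq_len(n), function(j) {
    1 / prod(nodes[j] - nodes[-j])
  }, numeric(1))
  D <- matrix(0, length(at), n)
  for (ii in seq_along(at)) {
    t0 <- at[ii]
    j0 <- which(abs(nodes - t0) < 1e-13)
    if (length(j0) == 1L) {
      # derivative of the Lagrange basis at one of the nodes
      for (j in seq_len(n)) {
        if (j == j0) next
        D[ii, j] <- (wb[j] / wb[j0]) / (t0 - nodes[j])
      }
      D[ii, j0] <- -sum(D[ii, -j0])
    } else {
      # generic point: differentiate the barycentric form
      diffs <- t0 - nodes
      l <- prod(diffs)
      lj <- l / diffs
      dlj <- vapply(seq_len(n), function(j) {
        sum(lj[j] / diffs[-j])
      }, numeric(1))
      D[ii, ] <- wb * dlj
    }
  }
  D
}
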
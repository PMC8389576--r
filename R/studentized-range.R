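# Studentized range distribution, needed by both the Tukey HSD and the
# Duncan multiple range test. The CDF is evaluated by Gauss-Legendre
# quadrature of
#   P(Q <= q) = E_s[ P(range of k std normals <= q s) ],
# where s = sqrt(chi2_df / df) is integrated in its probability scale
# (s = sqrt(qchisq(p, df)/df), p in (0,1)), and the inner normal-range CDF
#   P(W <= w) = k Int phi(z) [Phi(z) - Phi(z - w)]^(k-1) dz
# is integrated over z in [-9, 9]. The quantile inverts the CDF by
# root-finding, so quantile(cdf(q)) = q to the root tolerance.

gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: nodes/weights from the Jacobi matrix of Legendre polys
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# cached quadrature rules (fixed sizes, reused across calls)
.sr_env <- new.env(parent = emptyenv())

sr_rules <- function() {
  if (is.null(.sr_env$inner)) {
    .sr_env$inner <- gauss_legendre(100, -9, 9)
    .sr_env$outer <- gauss_legendre(160, 0, 1)
  }
  list(inner = .sr_env$inner, outer = .sr_env$outer)
}

# CDF of the range of k standard normals, vectorized over w via one
# matrix-shaped pnorm evaluation (length(w) x nodes)
normal_range_cdf <- function(w, k, rule) {
  z <- rule$nodes
  phi_z <- dnorm(z) * rule$weights
  Phi_z <- pnorm(z)
  v <- pmax(rep(Phi_z, each = length(w)) -
              pnorm(outer(-w, z, `+`)), 0)
  dim(v) <- c(length(w), length(z))
  out <- pmin(1, k * as.vector(v^(k - 1) %*% phi_z))
  out[w <= 0] <- 0
  out
}

#' Studentized range distribution
#'
#' `studentized_range_cdf()` evaluates P(Q <= q) for the studentized range
#' of `k` group means with `df` residual degrees of freedom, by numerical
#' integration; `studentized_range_quantile()` inverts it by root-finding,
#' so the round-trip `quantile(cdf(q)) = q` holds to about 1e-8. For
#' `k = 2` the distribution reduces to that of sqrt(2) |t_df|.
#'
#' @param q observed studentized range, > 0.
#' @param k number of groups, >= 2.
#' @param df residual degrees of freedom, >= 1.
#' @param p probability in (0, 1).
#' @return A probability (`_cdf`) or a quantile (`_quantile`).
#' @export
studentized_range_cdf <- function(q, k, df) {
  check_number(k, "k", lower = 2)
  check_number(df, "df", lower = 1)
  check_number(q, "q")
  if (q <= 0) return(0)
  r <- sr_rules()
  s <- sqrt(qchisq(r$outer$nodes, df) / df)
  vals <- normal_range_cdf(q * s, k, r$inner)
  min(1, max(0, sum(r$outer$weights * vals)))
}

#' @rdname studentized_range_cdf
#' @export
studentized_range_quantile <- function(p, k, df) {
  check_number(p, "p", lower = 1e-12, upper = 1 - 1e-12)
  key <- sprintf("q|%.12g|%g|%g", p, k, df)
  hit <- .sr_env[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(q) studentized_range_cdf(q, k, df) - p
  hi <- 4
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) {
      pk_stop("studentized range quantile search failed to bracket the root",
              "pamkit_numerical_error")
    }
  }
  out <- tryCatch(
    uniroot(f, c(1e-10, hi), tol = 1e-10)$root,
    error = function(e) {
      pk_stop(sprintf("studentized range quantile did not converge (p=%g, k=%g, df=%g): %s",
                      p, k, df, conditionMessage(e)),
              "pamkit_numerical_error")
    }
  )
  assign(key, out, envir = .sr_env)
  out
}
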
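# Vectorised small-matrix kernels used by the Gibbs sampler and the cut
# posterior.  All operate on parallel vectors holding the unique entries of
# many symmetric 2x2 or 3x3 matrices at once, so that per-subject (or
# per-draw) conditional updates never loop in R.

# Draw from N(mean, V) where V = P^{-1} and P is a batch of symmetric 2x2
# precisions given by vectors (p11, p12, p22); h is the linear term P*mean.
# Returns cbind(b1, b2).
.mvn2_sample <- function(p11, p12, p22, h1, h2, z1, z2) {
  det <- p11 * p22 - p12 * p12
  v11 <- p22 / det
  v12 <- -p12 / det
  v22 <- p11 / det
  m1 <- v11 * h1 + v12 * h2
  m2 <- v12 * h1 + v22 * h2
  l11 <- sqrt(pmax(v11, 1e-300))
  l21 <- v12 / l11
  l22 <- sqrt(pmax(v22 - l21 * l21, 1e-300))
  cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2)
}

# Same for batches of symmetric 3x3 precisions; entries (p11,p12,p13,p22,p23,p33).
.mvn3_sample <- function(p11, p12, p13, p22, p23, p33, h1, h2, h3, z1, z2, z3) {
  # inverse via adjugate
  c11 <- p22 * p33 - p23 * p23
  c12 <- p13 * p23 - p12 * p33
  c13 <- p12 * p23 - p13 * p22
  det <- p11 * c11 + p12 * c12 + p13 * c13
  v11 <- c11 / det
  v12 <- c12 / det
  v13 <- c13 / det
  v22 <- (p11 * p33 - p13 * p13) / det
  v23 <- (p13 * p12 - p11 * p23) / det
  v33 <- (p11 * p22 - p12 * p12) / det
  m1 <- v11 * h1 + v12 * h2 + v13 * h3
  m2 <- v12 * h1 + v22 * h2 + v23 * h3
  m3 <- v13 * h1 + v23 * h2 + v33 * h3
  l11 <- sqrt(pmax(v11, 1e-300))
  l21 <- v12 / l11
  l31 <- v13 / l11
  l22 <- sqrt(pmax(v22 - l21 * l21, 1e-300))
  l32 <- (v23 - l21 * l31) / l22
  l33 <- sqrt(pmax(v33 - l31 * l31 - l32 * l32, 1e-300))
  cbind(m1 + l11 * z1,
        m2 + l21 * z1 + l22 * z2,
        m3 + l31 * z1 + l32 * z2 + l33 * z3)
}

# Unique entries of the inverse of batches of symmetric 2x2 covariances.
.inv2 <- function(s11, s12, s22) {
  det <- s11 * s22 - s12 * s12
  list(i11 = s22 / det, i12 = -s12 / det, i22 = s11 / det)
}

# Unique entries of the inverse of batches of symmetric 3x3 covariances.
.inv3 <- function(s11, s12, s13, s22, s23, s33) {
  c11 <- s22 * s33 - s23 * s23
  c12 <- s13 * s23 - s12 * s33
  c13 <- s12 * s23 - s13 * s22
  det <- s11 * c11 + s12 * c12 + s13 * c13
  list(i11 = c11 / det,
       i12 = c12 / det,
       i13 = c13 / det,
       i22 = (s11 * s33 - s13 * s13) / det,
       i23 = (s13 * s12 - s11 * s23) / det,
       i33 = (s11 * s22 - s12 * s12) / det)
}

# One multivariate-normal draw per row of `mean` with common covariance Sigma.
.rmvnorm <- function(n, mean, Sigma) {
  d <- ncol(Sigma)
  L <- chol(Sigma)
  z <- matrix(rnorm(n * d), n, d)
  mean + z %*% L
}

# Inverse-Wishart draw: Sigma ~ IW(df, S)  <=>  Sigma^{-1} ~ Wishart(df, S^{-1}).
.rinvwishart <- function(df, S) {
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  solve(W)
}

# Draws from N(mean, sd^2) truncated to (-Inf, upper]; numerically robust in
# the far tail via log-scale inverse-CDF sampling.
.rtnorm_upper <- function(n, mean, sd, upper) {
  z <- (upper - mean) / sd
  lp <- pnorm(z, log.p = TRUE)
  u <- runif(n)
  mean + sd * qnorm(log(u) + lp, log.p = TRUE)
}

# Draws from N(mean, sd^2) truncated to [lower, upper].
.rtnorm_range <- function(n, mean, sd, lower, upper) {
  pl <- pnorm((lower - mean) / sd)
  pu <- pnorm((upper - mean) / sd)
  u <- pl + runif(n) * (pu - pl)
  # guard the degenerate case pu == pl
  u <- pmin(pmax(u, 1e-300), 1 - 1e-16)
  mean + sd * qnorm(u)
}

# Assemble a correlation-parameterised covariance matrix from SDs and the
# lower-triangle correlations (rho01[, rho02, rho12]); checks positive
# definiteness.
.make_sigma <- function(sds, rhos) {
  d <- length(sds)
  R <- diag(d)
  if (d == 2L) {
    R[1, 2] <- R[2, 1] <- rhos[1]
  } else if (d == 3L) {
    R[1, 2] <- R[2, 1] <- rhos[1]
    R[1, 3] <- R[3, 1] <- rhos[2]
    R[2, 3] <- R[3, 2] <- rhos[3]
  }
  Sigma <- diag(sds, d) %*% R %*% diag(sds, d)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("random-effect covariance is not positive definite", call. = FALSE)
  }
  Sigma
}

# Simple deterministic 32-bit FNV-1a hash of a character scalar, returned as
# hex; used for config fingerprints in run manifests.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
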
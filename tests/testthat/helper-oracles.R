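# Independent numerical oracles used to check closed-form predictions.

# First time >= t at which the curve A + B u + C u^2 reaches alpha, found by
# coarse grid bracketing followed by bisection; Inf when no crossing occurs
# within `horizon` years.  Deliberately independent of the quadratic-formula
# path it is used to check.
oracle_time_to_threshold <- function(A, B, C, t, alpha,
                                     horizon = 400, step = 0.5) {
  level <- function(u) A + B * u + C * u * u
  if (level(t) >= alpha) return(0)
  grid <- seq(t, t + horizon, by = step)
  above <- level(grid) >= alpha
  k <- which(above)[1]
  if (is.na(k)) return(Inf)
  lo <- grid[k - 1]; hi <- grid[k]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (level(mid) >= alpha) hi <- mid else lo <- mid
  }
  hi - t
}
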
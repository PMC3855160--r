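# Brute-force oracles, independent of the package's selection/pooling code,
# plus small shared fixtures.

# All interior local extrema of a profile by direct plateau scanning.
oracleExtrema <- function(p, hyp) {
  n <- length(p)
  out <- data.frame(index = integer(), disparity = numeric(),
                    value = numeric(), kind = character())
  t <- 1L
  while (t <= n) {
    u <- t
    while (u < n && p[u + 1] == p[t]) u <- u + 1L
    if (t > 1L && u < n) {
      hi <- p[t - 1] < p[t] && p[u + 1] < p[t]
      lo <- p[t - 1] > p[t] && p[u + 1] > p[t]
      if (hi || lo) {
        len <- u - t + 1L
        cand <- if (len %% 2L == 1L) t + len %/% 2L else {
          m <- c(t + len %/% 2L - 1L, t + len %/% 2L)
          m[order(abs(hyp[m]), m)][1]
        }
        out <- rbind(out, data.frame(index = cand, disparity = hyp[cand],
                                     value = p[t],
                                     kind = if (hi) "max" else "min"))
      }
    }
    t <- u + 1L
  }
  out
}

# First-scale rule by exhaustive comparison.
oracleSelectFirst <- function(p, hyp) {
  ex <- oracleExtrema(p, hyp)
  if (nrow(ex) == 0) {
    ord <- order(-p, abs(hyp), seq_along(hyp))
    return(hyp[ord[1]])
  }
  ord <- order(-abs(ex$value), abs(ex$disparity), ex$index)
  ex$disparity[ord[1]]
}

# Refinement rule by exhaustive comparison.
oracleSelectRefine <- function(p, hyp, prev) {
  ex <- oracleExtrema(p, hyp)
  if (nrow(ex) == 0) return(prev)
  ord <- order(abs(ex$disparity - prev), abs(ex$disparity), ex$index)
  ex$disparity[ord[1]]
}

# Hand simulation of the iterative robust-averaging rule on one multiset.
oracleRobust <- function(x, keep = ceiling(length(x) / 2)) {
  active <- rep(TRUE, length(x))
  while (sum(active) > keep) {
    m <- mean(x[active])
    d <- abs(x - m)
    d[!active] <- -Inf
    active[which.max(d)] <- FALSE   # which.max takes the lowest index on ties
  }
  mean(x[active])
}

# Random profiles with deliberate ties/plateaus mixed in.
randomProfile <- function(n, tied = FALSE) {
  if (tied) sample(0:4, n, replace = TRUE)
  else round(runif(n, 0, 10), 3)
}

# Small seeded stereo pair fixture.
smallPair <- function(seed = 1, n = 64, d = 2) {
  makeStereogram("uniform", seed = seed, width = n, height = n,
                 uniformDisparity = d)
}

# Wrap profile rows into a 1 x n_profiles x n_hyp EnergyStack.
stackFromProfiles <- function(profiles, hyp) {
  e <- array(0, c(1, nrow(profiles), ncol(profiles)))
  e[1, , ] <- profiles
  new("EnergyStack", energies = e,
      hypotheses = new("DisparityHypothesisSet", values = hyp,
                       step = if (length(hyp) > 1) hyp[2] - hyp[1] else 1),
      spec = channelSpec(90, 6))
}
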
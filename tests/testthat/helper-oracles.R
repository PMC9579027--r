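# Independent oracles used across tests. These deliberately avoid the package
# implementations they check.

# Critical transition index by explicit double loops over all pairs.
bruteForceIc <- function(m) {
  G <- ncol(m); C <- nrow(m)
  gg <- c()
  for (a in seq_len(G - 1)) for (b in seq((a + 1), G))
    gg <- c(gg, abs(cor(m[, a], m[, b])))
  cc <- c()
  for (a in seq_len(C - 1)) for (b in seq((a + 1), C))
    cc <- c(cc, abs(cor(m[a, ], m[b, ])))
  mean(gg) / mean(cc)
}

# James-Stein shrinkage entropy, re-coded from the closed form.
shrinkEntropyOracle <- function(counts) {
  n <- sum(counts); K <- length(counts)
  p <- counts / n
  t0 <- 1 / K
  lambda <- if (n <= 1) 1 else {
    num <- (1 - sum(p^2)) / (n - 1)
    den <- sum((t0 - p)^2)
    if (den == 0) 1 else min(max(num / den, 0), 1)
  }
  ps <- lambda * t0 + (1 - lambda) * p
  ps <- ps[ps > 0]
  -sum(ps * log(ps))
}

# Random rigid transform with rotation angle <= maxAngle.
randomRigid <- function(maxAngle, maxShift = 15, seed = 1) {
  set.seed(seed)
  ax <- sample(c("x", "y", "z"), 2)
  a1 <- runif(1, -maxAngle, maxAngle) * 0.7
  a2 <- runif(1, -maxAngle, maxAngle) * 0.3
  rigidTransform(rotationAboutAxis(ax[1], a1) %*% rotationAboutAxis(ax[2], a2),
                 runif(3, -maxShift, maxShift))
}

# Flat lattice fixture whose geometry is shift-ambiguous but whose linear
# color field identifies the true alignment (used for the colored-ICP tests).
latticeCloud <- function(nx = 20, ny = 10) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  pts <- cbind(g$x, g$y, 0)
  pointCloud(pts, channels = list(c = (g$x - 1) / (nx - 1)),
             sampleId = "lattice")
}
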
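# Geometric primitives behind the registration pipeline: voxel downsampling,
# normal estimation and fast point feature histograms (FPFH-style local
# descriptors) used to propose RANSAC correspondences.

# Voxel-grid downsampling: points falling in the same cubic voxel of edge
# `voxel` are averaged (coordinates and channels alike).
.voxelDownsample <- function(pts, voxel, chans = NULL) {
  key <- apply(floor(sweep(pts, 2, apply(pts, 2, min)) / voxel), 1,
               paste, collapse = "_")
  grp <- split(seq_len(nrow(pts)), key)
  out <- t(vapply(grp, function(i) colMeans(pts[i, , drop = FALSE]),
                  numeric(3)))
  ch <- if (!is.null(chans) && ncol(chans) > 0) {
    t(vapply(grp, function(i) colMeans(chans[i, , drop = FALSE]),
             numeric(ncol(chans))))
  } else NULL
  list(pts = out, chans = ch,
       rep = vapply(grp, `[`, integer(1), 1))  # a representative input index
}

# Per-point unit normals from the smallest principal axis of the k-NN
# neighbourhood covariance, oriented consistently toward the cloud centroid.
# Errors out when a neighbourhood is degenerate (collinear points).
.estimateNormals <- function(pts, k = 30) {
  n <- nrow(pts)
  k <- min(k, n)
  if (k < 3) .stopf("normal estimation needs >= 3 points")
  nn <- .knn(pts, pts, k)
  centroid <- colMeans(pts)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- pts[nn$idx[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300))
      .stopf("normal estimation failed: neighbourhood of point %d is collinear", i)
    nrm <- ev$vectors[, 3]
    if (sum(nrm * (centroid - pts[i, ])) < 0) nrm <- -nrm
    normals[i, ] <- nrm
  }
  normals
}

# Simplified FPFH descriptor: per point, the 33-bin histogram (11 bins for
# each of the three Darboux-frame angles) over neighbours within `radius`,
# then augmented with the distance-weighted mean of neighbouring histograms.
.fpfh <- function(pts, normals, radius) {
  n <- nrow(pts)
  d2 <- .crossDist2(pts, pts)
  r2 <- radius^2
  spfh <- matrix(0, n, 33)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(d2[i, ] <= r2 & seq_len(n) != i)
    nbrs[[i]] <- js
    if (!length(js)) next
    p <- pts[i, ]; np <- normals[i, ]
    dvec <- pts[js, , drop = FALSE] - matrix(p, length(js), 3, byrow = TRUE)
    dn <- sqrt(rowSums(dvec^2)); dn[dn == 0] <- 1
    u <- np
    dhat <- dvec / dn
    # Darboux angles per pair (source frame fixed at point i)
    alpha <- numeric(length(js)); phi <- numeric(length(js))
    theta <- numeric(length(js))
    for (m in seq_along(js)) {
      j <- js[m]
      v <- c(u[2] * dhat[m, 3] - u[3] * dhat[m, 2],
             u[3] * dhat[m, 1] - u[1] * dhat[m, 3],
             u[1] * dhat[m, 2] - u[2] * dhat[m, 1])
      nv <- sqrt(sum(v^2)); if (nv == 0) next
      v <- v / nv
      w <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      nj <- normals[j, ]
      alpha[m] <- sum(v * nj)
      phi[m] <- sum(u * dhat[m, ])
      theta[m] <- atan2(sum(w * nj), sum(u * nj))
    }
    b1 <- pmin(pmax(floor((alpha + 1) / 2 * 11) + 1, 1), 11)
    b2 <- pmin(pmax(floor((phi + 1) / 2 * 11) + 1, 1), 11)
    b3 <- pmin(pmax(floor((theta + pi) / (2 * pi) * 11) + 1, 1), 11)
    h <- tabulate(b1, 11)
    h <- c(h, tabulate(b2, 11), tabulate(b3, 11))
    spfh[i, ] <- h / max(sum(h) / 3, 1)
  }
  fp <- spfh
  for (i in seq_len(n)) {
    js <- nbrs[[i]]
    if (!length(js)) next
    wts <- 1 / pmax(sqrt(d2[i, js]), 1e-9)
    fp[i, ] <- spfh[i, ] +
      colSums(spfh[js, , drop = FALSE] * wts) / sum(wts)
  }
  fp
}

# Inlier correspondences of a transformed source against a target at a
# distance threshold; returns pairs plus metrics.
.evaluateAlignment <- function(srcPts, tgtPts, transform, maxDist,
                               srcColor = NULL, tgtColor = NULL) {
  moved <- applyTransform(srcPts, transform)
  nn <- .nn1(moved, tgtPts)
  inl <- which(nn$dist <= maxDist)
  fit <- length(inl) / nrow(srcPts)
  rmse <- if (length(inl)) sqrt(mean(nn$dist[inl]^2)) else Inf
  mae <- NA_real_
  if (!is.null(srcColor) && !is.null(tgtColor) && length(inl))
    mae <- mean(abs(srcColor[inl] - tgtColor[nn$idx[inl]]))
  list(pairs = cbind(source = inl, target = nn$idx[inl]),
       fitness = fit, rmse = rmse, mae = mae)
}

.resultFromEval <- function(ev, transform, nSource, nTarget, method) {
  new("RegistrationResult", transform = transform,
      correspondences = correspondenceMap(ev$pairs, nSource, nTarget),
      fitness = ev$fitness, inlierRMSE = ev$rmse,
      inlierMAE = if (is.null(ev$mae)) NA_real_ else ev$mae,
      method = method)
}
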
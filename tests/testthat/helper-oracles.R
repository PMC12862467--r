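# Independent brute-force oracles, written directly from the statistic
# definitions with plain loops; deliberately share no code with the package
# internals.

oracle_dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

oracle_levels <- function(vox, mask, bin_width) {
  x <- vox[mask != 0]
  lev <- array(0L, dim(vox))
  lev[mask != 0] <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  lev
}

# GLCM statistics by direct enumeration of voxel pairs, per direction,
# averaged over directions with at least one pair; MCC through the spec
# formula for Q and R's eigen.
oracle_glcm <- function(vox, mask, bin_width = 25) {
  lev <- oracle_levels(vox, mask, bin_width)
  G <- max(lev)
  if (G == 1) return(c(JointEntropy = 0, ClusterShade = 0, Imc1 = 0, MCC = 1))
  d <- dim(vox)
  vals <- NULL
  for (dd in seq_len(nrow(oracle_dirs13))) {
    off <- oracle_dirs13[dd, ]
    P <- matrix(0, G, G)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (lev[i, j, k] == 0) next
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (lev[ii, jj, kk] == 0) next
      a <- lev[i, j, k]; b <- lev[ii, jj, kk]
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
    if (sum(P) == 0) next
    p <- P / sum(P)
    px <- rowSums(p); py <- colSums(p)
    pos <- p > 0
    je <- -sum(p[pos] * log2(p[pos]))
    mui <- sum(seq_len(G) * px); muj <- sum(seq_len(G) * py)
    cs <- sum((row(p) + col(p) - mui - muj)^3 * p)
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    hxy1 <- -sum(p[pos] * log2(outer(px, py)[pos]))
    imc1 <- if (max(hx, hy) > 0) (je - hxy1) / max(hx, hy) else 0
    keep <- which(px > 0)
    if (length(keep) < 2) {
      mcc <- 1
    } else {
      Q <- matrix(0, length(keep), length(keep))
      for (a in seq_along(keep)) for (b in seq_along(keep)) {
        s <- 0
        for (kk2 in keep)
          s <- s + p[keep[a], kk2] * p[keep[b], kk2] / (px[keep[a]] * py[kk2])
        Q[a, b] <- s
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      mcc <- sqrt(min(max(ev[2], 0), 1))
    }
    vals <- rbind(vals, c(je, cs, imc1, mcc))
  }
  if (is.null(vals)) return(c(JointEntropy = 0, ClusterShade = 0, Imc1 = 0, MCC = 1))
  out <- colMeans(vals)
  names(out) <- c("JointEntropy", "ClusterShade", "Imc1", "MCC")
  out
}

# NGTDM busyness by direct neighbourhood enumeration
oracle_busyness <- function(vox, mask, bin_width = 25) {
  lev <- oracle_levels(vox, mask, bin_width)
  G <- max(lev)
  d <- dim(vox)
  n_i <- numeric(G); s_i <- numeric(G)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    li <- lev[i, j, k]
    if (li == 0) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (lev[ii, jj, kk] > 0) nb <- c(nb, lev[ii, jj, kk])
    }
    n_i[li] <- n_i[li] + 1
    if (length(nb) > 0) s_i[li] <- s_i[li] + abs(li - mean(nb))
  }
  p <- n_i / sum(n_i)
  occ <- which(p > 0)
  den <- 0
  for (a in occ) for (b in occ) den <- den + abs(a * p[a] - b * p[b])
  if (den == 0) return(0)
  sum(p * s_i) / den
}

# AUC as the fraction of concordant positive-negative pairs (ties 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Youden by exhaustive threshold scan
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  if (length(s) == 1) return(list(cutoff = s, J = 0))
  thr <- (s[-length(s)] + s[-1]) / 2
  best_j <- -Inf; best_t <- NA
  for (t in thr) {
    sens <- mean(scores[labels == 1] > t)
    spec <- mean(scores[labels == 0] <= t)
    j <- sens + spec - 1
    if (j > best_j + 1e-15) { best_j <- j; best_t <- t }
  }
  list(cutoff = best_t, J = best_j)
}

# squared Euclidean distance to the nearest foreground voxel, brute force
oracle_sedt <- function(mask) {
  d <- dim(mask)
  co <- which(mask != 0, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    out[i, j, k] <- min(colSums((t(co) - c(i, j, k))^2))
  out
}
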
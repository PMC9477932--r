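# Independent brute-force oracles used to validate the texture-matrix and
# statistics implementations.  These are deliberately naive (explicit
# loops, recursion, full enumeration) and share no code with the package
# internals.

# Build a discretized_roi straight from an integer level matrix (NA = out
# of ROI), bypassing intensity binning.
droi_from_levels <- function(m) {
  coords <- which(!is.na(m), arr.ind = TRUE)
  vals <- m[coords]
  # bin width 1 with values v maps v -> level v + 1; subtract 1 by using
  # values v - 1 so that levels equal the matrix entries
  discretize((vals - 1) + 0.5, background = 1, bin_width = 1,
             coords = coords)
}

# GLCM by explicit enumeration of every ordered voxel pair at the offset.
oracle_glcm <- function(m, ng, di, dj) {
  cm <- matrix(0, ng, ng)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (is.na(m[i, j])) next
    i2 <- i + di; j2 <- j + dj
    if (i2 < 1 || i2 > nrow(m) || j2 < 1 || j2 > ncol(m)) next
    if (is.na(m[i2, j2])) next
    cm[m[i, j], m[i2, j2]] <- cm[m[i, j], m[i2, j2]] + 1
  }
  cm <- cm + t(cm)
  if (sum(cm) > 0) cm / sum(cm) else cm
}

# GLRLM by walking each scan line cell by cell.
oracle_glrlm <- function(m, ng, max_run, dir) {
  starts <- switch(dir,
    `0`   = cbind(seq_len(nrow(m)), 1),
    `90`  = cbind(1, seq_len(ncol(m))),
    `45`  = rbind(cbind(seq_len(nrow(m)), 1),
                  cbind(nrow(m), 1 + seq_len(ncol(m) - 1))),
    `135` = rbind(cbind(seq_len(nrow(m)), 1),
                  cbind(1, 1 + seq_len(ncol(m) - 1))))
  step <- switch(dir, `0` = c(0, 1), `90` = c(1, 0),
                 `45` = c(-1, 1), `135` = c(1, 1))
  cm <- matrix(0, ng, max_run)
  for (s in seq_len(nrow(starts))) {
    i <- starts[s, 1]; j <- starts[s, 2]
    cur <- NA; len <- 0
    while (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m)) {
      v <- m[i, j]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) cm[cur, len] <- cm[cur, len] + 1
        cur <- v; len <- 1
      }
      i <- i + step[1]; j <- j + step[2]
    }
    if (!is.na(cur)) cm[cur, len] <- cm[cur, len] + 1
  }
  cm
}

# GLSZM by recursive 8-connected flood fill.
oracle_glszm <- function(m, ng) {
  visited <- matrix(FALSE, nrow(m), ncol(m))
  fill <- function(i, j, v) {
    if (i < 1 || i > nrow(m) || j < 1 || j > ncol(m)) return(0)
    if (visited[i, j] || is.na(m[i, j]) || m[i, j] != v) return(0)
    visited[i, j] <<- TRUE
    n <- 1
    for (di in -1:1) for (dj in -1:1)
      if (di != 0 || dj != 0) n <- n + fill(i + di, j + dj, v)
    n
  }
  sizes <- integer(0); levels <- integer(0)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!is.na(m[i, j]) && !visited[i, j]) {
      sz <- fill(i, j, m[i, j])
      sizes <- c(sizes, sz); levels <- c(levels, m[i, j])
    }
  }
  if (length(sizes) == 0) return(matrix(0, ng, 1))
  cm <- matrix(0, ng, max(sizes))
  for (q in seq_along(sizes))
    cm[levels[q], sizes[q]] <- cm[levels[q], sizes[q]] + 1
  cm
}

# IMC2 by direct entropy summation over a probability matrix (log base 2).
oracle_imc2 <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  q <- outer(px, py)
  hxy2 <- -sum(q[q > 0] * log2(q[q > 0]))
  sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
}

# INN by direct summation over a zone-count matrix.
oracle_inn <- function(s) {
  sum(rowSums(s)^2) / sum(s)^2
}

# AUC by counting all positive-negative pairs (ties worth 1/2).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# Fisher two-sided p by full enumeration over tables with fixed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) /
    choose(r1 + r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Greedy correlation-filter rule, re-implemented naively.
oracle_drop_correlated <- function(x, threshold) {
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2) break
    cm <- abs(cor(x[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) < threshold) break
    w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[w[1]]; b <- keep[w[2]]
    ma <- mean(cm[w[1], ]); mb <- mean(cm[w[2], ])
    victim <- if (ma > mb) a else if (mb > ma) b
              else keep[min(w[1], w[2])]
    keep <- setdiff(keep, victim)
  }
  keep
}

# Random level matrix (values 1..ng, NA with prob p_na) for property loops.
random_level_matrix <- function(nr, nc, ng, p_na = 0) {
  v <- sample.int(ng, nr * nc, replace = TRUE)
  if (p_na > 0) v[runif(nr * nc) < p_na] <- NA
  matrix(v, nr, nc)
}

# Small textured phantom for quantification tests.
toy_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

# Independent auto-contour oracle: recursive 8-connected flood fill from a
# start voxel over supra-threshold cells of one slice.
oracle_contour <- function(sl, background, threshold, start) {
  supra <- sl >= threshold * background
  visited <- matrix(FALSE, nrow(sl), ncol(sl))
  fill <- function(i, j) {
    if (i < 1 || i > nrow(sl) || j < 1 || j > ncol(sl)) return(invisible())
    if (visited[i, j] || !supra[i, j]) return(invisible())
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1)
      if (di != 0 || dj != 0) fill(i + di, j + dj)
    invisible()
  }
  fill(start[1], start[2])
  which(visited, arr.ind = TRUE)
}
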
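# Independent brute-force enumerations of the gray-level matrices, written
# as plain nested loops so they share no code with the compiled engine.

ORACLE_DIRS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

inGrid <- function(p, d) all(p >= 1) && all(p <= d)

oracleGLCM <- function(lev, ng) {
  d <- dim(lev)
  out <- vector("list", 13)
  for (k in 1:13) {
    m <- matrix(0, ng, ng)
    dd <- ORACLE_DIRS[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      li <- lev[x, y, z]
      if (li == 0) next
      for (s in c(1, -1)) {
        q <- c(x, y, z) + s * dd
        if (!inGrid(q, d)) next
        lj <- lev[q[1], q[2], q[3]]
        if (lj > 0) m[li, lj] <- m[li, lj] + 1
      }
    }
    out[[k]] <- m
  }
  out
}

oracleGLRLM <- function(lev, ng) {
  d <- dim(lev)
  maxlen <- max(d)
  out <- vector("list", 13)
  for (k in 1:13) {
    m <- matrix(0, ng, maxlen)
    dd <- ORACLE_DIRS[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      prev <- c(x, y, z) - dd
      if (inGrid(prev, d)) next   # not a line start
      p <- c(x, y, z)
      cur <- 0; len <- 0
      while (inGrid(p, d)) {
        l <- lev[p[1], p[2], p[3]]
        if (l == cur) {
          if (cur != 0) len <- len + 1
        } else {
          if (cur != 0) m[cur, len] <- m[cur, len] + 1
          cur <- l; len <- 1
        }
        p <- p + dd
      }
      if (cur != 0) m[cur, len] <- m[cur, len] + 1
    }
    out[[k]] <- m
  }
  out
}

neighbors26 <- function(p, d) {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    q <- p + c(dx, dy, dz)
    if (inGrid(q, d)) out[[length(out) + 1]] <- q
  }
  out
}

oracleGLSZM <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    lvl <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (q in neighbors26(p, d)) {
        if (lev[q[1], q[2], q[3]] == lvl && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lvl, size)
  }
  maxsize <- max(vapply(zones, `[`, 0, 2))
  m <- matrix(0, ng, maxsize)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1
  m
}

oracleGLDM <- function(lev, ng) {
  d <- dim(lev)
  m <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    dep <- 1
    for (q in neighbors26(c(x, y, z), d))
      if (lev[q[1], q[2], q[3]] == li) dep <- dep + 1
    m[li, dep] <- m[li, dep] + 1
  }
  m
}

oracleNGTDM <- function(lev, ng) {
  d <- dim(lev)
  m <- matrix(0, ng, 2)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    vals <- c()
    for (q in neighbors26(c(x, y, z), d)) {
      l2 <- lev[q[1], q[2], q[3]]
      if (l2 > 0) vals <- c(vals, l2)
    }
    m[li, 1] <- m[li, 1] + 1
    if (length(vals) > 0) m[li, 2] <- m[li, 2] + abs(li - mean(vals))
  }
  m
}

# random small discretized instance: dims <= 6, levels 0..5, >= 1 voxel
randomLevelArray <- function() {
  d <- sample(2:6, 3, replace = TRUE)
  lev <- array(sample(0:5, prod(d), replace = TRUE,
                      prob = c(0.3, rep(0.14, 5))), d)
  if (all(lev == 0)) lev[1] <- 1L
  storage.mode(lev) <- "integer"
  lev
}

# analytic LoG kernel sampled at voxel centers (same documented
# construction as the filter: unit-gain smoothing, DC-corrected curvature)
oracleLoGKernel <- function(sigma, voxelSize) {
  k1 <- lapply(1:3, function(a) {
    r <- max(2L, ceiling(4 * sigma / voxelSize[a]))
    x <- (-r:r) * voxelSize[a]
    g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    g <- g / sum(g)
    g2 <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) *
      (x^2 - sigma^2) / sigma^4 * voxelSize[a]
    g2 <- g2 - mean(g2)
    list(g = g, g2 = g2)
  })
  rx <- (length(k1[[1]]$g) - 1) / 2
  ry <- (length(k1[[2]]$g) - 1) / 2
  rz <- (length(k1[[3]]$g) - 1) / 2
  K <- array(0, c(2 * rx + 1, 2 * ry + 1, 2 * rz + 1))
  for (i in seq_len(dim(K)[1])) for (j in seq_len(dim(K)[2]))
    for (k in seq_len(dim(K)[3])) {
      K[i, j, k] <-
        k1[[1]]$g2[i] * k1[[2]]$g[j] * k1[[3]]$g[k] +
        k1[[1]]$g[i] * k1[[2]]$g2[j] * k1[[3]]$g[k] +
        k1[[1]]$g[i] * k1[[2]]$g[j] * k1[[3]]$g2[k]
    }
  K
}
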
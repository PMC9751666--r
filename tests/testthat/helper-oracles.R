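# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Euler characteristic of the closed cubical complex by explicit cell
# enumeration: every voxel contributes its 8 vertices, 12 edges, 6 faces and
# 1 cube as string keys; chi = V - E + F - C over the distinct cells.
oracle_euler <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  verts <- edges <- faces <- character(0)
  for (r in seq_len(nrow(idx))) {
    x <- idx[r, 1]; y <- idx[r, 2]; z <- idx[r, 3]
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      verts <- c(verts, paste(x + dx, y + dy, z + dz, sep = ","))
    for (dy in 0:1) for (dz in 0:1)
      edges <- c(edges, paste("ex", x, y + dy, z + dz, sep = ","))
    for (dx in 0:1) for (dz in 0:1)
      edges <- c(edges, paste("ey", x + dx, y, z + dz, sep = ","))
    for (dx in 0:1) for (dy in 0:1)
      edges <- c(edges, paste("ez", x + dx, y + dy, z, sep = ","))
    for (dz in 0:1) faces <- c(faces, paste("fxy", x, y, z + dz, sep = ","))
    for (dy in 0:1) faces <- c(faces, paste("fxz", x, y + dy, z, sep = ","))
    for (dx in 0:1) faces <- c(faces, paste("fyz", x + dx, y, z, sep = ","))
  }
  length(unique(verts)) - length(unique(edges)) +
    length(unique(faces)) - nrow(idx)
}

# connected components by flood fill; conn = 26 or 6
oracle_components <- function(mask, conn = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0 & nb$dz == 0), ]
  if (conn == 6) nb <- nb[abs(nb$dx) + abs(nb$dy) + abs(nb$dz) == 1, ]
  ncomp <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] > 0) next
    ncomp <- ncomp + 1L
    stack <- start
    lab[start] <- ncomp
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ai <- arrayInd(i, d)
      for (k in seq_len(nrow(nb))) {
        p <- ai + c(nb$dx[k], nb$dy[k], nb$dz[k])
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- ncomp
          stack <- c(stack, j)
        }
      }
    }
  }
  ncomp
}

# number of enclosed cavities: 6-connected background components that do
# not touch the array border
oracle_cavities <- function(mask) {
  d <- dim(mask)
  padded <- array(FALSE, d + 2)
  padded[1 + 1:d[1], 1 + 1:d[2], 1 + 1:d[3]] <- mask
  bg_comp_padded <- oracle_components(!padded, conn = 6)
  bg_comp_padded - 1L   # the outside is one 6-connected component
}

# exact two-sided Mann-Whitney p value by full enumeration of group
# assignments (no ties assumed)
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) # U for x vs y
  u_obs <- u_of(a, b)
  n <- length(pooled)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force median filter with reflective padding
oracle_median3 <- function(arr, k) {
  d <- dim(arr)
  r <- k %/% 2
  refl <- function(c, n) {
    while (c < 1 || c > n) {
      if (c < 1) c <- 1 - c + 0
      if (c > n) c <- 2 * n - c + 1
    }
    c
  }
  out <- arr
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    vals <- numeric(0)
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
      vals <- c(vals, arr[refl(x + dx, d[1]), refl(y + dy, d[2]),
                          refl(z + dz, d[3])])
    out[x, y, z] <- stats::median(vals)
  }
  out
}

# random blob mask for invariance tests: union of a few random balls
random_blob <- function(dim3, n_balls = 3, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dim3)
  ax <- lapply(dim3, seq_len)
  for (b in seq_len(n_balls)) {
    c0 <- sapply(dim3, function(n) runif(1, n * 0.3, n * 0.7))
    r0 <- runif(1, min(dim3) * 0.12, min(dim3) * 0.25)
    d2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, `+`),
                (ax[[3]] - c0[3])^2, `+`)
    m <- m | (d2 <= r0^2)
  }
  m
}
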
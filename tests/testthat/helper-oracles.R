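# Independent brute-force oracles. Deliberately slow and literal: explicit
# loops and recursion only, no shared code with the package implementation.

# Flood-fill patch labelling.
oracle_label <- function(cls, connectivity = 8L) {
  nr <- nrow(cls); nc <- ncol(cls)
  lab <- matrix(NA_integer_, nr, nc)
  nbrs <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(cls[r, c]) || !is.na(lab[r, c])) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in nbrs) {
        rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (is.na(cls[rr, cc]) || !is.na(lab[rr, cc])) next
        if (cls[rr, cc] != cls[r, c]) next
        lab[rr, cc] <- nxt
        stack[[length(stack) + 1L]] <- c(rr, cc)
      }
    }
  }
  lab
}

# Patch table (class, area, perimeter) from a window.
oracle_patches <- function(cls, connectivity = 8L) {
  lab <- oracle_label(cls, connectivity)
  nr <- nrow(cls); nc <- ncol(cls)
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- data.frame(patch = ids, class = NA_integer_, area = 0L, perimeter = 0L)
  for (k in seq_along(ids)) {
    cells <- which(lab == ids[k], arr.ind = TRUE)
    out$class[k] <- cls[cells[1, 1], cells[1, 2]]
    out$area[k] <- nrow(cells)
    per <- 0L
    for (i in seq_len(nrow(cells))) {
      r <- cells[i, 1]; c <- cells[i, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) per <- per + 1L
        else if (is.na(cls[rr, cc]) || cls[rr, cc] != cls[r, c]) per <- per + 1L
      }
    }
    out$perimeter[k] <- per
  }
  out
}

# CONTAG by explicit adjacency enumeration (double count).
oracle_contagion <- function(cls) {
  nr <- nrow(cls); nc <- ncol(cls)
  g <- matrix(0, 6, 6)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(cls[r, c])) next
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(cls[rr, cc])) next
      g[cls[r, c], cls[rr, cc]] <- g[cls[r, c], cls[rr, cc]] + 1
    }
  }
  p <- rep(0, 6)
  for (k in 1:6) p[k] <- sum(cls == k, na.rm = TRUE) / sum(!is.na(cls))
  m <- sum(p > 0)
  if (m <= 1) return(100)
  acc <- 0
  for (i in 1:6) for (k in 1:6) {
    if (p[i] == 0 || sum(g[i, ]) == 0) next
    pp <- p[i] * g[i, k] / sum(g[i, ])
    if (pp > 0) acc <- acc + pp * log(pp)
  }
  100 * (1 + acc / (2 * log(m)))
}

oracle_shdi <- function(cls) {
  tot <- sum(!is.na(cls))
  acc <- 0
  for (k in 1:6) {
    p <- sum(cls == k, na.rm = TRUE) / tot
    if (p > 0) acc <- acc - p * log(p)
  }
  acc
}

oracle_awmpfd <- function(cls, connectivity = 8L) {
  pt <- oracle_patches(cls, connectivity)
  A <- sum(!is.na(cls))
  acc <- 0
  for (i in seq_len(nrow(pt))) {
    fd <- if (pt$area[i] == 1) 1 else 2 * log(0.25 * pt$perimeter[i]) / log(pt$area[i])
    acc <- acc + fd * pt$area[i] / A
  }
  acc
}

oracle_cohesion <- function(cls, code, connectivity = 8L) {
  pt <- oracle_patches(cls, connectivity)
  pt <- pt[pt$class == code, ]
  if (!nrow(pt)) return(0)
  Z <- sum(!is.na(cls))
  (1 - sum(pt$perimeter) / sum(pt$perimeter * sqrt(pt$area))) /
    (1 - 1 / sqrt(Z)) * 100
}

# Exhaustive Fisher-Jenks: all ways to cut sorted values into k contiguous
# groups; returns the class assignment of the optimal partition.
oracle_jenks_assign <- function(x, k) {
  sx <- sort(x)
  n <- length(sx)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_assign <- NULL
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    ss <- 0
    assign <- integer(n)
    for (g in seq_len(k)) {
      idx <- (bounds[g] + 1):bounds[g + 1]
      seg <- sx[idx]
      ss <- ss + sum((seg - mean(seg))^2)
      assign[idx] <- g
    }
    if (ss < best - 1e-12) { best <- ss; best_assign <- assign }
  }
  list(wss = best, assign = best_assign, sorted = sx)
}

# Moran's I by double loop over a dense weight matrix.
oracle_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Gi* by per-cell formula evaluation (binary weights incl. self).
oracle_gistar <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in 1:n) {
    wi <- sum(W[i, ])
    w2i <- sum(W[i, ]^2)
    num <- sum(W[i, ] * x) - xbar * wi
    den <- S * sqrt((n * w2i - wi^2) / (n - 1))
    z[i] <- num / den
  }
  z
}

# Geodetector q by explicit variance decomposition.
oracle_q <- function(y, strata) {
  N <- length(y)
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (s in unique(strata)) {
    ys <- y[strata == s]
    ssw <- ssw + sum((ys - mean(ys))^2)
  }
  1 - ssw / sst
}

# Dense queen/rook weight matrix for an r x c lattice (for the oracles).
lattice_weights <- function(r, c, queen = TRUE, self = FALSE,
                            row_standardise = FALSE) {
  n <- r * c
  W <- matrix(0, n, n)
  id <- function(i, j) (i - 1) * c + j
  for (i in 1:r) for (j in 1:c) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (!queen && abs(di) + abs(dj) != 1) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > r || jj < 1 || jj > c) next
      W[id(i, j), id(ii, jj)] <- 1
    }
  }
  if (self) diag(W) <- 1
  if (row_standardise) W <- W / rowSums(W)
  W
}

# Random small land-use window under a fixed seed.
random_window <- function(nr, nc, classes = 1:3, seed = 1) {
  set.seed(seed)
  matrix(sample(classes, nr * nc, replace = TRUE), nr, nc)
}
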
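# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored binary fixtures.

# points on a (rotated, offset) ellipse arc, optional isotropic noise
genEllipsePoints <- function(n, cx = 0, cy = 0, a = 1, b = 1, theta = 0,
                             span = c(0, 2 * pi), sd = 0) {
  t <- seq(span[1], span[2], length.out = n)
  x <- a * cos(t); y <- b * sin(t)
  P <- cbind(cos(theta) * x - sin(theta) * y + cx,
             sin(theta) * x + cos(theta) * y + cy)
  if (sd > 0) P <- P + matrix(rnorm(2 * n, sd = sd), n, 2)
  P
}

# annulus (ring) mask of mid radius R and radial half-width hw
genAnnulusMask <- function(dim, cx, cy, R, hw = 1.5) {
  g <- expand.grid(row = seq_len(dim[1]), col = seq_len(dim[2]))
  r <- sqrt((g$row - 1 - cy)^2 + (g$col - 1 - cx)^2)
  matrix(as.integer(abs(r - R) <= hw), dim[1], dim[2])
}

# exact 1-px-wide 8-connected ring (midpoint circle algorithm: every
# pixel has exactly two neighbours)
genUnitRing <- function(dim, cx, cy, R) {
  x <- R; y <- 0; err <- 1 - R
  pts <- NULL
  while (x >= y) {
    pts <- rbind(pts,
                 c(x, y), c(y, x), c(-y, x), c(-x, y),
                 c(-x, -y), c(-y, -x), c(y, -x), c(x, -y))
    y <- y + 1
    if (err < 0) err <- err + 2 * y + 1
    else { x <- x - 1; err <- err + 2 * (y - x) + 1 }
  }
  pts <- unique(pts)
  m <- matrix(0L, dim[1], dim[2])
  m[cbind(cy + pts[, 2] + 1, cx + pts[, 1] + 1)] <- 1L
  m
}

# brute-force shortest Hamiltonian path over the skeleton pixel graph
# (Held-Karp DP, for tiny n); returns the minimal total path length
heldKarpShortestPath <- function(coords) {
  n <- nrow(coords)
  stopifnot(n <= 12)
  D <- as.matrix(dist(coords))
  full <- bitwShiftL(1L, n) - 1L
  best <- array(Inf, dim = c(full, n))
  for (i in seq_len(n)) best[bitwShiftL(1L, i - 1L), i] <- 0
  for (mask in seq_len(full)) {
    for (last in seq_len(n)) {
      if (!bitwAnd(mask, bitwShiftL(1L, last - 1L))) next
      cur <- best[mask, last]
      if (!is.finite(cur)) next
      for (nxt in seq_len(n)) {
        if (bitwAnd(mask, bitwShiftL(1L, nxt - 1L))) next
        m2 <- bitwOr(mask, bitwShiftL(1L, nxt - 1L))
        cand <- cur + D[last, nxt]
        if (cand < best[m2, nxt]) best[m2, nxt] <- cand
      }
    }
  }
  min(best[full, ])
}

# literal step-up definition of the BH adjustment (independent oracle):
# adjusted p for the i-th smallest p is min over j >= i of m * p_(j) / j
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * ps[j] / j, numeric(1))
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Kabsch-Sander energy for one donor/acceptor pair from raw coordinates
# (independent arithmetic, Angstrom in / kcal/mol out)
ksEnergy <- function(N, H, C, O) {
  d <- function(u, v) sqrt(sum((u - v)^2))
  27.888 * (1 / d(N, O) + 1 / d(H, C) - 1 / d(H, O) - 1 / d(N, C))
}

# path length of an ordered point sequence
polylineLength <- function(P) sum(sqrt(rowSums(diff(P)^2)))
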
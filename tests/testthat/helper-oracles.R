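# Independent scalar-loop oracles. These re-derive every quantity from the
# defining formulas with explicit loops, deliberately sharing no code with the
# package internals.

# grey_image from a vector of levels (column-major fill)
make_grey <- function(levels, nrow = length(levels), preprocessing = "none") {
  structure(list(levels = matrix(as.integer(levels), nrow = nrow),
                 preprocessing = preprocessing, element = "other"),
            class = "grey_image")
}

# histogram object from raw 256-bin counts
make_hist <- function(H) {
  stopifnot(length(H) == 256)
  structure(list(H = as.integer(H), P = sum(H)), class = "grey_histogram")
}

# counting-loop histogram oracle
oracle_hist <- function(levels) {
  H <- integer(256)
  for (v in as.vector(levels)) H[v + 1] <- H[v + 1] + 1L
  H
}

# direct evaluation of the histogram/Gaussian/relative-entropy formulas
oracle_entropy <- function(H) {
  P <- 0
  for (g in 0:255) P <- P + H[g + 1]
  gm <- 0
  for (g in 0:255) gm <- gm + g * H[g + 1]
  gm <- gm / P
  s2 <- 0
  for (g in 0:255) s2 <- s2 + (g - gm)^2 * H[g + 1]
  s2 <- s2 / (P - 1)
  G <- R <- RH <- numeric(256)
  for (g in 0:255) {
    G[g + 1] <- P / sqrt(2 * pi * s2) * exp(-(g - gm)^2 / (2 * s2))
    if (H[g + 1] > 0) {
      R[g + 1] <- log(H[g + 1] / G[g + 1])
      RH[g + 1] <- R[g + 1] * H[g + 1]
    }
  }
  q <- 0
  for (g in 0:255) q <- q + RH[g + 1]
  q <- q / P
  list(g_mean = gm, sigma2 = s2, G = G, R = R, RH = RH, q = q)
}

# exhaustive scan for the workflow-A threshold: smallest grey level strictly
# above the mean that begins a consecutive block (>= min_run long) of bins
# with H > 0 and R > 0; NA when no block qualifies
oracle_g0 <- function(H, min_run = 1) {
  o <- oracle_entropy(H)
  pos <- H > 0 & o$R > 0
  for (g in 0:255) {
    if (!pos[g + 1]) next
    if (g > 0 && pos[g]) next            # not a block start
    if (g <= o$g_mean) next
    len <- 0
    while (g + len <= 255 && pos[g + len + 1]) len <- len + 1
    if (len >= min_run) return(as.integer(g - 1))
  }
  NA_integer_
}

# exhaustive scan for the workflow-B threshold on the RH curve above g0
oracle_g1 <- function(RH, g0) {
  lv <- (g0 + 1):255
  rel <- RH[lv + 1]
  s <- which(rel > 0)[1]
  if (is.na(s)) return(NA_integer_)
  for (j in seq_along(rel)) {
    if (j > s && rel[j] <= 0) return(as.integer(lv[j - 1]))
  }
  # never returns to zero: first local minimum after the first maximum
  m <- s
  while (m < length(rel) && rel[m + 1] >= rel[m]) m <- m + 1
  j <- m
  while (j < length(rel) && rel[j + 1] <= rel[j]) j <- j + 1
  if (j < length(rel)) return(as.integer(lv[j]))
  255L
}

# deterministic discretized-Gaussian histogram: expected bin counts of n
# normal(mu, sd) draws rounded to integers
gaussian_counts <- function(n, mu, sd) {
  g <- 0:255
  round(n * (pnorm((g + 0.5 - mu) / sd) - pnorm((g - 0.5 - mu) / sd)))
}

# tiny region helper
full_region <- function(nr, nc) region_mask(matrix(TRUE, nr, nc))

# 0/1 disk painted on an nr x nc grid
disk_mask_px <- function(nr, nc, row, col, radius) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - row)^2 + (c_ - col)^2 <= radius^2) * 1
}
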
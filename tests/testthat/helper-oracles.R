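# Independent brute-force oracles: every one of these re-derives a quantity
# from its definition with plain loops, so package results can be checked
# against them on small instances.

# One blanket dilation step, straight from the definition: per-pixel max/min
# over the 8-connected neighbourhood clipped at the border.
oracle_dilate <- function(u, b) {
  nr <- nrow(u); nc <- ncol(u)
  u1 <- u; b1 <- b
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    u1[i, j] <- max(u[i, j] + 1, max(u[ii, jj]))
    b1[i, j] <- min(b[i, j] - 1, min(b[ii, jj]))
  }
  list(upper = u1, lower = b1)
}

# Blanket areas A(eps) by iterating the oracle dilation and summing volumes.
oracle_blanket_areas <- function(g, max_eps) {
  u <- g; b <- g
  v_prev <- 0
  areas <- numeric(max_eps)
  for (e in seq_len(max_eps)) {
    st <- oracle_dilate(u, b)
    u <- st$upper; b <- st$lower
    v <- 0
    for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
      v <- v + (u[i, j] - b[i, j])
    areas[e] <- (v - v_prev) / 2
    v_prev <- v
  }
  areas
}

# Differential box count over a cells x cells grid by scanning each cell.
oracle_box_total <- function(g, cells, gray_levels) {
  R <- nrow(g); S <- R / cells; h <- gray_levels * S / R
  total <- 0
  for (ci in seq_len(cells)) for (cj in seq_len(cells)) {
    blk <- g[((ci - 1) * S + 1):(ci * S), ((cj - 1) * S + 1):(cj * S)]
    k <- min(floor(min(blk) / h) + 1, cells)
    l <- min(floor(max(blk) / h) + 1, cells)
    total <- total + (l - k + 1)
  }
  total
}

# Mode-n product by direct summation over the contracted index.
oracle_mode_product <- function(x, u, mode) {
  d <- dim(x); dn <- d; dn[mode] <- nrow(u)
  out <- array(0, dn)
  idx <- as.matrix(expand.grid(lapply(dn, seq_len)))
  for (r in seq_len(nrow(idx))) {
    s <- 0
    for (i in seq_len(d[mode])) {
      src <- idx[r, ]; src[mode] <- i
      s <- s + x[matrix(src, 1)] * u[idx[r, mode], i]
    }
    out[matrix(idx[r, ], 1)] <- s
  }
  out
}

# Independent mode-n unfolding (natural residual-mode order, which differs
# from the package's cyclic order; the row space is order-invariant).
oracle_unfold <- function(x, mode) {
  d <- dim(x)
  y <- aperm(x, c(mode, setdiff(seq_along(d), mode)))
  dim(y) <- c(d[mode], prod(d[-mode]))
  y
}

# Leading left singular vectors of the mode unfolding (truncated HOSVD basis).
oracle_hosvd_basis <- function(x, mode, j) {
  svd(oracle_unfold(x, mode))$u[, seq_len(j), drop = FALSE]
}

# Largest principal angle (radians) between the column spaces of two
# orthonormal-column matrices.
principal_angle_max <- function(u, v) {
  s <- svd(crossprod(u, v))$d
  acos(min(pmax(pmin(s, 1), -1)))
}

# Slope of the radially averaged log power spectrum vs log frequency.
oracle_spectrum_slope <- function(img) {
  n <- nrow(img)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fr <- sqrt(outer(f^2, f^2, `+`))
  p <- Mod(stats::fft(img))^2
  sel <- fr > 2 / n & fr < 0.25
  bins <- cut(log(fr[sel]), 20)
  mx <- tapply(log(fr[sel]), bins, mean)
  my <- tapply(log(p[sel]), bins, mean)
  ok <- is.finite(mx) & is.finite(my)
  unname(stats::coef(stats::lm(my[ok] ~ mx[ok]))[2])
}

# Replays one uniform-choice ACO cycle (constant fitness) with the same RNG
# stream the package uses, applying the local and global updates by hand.
oracle_aco_one_cycle <- function(n_ants, rho, tau0, Q, acc, seed) {
  set.seed(seed)
  tau <- matrix(1, 10, 10)
  paths <- matrix(0L, n_ants, 10)
  for (ant in seq_len(n_ants)) for (col in 1:10) {
    d <- sample.int(10L, 1L) - 1L
    paths[ant, col] <- d
    tau[d + 1, col] <- (1 - rho) * tau[d + 1, col] + rho * tau0
  }
  best <- 1L  # constant fitness: which.max takes the first ant
  for (col in 1:10)
    tau[paths[best, col] + 1, col] <- tau[paths[best, col] + 1, col] + Q * acc
  list(tau = tau, digits = paths[best, ])
}

# Symmetric-reflection patch extraction matching the sliding-window maps.
reflect_idx <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))

patch_at <- function(g, pi, pj, w) {
  h <- w %/% 2
  g[reflect_idx((pi - h):(pi - h + w - 1), nrow(g)),
    reflect_idx((pj - h):(pj - h + w - 1), ncol(g))]
}
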
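# Independent oracles and fixture builders shared across the suite.

# Dense-grid oracle for the SS point p-value: maximize the product of
# binomial tails over a pi grid (vectorized pbinom, independent of the
# package's golden-section search).
oracle_ss_log10p <- function(x0, x1, t0, t1, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  lp <- pbinom(x0, t0, grid, log.p = TRUE) +
    ifelse(rep(x1, length(grid)) <= 0, 0,
           pbinom(x1 - 1, t1, grid, lower.tail = FALSE, log.p = TRUE))
  -max(lp) / log(10)
}

# Dense-grid oracle along a null-region boundary chain: grid each segment
# in its line parameter.
oracle_chain_log10p <- function(x0, x1, t0, t1, chain, step = 1e-4) {
  best <- -Inf
  for (k in seq_len(nrow(chain) - 1L)) {
    s <- seq(0, 1, by = step)
    p0 <- chain[k, 1L] + s * (chain[k + 1L, 1L] - chain[k, 1L])
    p1 <- chain[k, 2L] + s * (chain[k + 1L, 2L] - chain[k, 2L])
    lp <- pbinom(x0, t0, p0, log.p = TRUE) +
      ifelse(rep(x1, length(s)) <= 0, 0,
             pbinom(x1 - 1, t1, p1, lower.tail = FALSE, log.p = TRUE))
    best <- max(best, max(lp))
  }
  -min(best, 0) / log(10)
}

# 2-D grid oracle over an entire null region: for each pi0 the admissible
# pi1 are those at or below the region's upper envelope (recomputed here by
# direct interpolation of the chain, independent of the package's search).
oracle_region_log10p <- function(x0, x1, t0, t1, chain, step = 1e-3) {
  g <- seq(0, 1, by = step)
  ux <- unique(chain[, 1L])
  uy <- vapply(ux, function(x) max(chain[chain[, 1L] == x, 2L]), numeric(1))
  top <- if (length(ux) == 1L) rep(max(uy), length(g))
  else approx(ux, uy, xout = g, rule = 2)$y
  lup <- if (x1 <= 0) rep(0, length(g))
  else pbinom(x1 - 1, t1, g, lower.tail = FALSE, log.p = TRUE)
  cum_up <- cummax(lup)           # lup is increasing in pi1 anyway
  best <- -Inf
  for (i in seq_along(g)) {
    k <- findInterval(top[i] + 1e-12, g)
    if (k < 1) next
    lp <- pbinom(x0, t0, g[i], log.p = TRUE) + cum_up[k]
    if (lp > best) best <- lp
  }
  -min(best, 0) / log(10)
}

# Random 2 x V contingency table with both row totals >= 1.
random_table <- function(V, max_count = 20L) {
  repeat {
    cnt <- matrix(sample(0:max_count, 2L * V, replace = TRUE), nrow = 2L)
    if (sum(cnt[1L, ]) >= 1L && sum(cnt[2L, ]) >= 1L) {
      return(contingency_table(cnt))
    }
  }
}

# Exact concavity check on integer counts: segment slopes (dy/t1)/(dx/t0)
# must be non-increasing; compared via cross products, no division.
slopes_nonincreasing <- function(roc) {
  v <- roc$vertices
  k <- nrow(v) - 1L
  if (k < 2L) return(TRUE)
  dx <- diff(v[, 1L]) * roc$t1   # scale so slope_i ~ dy_i / dx_i
  dy <- diff(v[, 2L]) * roc$t0
  for (i in seq_len(k - 1L)) {
    if (dy[i] * dx[i + 1L] < dy[i + 1L] * dx[i]) return(FALSE)
  }
  TRUE
}

# Small random case-control genotype dataset (no missing calls).
random_geno_data <- function(m, n0, n1, maf_range = c(0.1, 0.5)) {
  q <- runif(m, maf_range[1L], maf_range[2L])
  geno <- matrix(rbinom(m * (n0 + n1), 2L, q), nrow = m)
  genotype_data(geno, c(rep(0L, n0), rep(1L, n1)))
}

# The XOR toy dataset: 4 controls split over cells (0,0)/(1,1), 4 cases
# over (0,1)/(1,0); both marginal single-SNP distributions are balanced.
xor_toy <- function() {
  list(g1 = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
       g2 = c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L),
       phenotype = rep(0:1, each = 4L))
}
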
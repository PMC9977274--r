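# Independent brute-force oracles used to cross-check package routines.
# These are deliberately written in the most literal way possible and share
# no code with the implementation.

# Benjamini-Hochberg step-up, straight from the definition: sort p, compute
# p_(i) * m / i, enforce monotonicity from the largest rank down.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# connected components by exhaustive reachability: repeated boolean
# multiplication of (A | I) until fixpoint, then group identical rows
components_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  memb <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (memb[i] == 0L) {
      cid <- cid + 1L
      memb[reach[i, ]] <- cid
    }
  }
  memb
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into the two groups (bitmask over subsets)
mw_exact_oracle <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mid <- na * length(b) / 2
  subsets <- utils::combn(n, na)
  hits <- 0L
  for (j in seq_len(ncol(subsets))) {
    ix <- subsets[, j]
    u <- u_of(pool[ix], pool[-ix])
    if (abs(u - mid) >= abs(u_obs - mid) - 1e-9) hits <- hits + 1L
  }
  list(u = u_obs, p = hits / ncol(subsets))
}

# Welch statistic and Satterthwaite df from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# all undirected graphs on n nodes (adjacency matrices), n small
all_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(code) {
    adj <- matrix(FALSE, n, n)
    on <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    for (e in on) {
      adj[pairs[e, 1], pairs[e, 2]] <- TRUE
      adj[pairs[e, 2], pairs[e, 1]] <- TRUE
    }
    adj
  })
}

# shared small fixtures -------------------------------------------------------

toy_volume_table <- function() {
  data.frame(
    subject = c("s1", "s2", "s3", "s4", "s5", "s6"),
    group = rep(c("ENR", "STD"), each = 3),
    hippocampus = c(10, 12, 11, 8, 9, 8.5),
    cortex = c(20, 21, 22, 20, 20.5, 21.5),
    cerebellum = c(5, 5.5, 5.2, 5.1, 4.9, 5.3),
    stringsAsFactors = FALSE
  )
}

# component edge sets as canonical sorted "a|b" strings, for set comparison
edge_key <- function(edges) {
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
             sep = "|"))
}
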
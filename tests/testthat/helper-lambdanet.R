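# Shared fixtures and independent oracles for the test suite.

# Demonstration network strings (inputs to the simulator).
FIG_NET <- "((((B,C)s1)h1#H1,A)s2,(h1#H1,D)s3)r;"
FIG_NET_LENGTHS <- "((((B:1,C:1)s1:1)h1#H1:1,A:3)s2:1,(h1#H1:0.5,D:2.5)s3:1.5)r;"
BIG_NET <- paste0("(((((((6:.1,7:.1)s_6:.4,2:.5)s_1:1.1,3:1.6)s_2:3.3,4:4.9)",
                  "s_3:2)h_2#.5:1.41,5:8.31)s_4:0.1,(1:7.2,h_2#.5:.3)s_5:1.21)r;")

# Random binary gene tree: sequential pairwise merges at increasing heights.
# Independent of the package's simulator.
random_gene_tree <- function(n_tip, species = c("a", "b")) {
  sp <- sample(species, n_tip, replace = TRUE)
  labels <- paste0(sp, "_", seq_len(n_tip))
  total <- 2L * n_tip - 1L
  parent <- integer(total)
  h <- numeric(total)
  active <- seq_len(n_tip)
  nxt <- n_tip + 1L
  t <- 0
  while (length(active) > 1L) {
    t <- t + runif(1, 0.05, 1)
    pick <- sample(length(active), 2L)
    parent[active[pick]] <- nxt
    h[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  lambdanet:::new_gene_tree(parent, h, h, labels, sp)
}

# Brute-force F_ST oracle: explicit loops over pairs under the package's
# documented conventions (within = all ordered pairs including self,
# between = all cross pairs).
fst_brute <- function(m, pops) {
  dd <- function(i, j) sum(m[i, ] != m[j, ])
  lev <- unique(pops)
  idx <- lapply(lev, function(p) which(pops == p))
  hw <- numeric(2)
  for (g in 1:2) {
    tot <- 0
    for (i in idx[[g]]) for (j in idx[[g]]) tot <- tot + dd(i, j)
    hw[g] <- tot / length(idx[[g]])^2
  }
  tot <- 0
  for (i in idx[[1]]) for (j in idx[[2]]) tot <- tot + dd(i, j)
  hb <- tot / (length(idx[[1]]) * length(idx[[2]]))
  n <- (length(idx[[1]]) + length(idx[[2]])) / 2
  list(H_w = mean(hw), H_b = hb,
       fst = if (hb > 0) 1 - (n / (n - 1)) * mean(hw) / hb else NA_real_)
}

# Infinite-sites / perfect-phylogeny check with known ancestral state 0:
# every pair of columns must be nested or disjoint as sets of 1-carriers.
is_perfect_phylogeny <- function(m) {
  if (ncol(m) < 2L) return(TRUE)
  for (i in seq_len(ncol(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      a <- which(m[, i] == 1L)
      b <- which(m[, j] == 1L)
      ab <- length(intersect(a, b))
      if (ab > 0L && ab < length(a) && ab < length(b)) return(FALSE)
    }
  }
  TRUE
}

# Mean waiting-time / frequency comparison helper: |x - mu| <= k standard errors.
within_se <- function(x, mu, k = 3) {
  abs(mean(x) - mu) <= k * stats::sd(x) / sqrt(length(x))
}
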
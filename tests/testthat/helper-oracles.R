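# Independent oracles used across the suite. Each re-derives the quantity
# from first principles, by a route different from the package code.

# Sort-average-reassign quantile normalization, written directly from the
# procedure: replace the k-th smallest value of every column by the mean of
# the k-th smallest values across columns; a within-column tie takes the
# mean of the reference values over its tied ranks.
qn_oracle <- function(A) {
  ref <- rowMeans(apply(A, 2L, sort))
  out <- A
  for (j in seq_len(ncol(A))) {
    x <- A[, j]
    o <- order(x)
    res <- numeric(length(x))
    res[o] <- ref
    for (v in unique(x[duplicated(x)])) {
      res[x == v] <- mean(ref[which(x[o] == v)])
    }
    out[, j] <- res
  }
  out
}

# Benjamini-Hochberg step-up by hand: sort, scale by m/i, cumulative min
# from the least significant end, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper hypergeometric tail P(X >= x) for X ~ Hypergeom(U, n_set, n_deg),
# by explicit summation of the mass written out in binomial coefficients.
hyper_tail_oracle <- function(U, n_deg, n_set, x) {
  js <- seq.int(max(x, 0L), min(n_deg, n_set))
  if (length(js) == 0L) return(0)
  sum(exp(lchoose(n_set, js) + lchoose(U - n_set, n_deg - js) -
            lchoose(U, n_deg)))
}

# Vectorized scan of every valid (n_deg, n_set, n_overlap) at a fixed
# universe size: mass from lchoose, tails by reverse-cumulative summation
# within each margin pair, overlap running from min(n_deg, n_set) down to 0.
ease_scan_oracle <- function(U) {
  md <- rep(0:U, each = U + 1L)
  ks <- rep(0:U, times = U + 1L)
  L <- pmin(md, ks) + 1L
  mm <- rep.int(md, L)
  kk <- rep.int(ks, L)
  pos <- sequence(L)
  j <- rep.int(pmin(md, ks), L) - pos + 1L
  mass <- exp(lchoose(kk, j) + lchoose(U - kk, mm - j) - lchoose(U, mm))
  # cumulative summation restarted per margin pair: groups are contiguous,
  # so summing within split chunks keeps tiny tails free of cancellation
  grp <- rep.int(seq_along(L), L)
  fisher <- unlist(lapply(split(mass, grp), cumsum), use.names = FALSE)
  nxt <- seq_along(fisher) + 1L           # tail at j - 1 sits one slot later
  nxt[j == 0L] <- which(j == 0L)          # jackknife floors the overlap at 0
  list(n_deg = mm, n_set = kk, n_overlap = j,
       fisher = fisher, ease = fisher[nxt])
}

# Type-7 quantile (linear interpolation) by direct indexing of the sorted
# vector.
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Build a norm_matrix directly from log2-scale values (bypassing the fpkm
# roundtrip) for tests that need exact control of the input.
as_norm <- function(values, groups, filtered = TRUE, qnormed = TRUE) {
  g <- factor(groups, c("control", "treated"))
  names(g) <- colnames(values)
  permDE:::new_norm_matrix(values, g, filtered = filtered,
                           quantile_normalized = qnormed)
}

# Small simulated instance run through the public preprocessing chain.
sim_norm <- function(n_genes = 300, seed = 1, ...) {
  sim <- simulate_fpkm(sim_config(n_genes = n_genes, seed = seed, ...))
  list(norm = preprocess_fpkm(sim$fpkm), truth = sim$truth, fpkm = sim$fpkm)
}
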
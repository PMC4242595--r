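# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (summation, enumeration, brute force) without
# touching the package's implementation path.

# --- Audic-Claverie: direct log-space summation of the per-outcome mass
# P(k | x) = r^k * (x+k)! / (x! k! (1+r)^(x+k+1)),  r = N2/N1
ac_logmass <- function(k, x, r) {
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

ac_oracle <- function(x, y, N1, N2, kmax = NULL) {
  r <- N2 / N1
  kmax <- kmax %||% max(2000L, y + 200L, ceiling(4 * (x + 1) * r) + 200L)
  k <- 0:kmax
  mass <- exp(ac_logmass(k, x, r))
  stopifnot(mass[kmax + 1] < 1e-18)      # truncation sanity
  lower <- sum(mass[k <= y])
  upper <- sum(mass[k >= y])
  min(1, 2 * min(lower, upper))
}

# grid version: matrix p[x+1, y+1] for x, y in 0:nmax
ac_oracle_grid <- function(nmax, r, kmax = 4 * nmax + 4000L) {
  k <- 0:kmax
  lo <- up <- matrix(NA_real_, nmax + 1, nmax + 1)
  for (x in 0:nmax) {
    mass <- exp(ac_logmass(k, x, r))
    cs <- cumsum(mass)
    tot <- cs[kmax + 1]
    y <- 0:nmax
    lower <- cs[y + 1]
    upper <- tot - c(0, cs[y[-1]])
    lo[x + 1, ] <- lower
    up[x + 1, ] <- upper
  }
  pmin(2 * pmin(lo, up), 1)   # matrix first: pmin keeps its dim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Benjamini-Hochberg step-up, written from the definition
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# --- hypergeometric upper tail by complete enumeration (small universes)
hyper_enum <- function(set_a, set_b, universe) {
  k <- length(intersect(set_a, set_b))
  draws <- combn(universe, length(set_b))
  mean(apply(draws, 2, function(d) length(intersect(set_a, d)) >= k))
}

# --- brute-force average-linkage agglomeration on a dissimilarity matrix;
# returns merge heights and the cophenetic matrix
avg_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
      }
    }
    heights[step] <- bestd
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  list(heights = sort(heights), cophenetic = coph)
}

# uncentered-Pearson dissimilarity matrix, from the definition
uncentered_dissim <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- 1 - sum(x[i, ] * x[j, ]) /
      sqrt(sum(x[i, ]^2) * sum(x[j, ]^2))
  d
}

# --- Mantel-Haenszel log-rank chi-square from observed-minus-expected sums
logrank_oracle <- function(time, event, group1) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at <- time >= t
    nj <- sum(at); n1j <- sum(at & group1)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & group1)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  (O - E)^2 / V
}

# vectorized permutation distribution of the log-rank chi-square
logrank_perm_p <- function(time, event, group1, nperm = 1e4, seed = 42) {
  set.seed(seed)
  ts <- sort(unique(time[event == 1]))
  A <- outer(ts, time, function(t, ti) as.numeric(ti >= t))      # risk sets
  B <- outer(ts, time, function(t, ti) as.numeric(ti == t)) *
    rep(event, each = length(ts))                                 # deaths
  nj <- A %*% rep(1, length(time))
  dj <- B %*% rep(1, length(time))
  chi2_of <- function(g) {
    n1j <- A %*% g; d1j <- B %*% g
    O <- sum(d1j); E <- sum(dj * n1j / nj)
    keep <- nj > 1
    V <- sum((dj * (n1j / nj) * (1 - n1j / nj) *
                (nj - dj) / (nj - 1))[keep])
    (O - E)^2 / V
  }
  obs <- chi2_of(as.numeric(group1))
  perm <- replicate(nperm, chi2_of(sample(as.numeric(group1))))
  mean(perm >= obs - 1e-12)
}

# --- Efron-tie Cox partial log-likelihood (single covariate), plus a
# grid-search maximizer
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R])); sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

efron_grid_max <- function(time, event, x, lo = -4, hi = 4) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, efron_loglik, numeric(1), time, event, x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-5)
  llf <- vapply(fine, efron_loglik, numeric(1), time, event, x)
  fine[which.max(llf)]
}

# --- brute-force <=1-mismatch tag mapper over a whole catalog
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

map_oracle <- function(tags, cat_seq, cat_unit) {
  # cat_unit: gene id, or a per-row ".siteN" label for unannotated sites
  vapply(tags, function(tg) {
    d <- vapply(cat_seq, hamming, numeric(1), a = tg)
    best <- min(d)
    if (best > 1) return("")                       # unmapped
    units <- unique(cat_unit[d == best])
    if (length(units) > 1) return(NA_character_)   # ambiguous
    if (grepl("^\\.site", units)) "" else units    # lone non-genic site
  }, character(1), USE.NAMES = FALSE)
}

# adjusted Rand index from the contingency-table formula
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(sum(tab), 2)
  (a - e) / ((b + cc) / 2 - e)
}

# random distinct 21-bp tags starting with CATG and containing no second
# CATG in their first 8 bases (keeps the planted site canonical when laid
# out on a synthetic genome)
random_tags <- function(n, seed = 1) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    tg <- paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, TRUE),
                               collapse = ""))
    if (substr(tg, 5, 8) != "CATG" && !tg %in% out) out <- c(out, tg)
  }
  out
}

# inject k substitutions into a tag
mutate_tag <- function(tag, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(tag, "")[[1]]
  pos <- sample(21, k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# minimal synthetic catalog built directly from tag sequences (one gene per
# tag), bypassing genome construction
catalog_from_tags <- function(seqs, genes = sprintf("g%04d", seq_along(seqs))) {
  ann <- data.frame(chrom = "chr1",
                    start = (seq_along(seqs) - 1) * 30L,
                    end = (seq_along(seqs) - 1) * 30L + 25L,
                    name = paste0(genes, ".t1"), score = 0L, strand = "+",
                    stringsAsFactors = FALSE)
  chars <- rep("T", max(ann$end))
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    chars[(ann$start[i] + 1):(ann$start[i] + 21)] <- s
  }
  genome <- setNames(paste(chars, collapse = ""), "chr1")
  build_tag_catalog(genome, ann)
}
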
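# Independent brute-force oracles used across the suite. These deliberately
# use per-bp boolean arrays, exact enumeration, and textbook definitions --
# never the package's own code paths.

# Per-bp bitmap of a set of intervals (0-based half-open data frame) over a
# genome given as named chromosome lengths.
bitmap_of <- function(df, chrom_sizes) {
  bm <- lapply(chrom_sizes, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    idx <- (df$start[i] + 1):df$end[i]
    bm[[df$chrom[i]]][idx] <- TRUE
  }
  bm
}

bitmap_union_bp <- function(df, chrom_sizes) {
  sum(vapply(bitmap_of(df, chrom_sizes), sum, numeric(1)))
}

bitmap_intersect_bp <- function(a, b, chrom_sizes) {
  ba <- bitmap_of(a, chrom_sizes)
  bb <- bitmap_of(b, chrom_sizes)
  sum(mapply(function(x, y) sum(x & y), ba, bb))
}

# GRanges -> 0-based half-open data frame
gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Random interval data frame on a small genome
random_intervals <- function(n, chrom_sizes, max_w = 50) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_sizes[chrom] - w))
  data.frame(chrom = chrom, start = start, end = start + w,
             stringsAsFactors = FALSE)
}

# Textbook Benjamini-Hochberg step-up: find largest k with
# p_(k) <= k/m * q is equivalent to the adjusted values below.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Exact hypergeometric upper tail P(X >= k) by direct summation of the
# probability mass written with choose().
hyper_upper_oracle <- function(k, K, n_draw, N) {
  lo <- max(0, k)
  hi <- min(K, n_draw)
  if (lo > hi) return(0)
  kk <- lo:hi
  sum(choose(K, kk) * choose(N - K, n_draw - kk)) / choose(N, n_draw)
}

hyper_lower_oracle <- function(k, K, n_draw, N) {
  lo <- max(0, n_draw - (N - K))
  hi <- min(k, K, n_draw)
  if (lo > hi) return(0)
  kk <- lo:hi
  sum(choose(K, kk) * choose(N - K, n_draw - kk)) / choose(N, n_draw)
}

# Mann-Whitney U by brute-force pair counting (ties count one half).
u_oracle <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Small default genome for interval tests
tiny_genome <- c(chrA = 10000, chrB = 8000)

make_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}
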
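# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the stats:: shortcuts) used by the package itself.

# exact two-sided binomial p vs 0.5 by full enumeration of point masses:
# total probability of outcomes no more likely than the observed one
oracle_binom_p <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Clopper-Pearson bounds by root-finding on the exact binomial tail sums
oracle_cp <- function(k, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lo <- if (k == 0) 0 else {
    uniroot(
      function(p) sum(dbinom(k:n, n, p)) - a,
      c(1e-12, 1 - 1e-12), tol = 1e-12
    )$root
  }
  hi <- if (k == n) 1 else {
    uniroot(
      function(p) sum(dbinom(0:k, n, p)) - a,
      c(1e-12, 1 - 1e-12), tol = 1e-12
    )$root
  }
  c(lo = lo, hi = hi)
}

# Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n2 <- c + d       # row 2 total
  k <- a + c        # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings,
# doubling the smaller tail (midranks for ties)
oracle_mw_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(r), nx)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  tol <- 1e-9
  p_lo <- mean(sums <= obs + tol)
  p_hi <- mean(sums >= obs - tol)
  min(1, 2 * min(p_lo, p_hi))
}

# naive pileup: walk each SAM record's CIGAR in R and tally the base covering
# each requested 1-based position, honoring base/mapping-quality filters
oracle_pileup <- function(sam_path, positions, min_bq = 20, min_mq = 20) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- matrix(
    0L, nrow = length(positions), ncol = 4,
    dimnames = list(NULL, c("A", "C", "G", "T"))
  )
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x100) > 0 || bitwAnd(flag, 0x400) > 0 ||
        bitwAnd(flag, 0x800) > 0 || bitwAnd(flag, 0x4) > 0) {
      next
    }
    if (as.integer(f[5]) < min_mq) next
    pos <- as.integer(f[4])
    cigar <- f[6]
    seq <- f[10]
    qual <- f[11]
    ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    rpos <- pos   # reference pointer (1-based)
    qpos <- 1L    # query pointer (1-based)
    for (i in seq_along(ops)) {
      len <- ops_len[i]
      op <- ops[i]
      if (op %in% c("M", "=", "X")) {
        hit <- which(positions >= rpos & positions <= rpos + len - 1L)
        for (h in hit) {
          off <- positions[h] - rpos
          q <- utf8ToInt(substr(qual, qpos + off, qpos + off)) - 33L
          if (q >= min_bq) {
            b <- substr(seq, qpos + off, qpos + off)
            if (b %in% colnames(counts)) {
              counts[h, b] <- counts[h, b] + 1L
            }
          }
        }
        rpos <- rpos + len
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      }
    }
  }
  counts
}

# naive junction counter: per SAM record, read the N gaps straight off the
# CIGAR string and match them to (donor_end0, acceptor_start0) pairs
oracle_junction_counts <- function(sam_path, junctions, min_overhang = 6) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- integer(nrow(junctions))
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    pos <- as.integer(f[4])
    cigar <- f[6]
    ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    # collapse to reference blocks separated by N
    blk_start <- integer(0); blk_end <- integer(0)
    cur_start <- pos; cur_end <- pos - 1L
    for (i in seq_along(ops)) {
      len <- ops_len[i]
      if (ops[i] %in% c("M", "D", "=", "X")) {
        cur_end <- cur_end + len
      } else if (ops[i] == "N") {
        blk_start <- c(blk_start, cur_start); blk_end <- c(blk_end, cur_end)
        cur_start <- cur_end + len + 1L
        cur_end <- cur_end + len
      }
    }
    blk_start <- c(blk_start, cur_start); blk_end <- c(blk_end, cur_end)
    if (length(blk_start) < 2) next
    for (j in seq_len(nrow(junctions))) {
      d0 <- junctions$donor_end[j]
      a0 <- junctions$acceptor_start[j]
      seen <- FALSE
      for (b in seq_len(length(blk_start) - 1L)) {
        if (blk_end[b] == d0 && blk_start[b + 1L] == a0 + 1L &&
            blk_end[b] - blk_start[b] + 1L >= min_overhang &&
            blk_end[b + 1L] - blk_start[b + 1L] + 1L >= min_overhang) {
          seen <- TRUE
        }
      }
      if (seen) out[j] <- out[j] + 1L
    }
  }
  names(out) <- junctions$junction
  out
}
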
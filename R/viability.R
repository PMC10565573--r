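#' Normalize growth-in-low-attachment viability to Day 0
#'
#' Each Day-8 luminescence value is divided by the mean of its cell line's
#' four Day-0 technical replicates (per biological replicate, since each
#' biological replicate has its own Day-0 plate), so normalized values are
#' fold-growth relative to the plating signal.
#'
#' @param plate Long-format tibble with columns `line`, `bio_rep`,
#'   `tech_rep`, `day` (0 or 8) and `value` (raw luminescence, arbitrary
#'   units, non-negative).
#' @return Tibble of the Day-8 rows with added `day0_mean` and `value_norm`.
#' @export
normalize_viability <- function(plate) {
  x <- as_tibble(plate)
  stopifnot(all(c("line", "bio_rep", "tech_rep", "day", "value") %in% names(x)))
  if (any(x$value < 0)) abort("raw viability values must be non-negative")
  if (!all(x$day %in% c(0, 8))) abort("`day` must be 0 or 8")
  d0 <- x |>
    filter(.data$day == 0) |>
    group_by(.data$line, .data$bio_rep) |>
    summarise(
      day0_mean = mean(.data$value), day0_n = n(), .groups = "drop"
    )
  if (any(d0$day0_mean == 0)) {
    abort("Day-0 mean is zero for at least one line/replicate")
  }
  d8 <- x |> filter(.data$day == 8)
  missing <- anti_join(d8, d0, by = c("line", "bio_rep"))
  if (nrow(missing) > 0) {
    abort("Day-8 wells without matching Day-0 replicates")
  }
  d8 |>
    inner_join(d0, by = c("line", "bio_rep")) |>
    mutate(value_norm = .data$value / .data$day0_mean)
}

#' Exact Mann-Whitney rank-sum test
#'
#' The U statistic is computed from midranks (average ranks over ties). The
#' two-sided p-value is exact — the rank-sum distribution over all
#' `choose(n, n_a)` group labelings of the observed (possibly tied) ranks,
#' computed by dynamic programming — whenever the combined sample size is at
#' most `exact_limit`; larger samples use the normal approximation with tie
#' correction. Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y Numeric vectors, the two groups (e.g. normalized viability of
#'   two cell lines).
#' @param exact_limit Largest combined sample size for exact enumeration
#'   (default 20).
#' @return One-row tibble: `n_x`, `n_y`, `u_x`, `u_y`, `statistic` (`u_x`),
#'   `p_value`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_limit = 20) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  ux <- rx - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  if (n <= exact_limit) {
    # exact null distribution of the group-x rank sum over all labelings,
    # on doubled midranks so tied ranks stay integral
    r2 <- as.integer(round(2 * r))
    dist <- rank_sum_distribution(r2, nx)
    obs <- as.integer(round(2 * rx))
    total <- sum(dist$count)
    p_lo <- sum(dist$count[dist$sum <= obs]) / total
    p_hi <- sum(dist$count[dist$sum >= obs]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact-enumeration"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (ux - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approx-ties"
  }
  tibble(
    n_x = nx, n_y = ny, u_x = ux, u_y = uy, statistic = ux,
    p_value = p, method = method
  )
}

# count, for every achievable rank sum s, the number of size-k subsets of the
# integer rank vector `ranks` summing to s (classic subset-sum DP)
rank_sum_distribution <- function(ranks, k) {
  smax <- sum(sort(ranks, decreasing = TRUE)[seq_len(k)])
  smin <- sum(sort(ranks)[seq_len(k)])
  # dp[j + 1, s + 1] = number of subsets of size j with sum s
  dp <- matrix(0, nrow = k + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (rk in ranks) {
    jmax <- k
    for (j in seq(jmax, 1)) {
      nz <- which(dp[j, ] > 0)
      if (length(nz) > 0) {
        tgt <- nz + rk
        keep <- tgt <= smax + 1
        dp[j + 1, tgt[keep]] <- dp[j + 1, tgt[keep]] + dp[j, nz[keep]]
      }
    }
  }
  sums <- which(dp[k + 1, ] > 0) - 1
  tibble(sum = sums, count = dp[k + 1, sums + 1])
}

#' Pairwise viability comparisons between cell lines
#'
#' Normalizes the plate (see [normalize_viability()]) and runs
#' [rank_sum_test()] for every pair of lines, either on all normalized
#' technical-replicate values (default, mirroring per-well plotting) or on
#' biological-replicate means (`aggregate = "biological"`).
#'
#' @inheritParams normalize_viability
#' @param aggregate `"none"` (test all technical replicates) or
#'   `"biological"` (average technical replicates per biological replicate
#'   first).
#' @param exact_limit Passed to [rank_sum_test()].
#' @return Tibble with one row per line pair: `line_a`, `line_b`, the group
#'   sizes, `statistic`, `p_value`, `method`.
#' @export
viability_tests <- function(plate, aggregate = c("none", "biological"),
                            exact_limit = 20) {
  aggregate <- match.arg(aggregate)
  norm <- normalize_viability(plate)
  vals <- if (aggregate == "biological") {
    norm |>
      group_by(.data$line, .data$bio_rep) |>
      summarise(value_norm = mean(.data$value_norm), .groups = "drop")
  } else {
    norm
  }
  lines <- sort(unique(vals$line))
  pairs <- utils::combn(lines, 2, simplify = FALSE)
  map(pairs, function(pr) {
    a <- vals$value_norm[vals$line == pr[1]]
    b <- vals$value_norm[vals$line == pr[2]]
    rank_sum_test(a, b, exact_limit) |>
      mutate(line_a = pr[1], line_b = pr[2], .before = 1)
  }) |>
    bind_rows()
}
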
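model <- example_gene_model()
site_tbl <- dplyr::mutate(model$snvs, contig = model$contig)

test_that("allele fractions are arithmetic on informative reads only", {
  rna <- make_counts(ref_count = 10, alt_count = 90, material = "RNA")
  het <- make_counts(ref_count = 50, alt_count = 50) |> call_zygosity()
  fr <- allele_fraction(rna, het)
  expect_equal(fr$f_rna, 0.9)
  expect_equal(fr$informative, 100L)

  # third-allele noise excluded from the denominator, reported separately
  noisy <- make_counts(
    ref_count = 25, alt_count = 25, other = c(T = 5L), material = "RNA"
  )
  fr2 <- allele_fraction(noisy, het)
  expect_equal(fr2$f_rna, 0.5)
  expect_equal(fr2$noise_count, 5L)
  ora <- oracle_cp(25, 50)
  expect_equal(fr2$ci_lo, unname(ora["lo"]), tolerance = 1e-6)
  expect_equal(fr2$ci_hi, unname(ora["hi"]), tolerance = 1e-6)

  # no informative reads at all -> undefined fraction, insufficient verdict
  empty <- make_counts(
    ref_count = 0, alt_count = 0, other = c(T = 5L), material = "RNA"
  )
  fr3 <- allele_fraction(empty, het) |> test_imbalance()
  expect_true(is.na(fr3$f_rna))
  expect_equal(fr3$verdict, "insufficient")
})

test_that("imbalance verdicts follow the exact binomial test and effect floor", {
  null_site <- test_imbalance(make_fraction_row(50, 50))
  expect_equal(null_site$p_value, 1)
  expect_equal(null_site$verdict, "balanced")

  # monoallelic expression: the 'close to 100%' extreme
  mono <- test_imbalance(make_fraction_row(0, 100))
  expect_equal(mono$verdict, "imbalanced")
  expect_lt(mono$p_value, 1e-25)

  seventy <- test_imbalance(make_fraction_row(30, 70))
  expect_equal(seventy$p_value, oracle_binom_p(70, 100), tolerance = 1e-12)
  expect_equal(seventy$verdict, "imbalanced")

  # significant but tiny effect at huge depth stays 'balanced'
  deep <- test_imbalance(make_fraction_row(4700, 5300))
  expect_lt(deep$q_value, 0.05)
  expect_equal(deep$verdict, "balanced")
})

test_that("relabeling alleles flips the fraction but not the inference", {
  set.seed(21)
  rows <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_fraction_row(sample(0:80, 1), sample(0:80, 1), pos = i)
  }))
  flipped <- rows
  tmp <- flipped$ref_count
  flipped$ref_count <- flipped$alt_count
  flipped$alt_count <- tmp
  flipped$f_rna <- flipped$alt_count / flipped$informative
  a <- test_imbalance(rows)
  b <- test_imbalance(flipped)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$q_value, b$q_value)
  expect_equal(a$verdict, b$verdict)
  expect_equal(a$f_rna, 1 - b$f_rna)
})

test_that("BH adjustment is monotone in p-rank and bounded by one", {
  set.seed(22)
  rows <- dplyr::bind_rows(lapply(1:20, function(i) {
    make_fraction_row(sample(5:60, 1), sample(5:60, 1), pos = i)
  }))
  res <- test_imbalance(rows, min_depth = 10)
  expect_true(all(res$q_value <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  o <- order(res$p_value)
  expect_true(!is.unsorted(res$q_value[o]))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("pooled fraction equals the depth-weighted mean of site fractions", {
  set.seed(23)
  rows <- dplyr::bind_rows(lapply(1:8, function(i) {
    make_fraction_row(sample(10:100, 1), sample(10:100, 1), pos = i)
  }))
  res <- test_imbalance(rows)
  s <- summarize_sample(res)
  expect_equal(
    s$pooled_fraction,
    sum(res$f_rna * res$informative) / sum(res$informative)
  )
  expect_lte(s$n_imbalanced, s$n_het_sites)
})

test_that("sample verdicts behave under null and strong-ASE simulations", {
  # strong ASE: theta 0.95, 8 sites, depth 150 -> imbalanced essentially always
  hits <- vapply(1:60, function(s) {
    sim <- simulate_counts(
      model, sim_truth(theta_rna = 0.95, depth_rna = 150, seed = 3000 + s)
    )
    imb <- test_imbalance(allele_fraction(sim$rna, site_tbl))
    summarize_sample(imb)$verdict == "imbalanced"
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # null: sample-level false-positive rate stays below alpha + 3 MC SE
  fp <- vapply(1:300, function(s) {
    sim <- simulate_counts(
      model, sim_truth(theta_rna = 0.5, depth_rna = 150, seed = 40000 + s)
    )
    imb <- test_imbalance(allele_fraction(sim$rna, site_tbl))
    summarize_sample(imb)$verdict == "imbalanced"
  }, logical(1))
  expect_lte(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / length(fp)))

  expect_equal(summarize_sample(make_fraction_row(0, 0) |> test_imbalance())$verdict, "insufficient")
})

test_that("per-site exact test holds its size under the null", {
  # analytic attained level of the discrete exact test at Poisson(150) depths;
  # the Monte-Carlo rejection rate must sit within 3 SE of it and below alpha
  rej_region_mass <- function(n) {
    k <- 0:n
    p <- pmin(1, 2 * pbinom(pmin(k, n - k), n, 0.5))
    sum(dbinom(k, n, 0.5)[p < 0.05])
  }
  ns <- 60:260
  w <- dpois(ns, 150)
  attained <- sum(w * vapply(ns, rej_region_mass, numeric(1))) / sum(w)
  set.seed(77)
  n_sites <- 20000
  depth <- rpois(n_sites, 150)
  alt <- rbinom(n_sites, depth, 0.5)
  p <- binom_p_half(alt, depth)
  rate <- mean(p < 0.05, na.rm = TRUE)
  expect_lte(rate, 0.05)
  expect_lt(abs(rate - attained), 3 * sqrt(attained * (1 - attained) / n_sites))
})

test_that("tumor/normal contrast flags only tumor-specific imbalance", {
  tum <- simulate_counts(
    model, sim_truth(theta_rna = 0.95, depth_rna = 150, seed = 61),
    sample = "t", condition = "tumor"
  )
  nrm <- simulate_counts(
    model, sim_truth(theta_rna = 0.5, depth_rna = 150, seed = 62),
    sample = "n", condition = "normal"
  )
  ti <- test_imbalance(allele_fraction(tum$rna, site_tbl))
  ni <- test_imbalance(allele_fraction(nrm$rna, site_tbl))
  ct <- compare_tumor_normal(ti, ni)
  expect_true(ct$tumor_specific)
  g <- glance(ct)
  expect_equal(g$tumor_verdict, "imbalanced")
  expect_equal(g$normal_verdict, "balanced")
  expect_equal(nrow(tidy(ct)), 8L)

  # identical tables: Fisher p = 1 everywhere, no flag
  ct2 <- compare_tumor_normal(ti, ti)
  expect_false(ct2$tumor_specific)
  expect_true(all(ct2$sites$fisher_p > 1 - 1e-7))

  # disjoint site sets cannot be contrasted
  ni_moved <- dplyr::mutate(ni, pos = pos + 10000L)
  expect_error(compare_tumor_normal(ti, ni_moved), "share no")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(
    compare_tumor_normal(
      make_fraction_row(10, 90) |> test_imbalance(),
      make_fraction_row(50, 50) |> test_imbalance()
    )$sites$fisher_p,
    oracle_fisher_p(90, 10, 50, 50),
    tolerance = 1e-9
  )
  set.seed(31)
  for (i in 1:30) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    c2 <- sample(0:40, 1); d2 <- sample(0:40, 1)
    if ((a + b) == 0 || (c2 + d2) == 0) next
    got <- compare_tumor_normal(
      make_fraction_row(b, a) |> test_imbalance(min_depth = 0),
      make_fraction_row(d2, c2) |> test_imbalance(min_depth = 0)
    )$sites$fisher_p
    expect_equal(got, oracle_fisher_p(a, b, c2, d2), tolerance = 1e-9)
  }
})
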
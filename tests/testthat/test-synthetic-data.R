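model <- example_gene_model()

test_that("simulated counts conserve depth and respect degenerate settings", {
  for (seed in 1:5) {
    sim <- simulate_counts(model, sim_truth(seed = seed))
    for (tb in list(sim$dna, sim$rna)) {
      expect_equal(tb$n_a + tb$n_c + tb$n_g + tb$n_t + tb$n_other, tb$depth)
    }
  }
  # no skipping configured -> exclusion junction silent
  sim0 <- simulate_counts(
    model, sim_truth(theta_rna = 0.5, psi_ref = 0, psi_alt = 0, seed = 4)
  )
  expect_equal(sim0$junctions$exclusion, 0L)
  # degenerate haplotype fraction, error-free: every RNA read carries alt
  sim1 <- simulate_counts(
    model, sim_truth(theta_rna = 1, error_rate = 0, depth_rna = 100, seed = 5)
  )
  cc <- cbind(A = sim1$rna$n_a, C = sim1$rna$n_c, G = sim1$rna$n_g,
              T = sim1$rna$n_t)
  alt_n <- cc[cbind(seq_len(nrow(cc)), match(sim1$rna$alt, colnames(cc)))]
  expect_equal(alt_n, sim1$rna$depth)
})

test_that("sim_truth rejects out-of-range probabilities", {
  expect_error(sim_truth(theta_rna = 1.2), "probabilities")
  expect_error(sim_truth(error_rate = -0.1), "probabilities")
})

test_that("pooled alt fraction tracks configured theta (Monte Carlo)", {
  # theta 0.9, error 0.001, depth 200, 8 sites: adjusted theta' = 0.89943,
  # pooled informative reads ~ 1600 so 0.05 is ~6.7 binomial SE
  truth <- sim_truth(
    theta_rna = 0.9, error_rate = 0.001, depth_rna = 200, seed = 77
  )
  sim <- simulate_counts(model, truth)
  fr <- allele_fraction(sim$rna, model$snvs |>
    dplyr::mutate(contig = model$contig))
  pooled <- sum(fr$alt_count) / sum(fr$informative)
  expect_lt(abs(pooled - 0.9), 0.05)

  # error-free mean over replicates within 3 MC standard errors of theta
  reps <- vapply(1:60, function(s) {
    sim <- simulate_counts(
      model, sim_truth(theta_rna = 0.7, error_rate = 0, seed = 1000 + s)
    )
    fr <- allele_fraction(sim$rna, model$snvs |>
      dplyr::mutate(contig = model$contig))
    sum(fr$alt_count) / sum(fr$informative)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.7), 3 * se + 1e-9)
})

test_that("identical seeds give byte-identical count tables and SAM text", {
  truth <- sim_truth(theta_rna = 0.8, psi_alt = 0.5, seed = 99)
  s1 <- simulate_counts(model, truth)
  s2 <- simulate_counts(model, truth)
  expect_identical(s1$dna, s2$dna)
  expect_identical(s1$rna, s2$rna)
  expect_identical(s1$junctions, s2$junctions)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a1 <- simulate_alignments(model, truth, dir = d1)
  a2 <- simulate_alignments(model, truth, dir = d2)
  expect_identical(readLines(a1$dna_sam), readLines(a2$dna_sam))
  expect_identical(readLines(a1$rna_sam), readLines(a2$rna_sam))
  expect_identical(readLines(a1$truth_vcf), readLines(a2$truth_vcf))
})

test_that("simulated SAM validates and truth sidecars round-trip", {
  d <- withr::local_tempdir()
  truth <- sim_truth(theta_rna = 0.9, psi_alt = 0.9, seed = 21)
  al <- simulate_alignments(model, truth, dir = d)
  # strict format check: conversion to (sorted, indexed) BAM must succeed
  for (sam in c(al$dna_sam, al$rna_sam)) {
    bam <- Rsamtools::asBam(
      sam, destination = tempfile(), overwrite = TRUE,
      indexDestination = FALSE
    )
    expect_true(file.exists(bam))
  }
  sites <- read_sites(al$truth_vcf)
  expect_equal(sites$pos, model$snvs$pos)
  expect_equal(sites$ref, model$snvs$ref)
  expect_equal(sites$alt, model$snvs$alt)
  side <- jsonlite::read_json(al$truth_json)
  expect_equal(side$theta_rna, truth$theta_rna)
  expect_equal(side$seed, truth$seed)
})

test_that("alignment route and count route agree in distribution", {
  # pooled RNA alt fractions from the two generators over replicate seeds
  site_tbl <- model$snvs |> dplyr::mutate(contig = model$contig)
  pooled_counts <- numeric(12)
  pooled_align <- numeric(12)
  for (i in seq_along(pooled_counts)) {
    truth <- sim_truth(
      theta_rna = 0.8, depth_dna = 30, depth_rna = 50, seed = 500 + i
    )
    sc <- simulate_counts(model, truth)
    fr <- allele_fraction(sc$rna, site_tbl)
    pooled_counts[i] <- sum(fr$alt_count) / sum(fr$informative)
    d <- withr::local_tempdir()
    al <- simulate_alignments(model, truth, dir = d)
    rc <- count_alleles(al$rna_sam, site_tbl, material = "RNA")
    fa <- allele_fraction(rc, site_tbl)
    pooled_align[i] <- sum(fa$alt_count) / sum(fa$informative)
  }
  wt <- suppressWarnings(wilcox.test(pooled_counts, pooled_align))
  expect_gt(wt$p.value, 0.01)
})

test_that("reads shorter than two bases are rejected", {
  expect_error(
    simulate_alignments(model, sim_truth(), read_length = 1),
    "read_length"
  )
})

test_that("gene model invariants are enforced", {
  ex <- tibble::tibble(start = c(0L, 100L, 200L), end = c(50L, 150L, 250L))
  snv <- tibble::tibble(pos = 10L, ref = "A", alt = "G")
  expect_s3_class(gene_model("c", ex, 2L, snv), "gene_model")
  expect_error(gene_model("c", ex, 1L, snv), "interior")
  expect_error(gene_model("c", ex, 2L, tibble::tibble(pos = 60L, ref = "A", alt = "G")), "outside exons")
  expect_error(gene_model("c", ex, 2L, tibble::tibble(pos = 10L, ref = "A", alt = "A")), "must differ")
  overlapping <- tibble::tibble(start = c(0L, 40L, 200L), end = c(50L, 150L, 250L))
  expect_error(gene_model("c", overlapping, 2L, snv), "non-overlapping")
})

test_that("gene model exons survive a BED round trip", {
  d <- withr::local_tempdir()
  bed <- file.path(d, "model.bed")
  write_model_bed(model, bed)
  back <- read_model_bed(bed, snvs = model$snvs)
  expect_equal(back$exons, model$exons)
  expect_equal(back$cassette_exon, model$cassette_exon)
  expect_equal(back$junctions, model$junctions)
})
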
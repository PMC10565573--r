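#' Ground-truth parameters for a synthetic sample
#'
#' Bundles the generative parameters of one synthetic tumor or normal sample:
#' the DNA alternate-allele fraction `theta_dna` (0.5 for a germline
#' heterozygote), the RNA alternate-haplotype fraction `theta_rna` (deviates
#' from 0.5 under allele-specific expression), the per-haplotype probability
#' that a transcript skips the cassette exon (`psi_ref`, `psi_alt`), mean
#' sequencing depths, the per-base error rate, and the seed that makes the
#' sample reproducible.
#'
#' Defaults are the study conditions the generator emulates: germline
#' heterozygosity (`theta_dna = 0.5`), balanced expression and no skipping
#' unless asked for, whole-exome-like DNA depth of 80x, RNA depth of 150x
#' (junction coverage follows RNA depth), and an Illumina-like substitution
#' error rate of 0.001.
#'
#' @param theta_dna DNA alt fraction in `[0, 1]` (scalar, applies to all sites).
#' @param theta_rna RNA alt-haplotype fraction in `[0, 1]`.
#' @param psi_ref,psi_alt Probability that a transcript from the ref / alt
#'   haplotype skips the cassette exon.
#' @param depth_dna,depth_rna Mean per-site read depth (Poisson) for DNA / RNA.
#' @param depth_junction Mean per-junction read depth; defaults to `depth_rna`.
#' @param error_rate Per-base substitution error probability (misread base is
#'   uniform over the three other bases).
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `sim_truth` (a named list).
#' @export
sim_truth <- function(theta_dna = 0.5, theta_rna = 0.5,
                      psi_ref = 0, psi_alt = 0,
                      depth_dna = 80, depth_rna = 150,
                      depth_junction = depth_rna,
                      error_rate = 0.001, seed = 1L) {
  probs <- c(
    theta_dna = theta_dna, theta_rna = theta_rna, psi_ref = psi_ref,
    psi_alt = psi_alt, error_rate = error_rate
  )
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  stopifnot(depth_dna >= 0, depth_rna >= 0, depth_junction >= 0)
  structure(
    list(
      theta_dna = theta_dna, theta_rna = theta_rna,
      psi_ref = psi_ref, psi_alt = psi_alt,
      depth_dna = depth_dna, depth_rna = depth_rna,
      depth_junction = depth_junction,
      error_rate = error_rate, seed = as.integer(seed)
    ),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> theta_dna=%.3g theta_rna=%.3g psi=(%.3g,%.3g) depth=(%g,%g) err=%.3g seed=%d\n",
    x$theta_dna, x$theta_rna, x$psi_ref, x$psi_alt,
    x$depth_dna, x$depth_rna, x$error_rate, x$seed
  ))
  invisible(x)
}

# expected exclusion-junction read fraction under the haplotype mixture
mixture_skip_fraction <- function(truth) {
  truth$theta_rna * truth$psi_alt + (1 - truth$theta_rna) * truth$psi_ref
}

# draw observed base counts at one site: depth reads whose true allele is alt
# with probability theta, each read then misread to a uniform other base with
# probability err
draw_site_counts <- function(depth, theta, ref, alt, err) {
  bases <- c("A", "C", "G", "T")
  counts <- setNames(integer(4), bases)
  true_alt <- rbinom(1L, depth, theta)
  true_ref <- depth - true_alt
  for (b in list(c(alt, true_alt), c(ref, true_ref))) {
    base <- b[1]
    nb <- as.integer(b[2])
    wrong <- rbinom(1L, nb, err)
    counts[base] <- counts[base] + nb - wrong
    if (wrong > 0) {
      others <- sample(setdiff(bases, base), wrong, replace = TRUE)
      tab <- table(others)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  counts
}

#' Simulate per-site allele-count tables and junction counts
#'
#' Draws DNA and RNA allele counts at every SNV site of the model plus the
#' three junction counts, from the generative model the analysis assumes:
#' per-site depth is Poisson around the configured mean; the alternate-read
#' count is binomial with success probability `theta` adjusted for sequencing
#' error (`theta * (1 - e) + (1 - theta) * e / 3`); junction reads are a
#' haplotype mixture with exclusion fraction
#' `theta_rna * psi_alt + (1 - theta_rna) * psi_ref`, with each isoform
#' covering its own junction(s) at the configured junction depth.
#'
#' @param model A [gene_model()].
#' @param truth A [sim_truth()].
#' @param sample Sample label stored in the output tables.
#' @param condition `"tumor"` or `"normal"` tag stored in the output tables.
#' @return A list of class `sim_counts` with elements `dna`, `rna` (site
#'   allele-count tibbles), `junctions` (one-row junction-count tibble) and
#'   `truth` (the input echoed back).
#' @examples
#' sim <- simulate_counts(example_gene_model(), sim_truth(theta_rna = 0.9, seed = 7))
#' sim$rna
#' @export
simulate_counts <- function(model, truth, sample = "sim_sample",
                            condition = "tumor") {
  stopifnot(inherits(model, "gene_model"), inherits(truth, "sim_truth"))
  withr::with_seed(truth$seed, {
    draw_tbl <- function(mean_depth, theta, material) {
      depth <- rpois(nrow(model$snvs), mean_depth)
      mat <- t(mapply(
        draw_site_counts,
        depth = depth, ref = model$snvs$ref, alt = model$snvs$alt,
        MoreArgs = list(theta = theta, err = truth$error_rate)
      ))
      tibble(
        contig = model$contig,
        pos = model$snvs$pos,
        ref = model$snvs$ref,
        alt = model$snvs$alt,
        n_a = as.integer(mat[, "A"]),
        n_c = as.integer(mat[, "C"]),
        n_g = as.integer(mat[, "G"]),
        n_t = as.integer(mat[, "T"]),
        n_other = 0L,
        depth = as.integer(depth),
        sample = sample,
        material = material,
        condition = condition
      )
    }
    dna <- draw_tbl(truth$depth_dna, truth$theta_dna, "DNA")
    rna <- draw_tbl(truth$depth_rna, truth$theta_rna, "RNA")
    e <- mixture_skip_fraction(truth)
    junctions <- tibble(
      sample = sample,
      inclusion_upstream = rpois(1L, truth$depth_junction * (1 - e)),
      inclusion_downstream = rpois(1L, truth$depth_junction * (1 - e)),
      exclusion = rpois(1L, truth$depth_junction * e)
    )
    structure(
      list(dna = dna, rna = rna, junctions = junctions, truth = truth),
      class = "sim_counts"
    )
  })
}
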
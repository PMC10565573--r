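#' RNA allele fraction at heterozygous sites
#'
#' Joins RNA allele counts to the heterozygous calls made from DNA and
#' computes, per site, the fraction of informative RNA reads carrying the
#' alternate allele — the quantity plotted as "percent non-reference allele"
#' in per-sample ASE panels — together with its exact Clopper-Pearson
#' interval. Bases other than the site's ref/alt are excluded from the
#' denominator and reported in `noise_count`.
#'
#' @param rna_counts RNA site allele-count tibble (`material == "RNA"`).
#' @param het_calls Zygosity-call tibble ([call_zygosity()] output) or any
#'   site table with `contig`, `pos`, `ref`, `alt`; only rows with
#'   `call == "het"` are used when a `call` column is present.
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `noise_count`, `informative`, `f_rna`, `ci_lo`, `ci_hi`,
#'   `sample`.
#' @export
allele_fraction <- function(rna_counts, het_calls, conf_level = 0.95) {
  rna_counts <- as_tibble(rna_counts)
  if (!all(rna_counts$material == "RNA")) {
    abort("allele_fraction() expects RNA counts (material == 'RNA')")
  }
  het_calls <- as_tibble(het_calls)
  if ("call" %in% names(het_calls)) {
    het_calls <- het_calls |> filter(.data$call == "het")
  }
  sites <- het_calls |> select("contig", "pos", "ref", "alt")
  x <- sites |>
    inner_join(
      rna_counts |> select(-dplyr::any_of(c("ref", "alt"))),
      by = c("contig", "pos")
    )
  cc <- base_counts_matrix(x)
  idx <- seq_len(nrow(x))
  ref_count <- as.integer(cc[cbind(idx, match(x$ref, colnames(cc)))])
  alt_count <- as.integer(cc[cbind(idx, match(x$alt, colnames(cc)))])
  informative <- ref_count + alt_count
  ci <- clopper_pearson(alt_count, informative, conf_level)
  x |>
    mutate(
      ref_count = ref_count,
      alt_count = alt_count,
      noise_count = .data$depth - informative,
      informative = informative,
      f_rna = ifelse(informative > 0, alt_count / informative, NA_real_),
      ci_lo = ci$ci_lo, ci_hi = ci$ci_hi
    ) |>
    select(
      "contig", "pos", "ref", "alt", "ref_count", "alt_count", "noise_count",
      "informative", "f_rna", "ci_lo", "ci_hi", "sample"
    )
}

#' Test per-site allelic imbalance
#'
#' Formalizes "RNA allele fraction close to 0% or 100%" as a statistical
#' rule: per site, an exact two-sided binomial test of the alternate-read
#' count against a balanced 0.5 null, Benjamini-Hochberg adjustment across
#' the sample's sites, and a verdict of `imbalanced` only when the adjusted
#' q-value falls below `alpha` *and* the fraction departs from 0.5 by at
#' least `effect_floor` (a pure p-value rule over-calls at high depth).
#' Sites with fewer than `min_depth` informative reads are `insufficient`.
#'
#' @param fractions Output of [allele_fraction()] (or a tibble with
#'   `ref_count`, `alt_count`, `informative`, `f_rna`).
#' @param alpha FDR threshold for the imbalance verdict (default 0.05).
#' @param effect_floor Minimum `|f_rna - 0.5|` for an imbalance verdict
#'   (default 0.15).
#' @param min_depth Minimum informative depth (default 14).
#' @return The input plus `p_value`, `q_value`, `verdict`
#'   (`balanced`/`imbalanced`/`insufficient`).
#' @export
test_imbalance <- function(fractions, alpha = 0.05, effect_floor = 0.15,
                           min_depth = 14) {
  x <- as_tibble(fractions)
  p <- binom_p_half(x$alt_count, x$informative)
  ok <- x$informative >= min_depth
  q <- rep(NA_real_, nrow(x))
  q[ok] <- p.adjust(p[ok], method = "BH")
  x |>
    mutate(
      p_value = p,
      q_value = q,
      verdict = case_when(
        !ok ~ "insufficient",
        q < alpha & abs(.data$f_rna - 0.5) >= effect_floor ~ "imbalanced",
        TRUE ~ "balanced"
      )
    )
}

#' Summarise allelic imbalance over one sample
#'
#' Pools ref/alt read counts across the sample's heterozygous sites (they lie
#' on one haplotype pair within a single gene; pooling sums counts under that
#' assumption, without inferring phase between sites), tests the pooled
#' fraction against 0.5, and issues a sample-level verdict: `imbalanced` when
#' the pooled test rejects at `alpha` and at least half of the informative
#' sites are individually imbalanced.
#'
#' @param results Per-site tibble from [test_imbalance()].
#' @param alpha Significance threshold for the pooled verdict.
#' @return One-row tibble: `sample`, `n_het_sites`, `n_informative`,
#'   `n_imbalanced`, `pooled_ref`, `pooled_alt`, `pooled_fraction`,
#'   `pooled_p`, `majority_allele` (`ref`/`alt`/`none`), `verdict`.
#' @export
summarize_sample <- function(results, alpha = 0.05) {
  x <- as_tibble(results)
  sample_lab <- if (nrow(x) > 0) x$sample[1] else NA_character_
  inf <- x |> filter(.data$verdict != "insufficient")
  if (nrow(inf) == 0) {
    return(tibble(
      sample = sample_lab, n_het_sites = nrow(x), n_informative = 0L,
      n_imbalanced = 0L, pooled_ref = 0L, pooled_alt = 0L,
      pooled_fraction = NA_real_, pooled_p = NA_real_,
      majority_allele = "none", verdict = "insufficient"
    ))
  }
  pooled_ref <- sum(inf$ref_count)
  pooled_alt <- sum(inf$alt_count)
  pooled_n <- pooled_ref + pooled_alt
  pooled_f <- pooled_alt / pooled_n
  pooled_p <- binom_p_half(pooled_alt, pooled_n)
  n_imb <- sum(inf$verdict == "imbalanced")
  tibble(
    sample = sample_lab,
    n_het_sites = nrow(x),
    n_informative = nrow(inf),
    n_imbalanced = as.integer(n_imb),
    pooled_ref = as.integer(pooled_ref),
    pooled_alt = as.integer(pooled_alt),
    pooled_fraction = pooled_f,
    pooled_p = pooled_p,
    majority_allele = if (pooled_f > 0.5) "alt" else if (pooled_f < 0.5) "ref" else "none",
    verdict = if (pooled_p < alpha && n_imb >= nrow(inf) / 2) "imbalanced" else "balanced"
  )
}

#' Contrast tumor against matched normal at shared heterozygous sites
#'
#' Per shared site, a Fisher exact test on the 2x2 table of (alt, ref) reads
#' in tumor versus normal, alongside the two sample-level verdicts. The
#' tumor-specific ASE flag fires when the tumor sample is imbalanced while
#' the matched normal — which should express both alleles equally — is
#' balanced.
#'
#' @param tumor,normal Per-site [test_imbalance()] tibbles for the two
#'   samples.
#' @param alpha Significance threshold passed to [summarize_sample()].
#' @return An object of class `tn_contrast`: list with `sites` (per-site
#'   tibble incl. `fisher_p`), `tumor_summary`, `normal_summary`,
#'   `tumor_specific` (logical). Use [generics::tidy()] / [generics::glance()].
#' @export
compare_tumor_normal <- function(tumor, normal, alpha = 0.05) {
  tumor <- as_tibble(tumor)
  normal <- as_tibble(normal)
  shared <- inner_join(
    tumor, normal,
    by = c("contig", "pos", "ref", "alt"), suffix = c("_tumor", "_normal")
  )
  if (nrow(shared) == 0) {
    abort("tumor and normal share no heterozygous sites")
  }
  n_only <- nrow(tumor) - nrow(shared)
  m_only <- nrow(normal) - nrow(shared)
  if (n_only > 0 || m_only > 0) {
    warn(sprintf(
      "%d tumor-only and %d normal-only site(s) dropped from the contrast",
      n_only, m_only
    ))
  }
  fisher_p <- map_dbl(seq_len(nrow(shared)), function(i) {
    tab <- matrix(
      c(
        shared$alt_count_tumor[i], shared$ref_count_tumor[i],
        shared$alt_count_normal[i], shared$ref_count_normal[i]
      ),
      nrow = 2
    )
    fisher.test(tab)$p.value
  })
  shared$fisher_p <- fisher_p
  ts <- summarize_sample(
    tumor |> rename_with_suffix(), alpha = alpha
  )
  ns <- summarize_sample(
    normal |> rename_with_suffix(), alpha = alpha
  )
  structure(
    list(
      sites = shared,
      tumor_summary = ts,
      normal_summary = ns,
      tumor_specific = identical(ts$verdict, "imbalanced") &&
        identical(ns$verdict, "balanced")
    ),
    class = "tn_contrast"
  )
}

# pass-through hook kept so compare_tumor_normal() can accept pre-suffixed
# inputs later without changing its interface
rename_with_suffix <- function(x) x

#' @export
print.tn_contrast <- function(x, ...) {
  cat(sprintf(
    "<tn_contrast> %d shared site(s); tumor: %s (f=%.3f), normal: %s (f=%.3f); tumor-specific ASE: %s\n",
    nrow(x$sites),
    x$tumor_summary$verdict, x$tumor_summary$pooled_fraction,
    x$normal_summary$verdict, x$normal_summary$pooled_fraction,
    x$tumor_specific
  ))
  invisible(x)
}
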
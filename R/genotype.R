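#' Call per-site germline zygosity from DNA allele counts
#'
#' Formalizes the near-1:1 heterozygosity criterion: a site is called
#' heterozygous when the DNA alternate-allele fraction lies inside
#' `het_window` *and* an exact binomial test against 0.5 does not reject at
#' `alpha`; it is called homozygous reference (alternate) when the fraction
#' falls below `hom_cut` (above `1 - hom_cut`, allowing for error bases);
#' anything else — including sites with fewer than `min_depth` informative
#' reads — is ambiguous.
#'
#' When the input carries no `alt` base, the alternate is taken as the most
#' frequent non-reference base (ties broken to the lexicographically smallest
#' base, recorded in `alt_tie`).
#'
#' @param counts DNA site allele-count tibble (as from [count_alleles()] or
#'   [simulate_counts()]); `material` must be `"DNA"`.
#' @param het_window Length-2 numeric, the allowed alt-fraction window for a
#'   heterozygous call (default `c(0.2, 0.8)`).
#' @param min_depth Minimum informative depth (ref + alt reads) for any
#'   non-ambiguous call (default 14).
#' @param alpha Significance level of the exact binomial test supporting the
#'   het call (default 0.001).
#' @param hom_cut Alt-fraction cutoff for homozygous calls (default 0.02).
#' @return The input with columns `ref_count`, `alt_count`, `f_dna`,
#'   `p_binom`, `call` (`hom_ref`/`het`/`hom_alt`/`ambiguous`), `alt_tie`.
#' @examples
#' x <- tibble::tibble(
#'   contig = "c", pos = 1L, ref = "A", alt = "G",
#'   n_a = 60L, n_c = 0L, n_g = 40L, n_t = 0L, n_other = 0L, depth = 100L,
#'   sample = "s", material = "DNA", condition = "tumor"
#' )
#' call_zygosity(x)$call
#' @export
call_zygosity <- function(counts, het_window = c(0.2, 0.8), min_depth = 14,
                          alpha = 0.001, hom_cut = 0.02) {
  counts <- as_tibble(counts)
  if (!all(counts$material == "DNA")) {
    abort("call_zygosity() expects DNA counts (material == 'DNA')")
  }
  stopifnot(
    length(het_window) == 2L, het_window[1] <= het_window[2],
    all(het_window >= 0), all(het_window <= 1)
  )
  counts <- pick_alt(counts)
  cc <- base_counts_matrix(counts)
  ref_count <- cc[cbind(seq_len(nrow(counts)), match(counts$ref, colnames(cc)))]
  alt_count <- cc[cbind(seq_len(nrow(counts)), match(counts$alt, colnames(cc)))]
  informative <- ref_count + alt_count
  f <- ifelse(informative > 0, alt_count / informative, NA_real_)
  p <- binom_p_half(alt_count, informative)
  call <- case_when(
    informative < min_depth ~ "ambiguous",
    f < hom_cut ~ "hom_ref",
    f > 1 - hom_cut ~ "hom_alt",
    f >= het_window[1] & f <= het_window[2] & p >= alpha ~ "het",
    TRUE ~ "ambiguous"
  )
  counts |>
    mutate(
      ref_count = as.integer(ref_count),
      alt_count = as.integer(alt_count),
      f_dna = f, p_binom = p, call = call
    )
}

# choose alt as the most frequent non-ref base where unset; lexicographic on
# ties, flagged in alt_tie
pick_alt <- function(counts) {
  cc <- base_counts_matrix(counts)
  bases <- colnames(cc)
  need <- is.na(counts$alt) | counts$alt == ""
  counts$alt_tie <- FALSE
  if (!any(need)) return(counts)
  for (i in which(need)) {
    cand <- setdiff(bases, counts$ref[i])
    cnt <- cc[i, cand]
    best <- cand[cnt == max(cnt)]
    counts$alt[i] <- sort(best)[1]
    counts$alt_tie[i] <- length(best) > 1
  }
  counts
}

base_counts_matrix <- function(counts) {
  m <- cbind(
    A = counts$n_a, C = counts$n_c, G = counts$n_g, T = counts$n_t
  )
  storage.mode(m) <- "integer"
  m
}

#' Genotype all sites of one sample and emit the heterozygous-site VCF
#'
#' Calls zygosity at every site (see [call_zygosity()]) and optionally writes
#' the heterozygous sites to a VCF 4.2 file with genotype `0/1` — the site
#' list the allelic-imbalance step consumes. Input must come from a single
#' sample's DNA and contain no duplicate positions.
#'
#' @inheritParams call_zygosity
#' @param out_vcf Optional path; when given, het sites are written as VCF.
#' @return The zygosity call tibble, ordered by contig and position, with the
#'   het-VCF path (if written) in attribute `het_vcf`.
#' @export
genotype_region <- function(counts, het_window = c(0.2, 0.8), min_depth = 14,
                            alpha = 0.001, hom_cut = 0.02, out_vcf = NULL) {
  counts <- as_tibble(counts)
  if (length(unique(counts$sample)) > 1) {
    abort("genotype_region() expects counts from a single sample")
  }
  if (anyDuplicated(counts[, c("contig", "pos")]) > 0) {
    abort("duplicate positions in input counts")
  }
  calls <- call_zygosity(counts, het_window, min_depth, alpha, hom_cut) |>
    arrange(.data$contig, .data$pos)
  if (!is.null(out_vcf)) {
    het <- calls |> filter(.data$call == "het")
    write_site_vcf(
      out_vcf, contig = het$contig[1] %||% "NA",
      sites = het[, c("pos", "ref", "alt")],
      gt = "0/1", sample = counts$sample[1] %||% "sample1"
    )
    attr(calls, "het_vcf") <- out_vcf
  }
  calls
}
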
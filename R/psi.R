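#' Count reads supporting the cassette-exon junctions
#'
#' Tallies, from spliced alignments, the reads supporting each of the three
#' informative junctions of the cassette event: upstream->cassette and
#' cassette->downstream (inclusion) and upstream->downstream (exclusion). A
#' read supports a junction only if one of its alignment gaps (`N` CIGAR
#' operations) matches the junction's donor/acceptor coordinates exactly and
#' the aligned blocks flanking that gap extend at least `min_overhang` bases
#' on both sides; each read counts at most once per junction.
#'
#' @param alignments Path to the spliced RNA SAM/BAM.
#' @param model A [gene_model()] (provides the junction coordinates).
#' @param min_overhang Minimum flanking aligned bases on each side of the
#'   junction (default 6).
#' @param sample Sample label for the output row.
#' @return One-row junction-count tibble: `sample`, `inclusion_upstream`,
#'   `inclusion_downstream`, `exclusion`.
#' @export
extract_junction_counts <- function(alignments, model, min_overhang = 6,
                                    sample = "sample1") {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(model$junctions) || nrow(model$junctions) != 3L) {
    abort("gene model lacks a cassette junction definition")
  }
  bam <- prepare_bam(alignments)
  gal <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(
        isSecondaryAlignment = FALSE, isDuplicate = FALSE,
        isSupplementaryAlignment = FALSE, isUnmappedQuery = FALSE
      ),
      which = GenomicRanges::GRanges(
        model$contig, IRanges::IRanges(1L, max(model$exons$end) + 10000L)
      )
    )
  )
  counts <- setNames(integer(3), model$junctions$junction)
  if (length(gal) > 0) {
    # reference-space M blocks per read; gaps between consecutive blocks are
    # the junctions the read spans
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(gal),
      pos = GenomicRanges::start(gal),
      ops = c("M", "D", "=", "X"),
      reduce.ranges = TRUE
    )
    starts <- IRanges::start(blocks)
    ends <- IRanges::end(blocks)
    nblk <- lengths(blocks)
    for (j in seq_len(3L)) {
      # intron of this junction in 1-based inclusive coords
      i_start <- model$junctions$donor_end[j] + 1L
      i_end <- model$junctions$acceptor_start[j]
      hits <- vapply(
        seq_along(gal),
        function(r) {
          nb <- nblk[r]
          if (nb < 2L) return(FALSE)
          s <- starts[[r]]; e <- ends[[r]]
          for (b in seq_len(nb - 1L)) {
            if (e[b] + 1L == i_start && s[b + 1L] - 1L == i_end &&
                (e[b] - s[b] + 1L) >= min_overhang &&
                (e[b + 1L] - s[b + 1L] + 1L) >= min_overhang) {
              return(TRUE)
            }
          }
          FALSE
        },
        logical(1)
      )
      counts[j] <- sum(hits)
    }
  }
  tibble(
    sample = sample,
    inclusion_upstream = counts[["inclusion_upstream"]],
    inclusion_downstream = counts[["inclusion_downstream"]],
    exclusion = counts[["exclusion"]]
  )
}

#' Percent skipping of the cassette exon from junction counts
#'
#' The skipping fraction is `exclusion / (exclusion + I)` where `I` is the
#' mean of the two inclusion-junction counts (two-junction flank averaging,
#' the convention of junction-based splicing quantifiers). The estimate is
#' undefined (NA) when total junction support `exclusion + I` falls below
#' `min_total`.
#'
#' @param junctions Junction-count tibble (`inclusion_upstream`,
#'   `inclusion_downstream`, `exclusion`; one row per sample).
#' @param min_total Minimum junction support (default 10 reads).
#' @return Tibble with `sample`, `psi_skip` (0-1), `psi_skip_pct`,
#'   `inclusion_support`, `exclusion_support`, `method`.
#' @examples
#' compute_psi(tibble::tibble(
#'   sample = "s", inclusion_upstream = 10, inclusion_downstream = 10,
#'   exclusion = 80
#' ))
#' @export
compute_psi <- function(junctions, min_total = 10) {
  x <- as_tibble(junctions)
  incl <- (x$inclusion_upstream + x$inclusion_downstream) / 2
  excl <- x$exclusion
  total <- excl + incl
  psi <- ifelse(total >= min_total & total > 0, excl / total, NA_real_)
  tibble(
    sample = if ("sample" %in% names(x)) x$sample else NA_character_,
    psi_skip = psi,
    psi_skip_pct = 100 * psi,
    inclusion_support = incl,
    exclusion_support = excl,
    method = "junction-flank-mean"
  )
}

#' Compare an estimated skipping fraction with its simulated truth
#'
#' For a synthetic sample the expected skipping fraction is the haplotype
#' mixture `theta_rna * psi_alt + (1 - theta_rna) * psi_ref`; this helper
#' returns the estimate, the expectation, and their difference.
#'
#' @param psi A [compute_psi()] row (or tibble).
#' @param truth The generating [sim_truth()].
#' @return Tibble with `psi_skip`, `expected`, `error`, `abs_error`.
#' @export
recover_psi_truth <- function(psi, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  x <- as_tibble(psi)
  expected <- mixture_skip_fraction(truth)
  tibble(
    sample = x$sample,
    psi_skip = x$psi_skip,
    expected = expected,
    error = x$psi_skip - expected,
    abs_error = abs(x$psi_skip - expected)
  )
}
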
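#' Per-site allele counts from alignments
#'
#' Pileup-counts the bases observed at each requested site, the programmatic
#' equivalent of reading allele ratios off a genome-browser pileup. Reads that
#' are secondary, supplementary, or marked duplicates are excluded, as are
#' bases below `min_base_quality` and reads below `min_mapping_quality`.
#' Deletions spanning a site are tallied as `n_other`; reference skips
#' (spliced-out introns) contribute nothing to depth.
#'
#' @param alignments Path to a BAM file (indexed or indexable) or a SAM file
#'   (converted on the fly).
#' @param sites Site table with columns `contig`, `pos` (1-based) and
#'   optionally `ref`, `alt`; or a path to a VCF/TSV with those sites
#'   (see [read_sites()]).
#' @param min_base_quality,min_mapping_quality Phred thresholds (defaults 20).
#' @param sample,material,condition Labels stored on every output row;
#'   `material` is `"DNA"` or `"RNA"`.
#' @return A site allele-count tibble: `contig`, `pos`, `ref`, `alt`, `n_a`,
#'   `n_c`, `n_g`, `n_t`, `n_other`, `depth`, `sample`, `material`,
#'   `condition`. Sites without any passing read have depth 0.
#' @export
count_alleles <- function(alignments, sites,
                          min_base_quality = 20, min_mapping_quality = 20,
                          sample = "sample1", material = "DNA",
                          condition = "tumor") {
  sites <- if (is.character(sites)) read_sites(sites) else as_tibble(sites)
  stopifnot(all(c("contig", "pos") %in% names(sites)))
  material <- match.arg(material, c("DNA", "RNA"))
  bam <- prepare_bam(alignments)

  known <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  bad <- setdiff(unique(sites$contig), names(known))
  if (length(bad) > 0) {
    abort(sprintf(
      "site contig(s) not present in alignments: %s", paste(bad, collapse = ", ")
    ))
  }

  which <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos, sites$pos)
  )
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = which,
      flag = Rsamtools::scanBamFlag(
        isSecondaryAlignment = FALSE, isDuplicate = FALSE,
        isSupplementaryAlignment = FALSE, isUnmappedQuery = FALSE
      ),
      mapqFilter = min_mapping_quality
    ),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 10000000L,
      min_base_quality = as.integer(min_base_quality),
      min_mapq = as.integer(min_mapping_quality),
      min_nucleotide_depth = 0L,
      distinguish_strands = FALSE,
      distinguish_nucleotides = TRUE,
      ignore_query_Ns = TRUE,
      include_deletions = TRUE,
      include_insertions = FALSE
    )
  )
  p <- as_tibble(p)
  wide <- p |>
    mutate(
      contig = as.character(.data$seqnames),
      nucleotide = as.character(.data$nucleotide)
    ) |>
    group_by(.data$contig, .data$pos, .data$nucleotide) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "nucleotide", values_from = "count", values_fill = 0L
    )
  for (b in c("A", "C", "G", "T", "-")) {
    if (!b %in% names(wide)) wide[[b]] <- 0L
  }
  out <- sites |>
    left_join(wide, by = c("contig", "pos")) |>
    mutate(
      n_a = as.integer(.data$A %|0|% 0L),
      n_c = as.integer(.data$C %|0|% 0L),
      n_g = as.integer(.data$G %|0|% 0L),
      n_t = as.integer(.data$T %|0|% 0L),
      n_other = as.integer(.data$`-` %|0|% 0L)
    ) |>
    mutate(
      depth = .data$n_a + .data$n_c + .data$n_g + .data$n_t + .data$n_other,
      sample = sample, material = material, condition = condition
    ) |>
    arrange(.data$contig, .data$pos)
  if (!"ref" %in% names(out)) out$ref <- NA_character_
  if (!"alt" %in% names(out)) out$alt <- NA_character_
  out |>
    select(
      "contig", "pos", "ref", "alt", "n_a", "n_c", "n_g", "n_t",
      "n_other", "depth", "sample", "material", "condition"
    )
}

# NA-to-zero for count columns materialised by a left join
`%|0|%` <- function(x, z) ifelse(is.na(x), z, x)

#' Scan a region for heterozygous-candidate sites
#'
#' Pileups every position of a region and keeps those where the second most
#' common base reaches `min_minor_fraction` of the passing depth and depth
#' reaches `min_depth` — a liberal pre-filter over the whole gene; the
#' genotyping step makes the real call. Results are ordered by position.
#'
#' @inheritParams count_alleles
#' @param region List or one-row data frame with `contig`, `start`, `end`
#'   (1-based, inclusive).
#' @param min_depth Minimum passing depth (default 14).
#' @param min_minor_fraction Minimum minor-base fraction (default 0.2).
#' @return Tibble with `contig`, `pos`, `major`, `minor`, `major_count`,
#'   `minor_count`, `depth`, `minor_fraction`.
#' @export
scan_het_candidates <- function(alignments, region, min_depth = 14,
                                min_minor_fraction = 0.2,
                                min_base_quality = 20,
                                min_mapping_quality = 20) {
  region <- as.list(region)
  stopifnot(all(c("contig", "start", "end") %in% names(region)))
  empty <- tibble(
    contig = character(), pos = integer(), major = character(),
    minor = character(), major_count = integer(), minor_count = integer(),
    depth = integer(), minor_fraction = double()
  )
  if (region$end < region$start) return(empty)
  bam <- prepare_bam(alignments)
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(
        region$contig, IRanges::IRanges(region$start, region$end)
      ),
      flag = Rsamtools::scanBamFlag(
        isSecondaryAlignment = FALSE, isDuplicate = FALSE,
        isSupplementaryAlignment = FALSE, isUnmappedQuery = FALSE
      ),
      mapqFilter = min_mapping_quality
    ),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 10000000L,
      min_base_quality = as.integer(min_base_quality),
      min_mapq = as.integer(min_mapping_quality),
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  p <- as_tibble(p) |>
    mutate(nucleotide = as.character(.data$nucleotide)) |>
    filter(.data$nucleotide %in% c("A", "C", "G", "T"))
  if (nrow(p) == 0) return(empty)
  p |>
    group_by(contig = as.character(.data$seqnames), pos = .data$pos) |>
    summarise(
      depth = as.integer(sum(.data$count)),
      # ties broken lexicographically: sort by count desc, then base
      major = .data$nucleotide[order(-.data$count, .data$nucleotide)][1],
      minor = c(.data$nucleotide[order(-.data$count, .data$nucleotide)], NA)[2],
      major_count = as.integer(sort(.data$count, decreasing = TRUE)[1]),
      minor_count = as.integer(c(sort(.data$count, decreasing = TRUE), 0L)[2]),
      .groups = "drop"
    ) |>
    mutate(
      minor_count = ifelse(is.na(.data$minor_count), 0L, .data$minor_count),
      minor_fraction = ifelse(.data$depth > 0, .data$minor_count / .data$depth, 0)
    ) |>
    filter(
      .data$depth >= min_depth, .data$minor_fraction >= min_minor_fraction,
      !is.na(.data$minor)
    ) |>
    arrange(.data$pos)
}

# accept SAM or BAM; return an indexed BAM path
prepare_bam <- function(alignments) {
  stopifnot(is.character(alignments), length(alignments) == 1L)
  if (!file.exists(alignments)) {
    abort(sprintf("alignment file not found: %s", alignments))
  }
  is_sam <- grepl("\\.sam$", alignments, ignore.case = TRUE)
  if (is_sam) {
    dest <- sub("\\.sam$", "", alignments, ignore.case = TRUE)
    bam <- paste0(dest, ".bam")
    if (!file.exists(bam) ||
        file.mtime(bam) < file.mtime(alignments)) {
      tmp <- Rsamtools::asBam(
        alignments, destination = paste0(dest, ".unsorted"),
        overwrite = TRUE, indexDestination = FALSE
      )
      bam <- Rsamtools::sortBam(tmp, destination = dest)
      unlink(tmp)
      Rsamtools::indexBam(bam)
    }
    alignments <- bam
  }
  if (!file.exists(paste0(alignments, ".bai"))) {
    Rsamtools::indexBam(alignments)
  }
  alignments
}

#' Read and write site allele-count tables
#'
#' The on-disk TSV schema is `contig, pos_1based, ref, alt, nA, nC, nG, nT,
#' nOther` plus the `sample`, `material`, `condition` labels; in memory the
#' count columns are `n_a` ... `n_other` with a derived `depth`.
#'
#' @param counts A site allele-count tibble.
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly; `read_counts_tsv()`
#'   returns the tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- counts |>
    select(
      contig = "contig", pos_1based = "pos", ref = "ref", alt = "alt",
      nA = "n_a", nC = "n_c", nG = "n_g", nT = "n_t", nOther = "n_other",
      sample = "sample", material = "material", condition = "condition"
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      contig = readr::col_character(), pos_1based = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      nA = readr::col_integer(), nC = readr::col_integer(),
      nG = readr::col_integer(), nT = readr::col_integer(),
      nOther = readr::col_integer(),
      sample = readr::col_character(), material = readr::col_character(),
      condition = readr::col_character()
    )
  ) |>
    rename(
      pos = "pos_1based", n_a = "nA", n_c = "nC", n_g = "nG", n_t = "nT",
      n_other = "nOther"
    ) |>
    mutate(
      depth = .data$n_a + .data$n_c + .data$n_g + .data$n_t + .data$n_other
    ) |>
    select(
      "contig", "pos", "ref", "alt", "n_a", "n_c", "n_g", "n_t", "n_other",
      "depth", "sample", "material", "condition"
    )
}

#' Read a site list from VCF or TSV
#'
#' VCF input keeps `CHROM`, `POS`, `REF`, `ALT` (first alternate allele);
#' TSV input must have columns `contig`, `pos` and optionally `ref`, `alt`.
#'
#' @param path Path to a `.vcf` or tab-separated site table.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`.
#' @export
read_sites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) {
      fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
    }
    fix <- as.data.frame(fx, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      return(tibble(
        contig = character(), pos = integer(), ref = character(),
        alt = character()
      ))
    }
    tibble(
      contig = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = vapply(strsplit(fix$ALT, ","), `[`, character(1), 1)
    )
  } else {
    s <- readr::read_tsv(path, show_col_types = FALSE)
    stopifnot(all(c("contig", "pos") %in% names(s)))
    if (!"ref" %in% names(s)) s$ref <- NA_character_
    if (!"alt" %in% names(s)) s$alt <- NA_character_
    as_tibble(s[, c("contig", "pos", "ref", "alt")])
  }
}
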
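# quick constructor for a site allele-count tibble
make_counts <- function(ref = "A", alt = "G", ref_count = 0L, alt_count = 0L,
                        other = c(C = 0L, T = 0L), pos = 1L,
                        material = "DNA", sample = "s1",
                        condition = "tumor", contig = "ctg") {
  n <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  n[ref] <- n[ref] + as.integer(ref_count)
  n[alt] <- n[alt] + as.integer(alt_count)
  for (b in names(other)) n[b] <- n[b] + as.integer(other[[b]])
  tibble::tibble(
    contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
    n_a = n[["A"]], n_c = n[["C"]], n_g = n[["G"]], n_t = n[["T"]],
    n_other = 0L, depth = sum(n), sample = sample, material = material,
    condition = condition
  )
}

# imbalance-result-shaped row without going through count tables
make_fraction_row <- function(ref_count, alt_count, pos = 1L, sample = "s1",
                              ref = "A", alt = "G") {
  informative <- ref_count + alt_count
  ci <- aseskip::clopper_pearson(alt_count, informative)
  tibble::tibble(
    contig = "ctg", pos = as.integer(pos), ref = ref, alt = alt,
    ref_count = as.integer(ref_count), alt_count = as.integer(alt_count),
    noise_count = 0L, informative = as.integer(informative),
    f_rna = ifelse(informative > 0, alt_count / informative, NA_real_),
    ci_lo = ci$ci_lo, ci_hi = ci$ci_hi, sample = sample
  )
}

# write a tiny SAM file from a tibble of records (pos, cigar, seq, qual, ...)
write_test_sam <- function(path, records, contig = "ctg", contig_len = 1000L) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len)
  )
  col_or <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else default
  }
  body <- sprintf(
    "r%03d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    seq_len(nrow(records)),
    col_or("flag", 0L),
    contig,
    records$pos,
    col_or("mapq", 60L),
    records$cigar,
    records$seq,
    col_or("qual", strrep("F", nchar(records$seq)))
  )
  writeLines(c(header, body[order(records$pos)]), path)
  path
}
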
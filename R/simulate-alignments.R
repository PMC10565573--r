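#' Simulate spliced alignments for a synthetic sample
#'
#' Writes single-end reads for a synthetic tumor or normal sample as
#' coordinate-sorted SAM: an unspliced whole-contig DNA library and a spliced
#' RNA library whose reads are drawn from the four haplotype-by-isoform
#' transcript classes (ref/alt haplotype, cassette included/skipped) with
#' class weights `P(alt) = theta_rna` and per-haplotype skipping
#' probabilities `psi_ref`, `psi_alt`. Skipping is encoded in the alignment as
#' an `N` CIGAR gap across the cassette exon. A reference haplotype sequence
#' is generated from the seed; alternate-haplotype reads carry the alt base at
#' every SNV site, and each sequenced base is misread to a uniformly chosen
#' other base with probability `error_rate`.
#'
#' Alongside the two SAM files the function writes the ground truth: a VCF of
#' the heterozygous sites (GT 0/1) and a JSON sidecar of the full
#' [sim_truth()] parameters. Running [count_alleles()] and
#' [extract_junction_counts()] on the SAM output recovers, up to sampling
#' error, the same distributions as [simulate_counts()] at matched parameters.
#'
#' @param model A [gene_model()].
#' @param truth A [sim_truth()].
#' @param read_length Read length in bases (must be at least 2 and no longer
#'   than the shortest transcript).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for the outputs.
#' @param sample Sample label written into read group / file names.
#' @return A list of class `sim_alignments` with elements `dna_sam`,
#'   `rna_sam`, `truth_vcf`, `truth_json`, `contig`, `contig_length`, `truth`.
#' @export
simulate_alignments <- function(model, truth, read_length = 75,
                                dir = tempdir(), prefix = "sim",
                                sample = "sim_sample") {
  stopifnot(inherits(model, "gene_model"), inherits(truth, "sim_truth"))
  if (read_length < 2) abort("read_length must be >= 2")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  contig_len <- max(model$exons$end) + 300L
  bases <- c("A", "C", "G", "T")

  withr::with_seed(truth$seed, {
    ref_chars <- sample(bases, contig_len, replace = TRUE)
    ref_chars[model$snvs$pos] <- model$snvs$ref
    alt_chars <- ref_chars
    alt_chars[model$snvs$pos] <- model$snvs$alt
    hap_str <- c(
      ref = paste(ref_chars, collapse = ""),
      alt = paste(alt_chars, collapse = "")
    )

    err_one <- function(s) {
      len <- nchar(s)
      ne <- rbinom(1L, len, truth$error_rate)
      if (ne == 0L) return(s)
      ch <- strsplit(s, "")[[1]]
      at <- sample.int(len, ne)
      for (p in at) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      paste(ch, collapse = "")
    }

    # --- DNA library: unspliced reads uniform over the contig -----------
    n_dna <- round(truth$depth_dna * contig_len / read_length)
    dna <- NULL
    if (n_dna > 0) {
      starts <- sample.int(contig_len - read_length + 1L, n_dna, replace = TRUE)
      hap <- ifelse(runif(n_dna) < truth$theta_dna, "alt", "ref")
      seqs <- vapply(
        seq_len(n_dna),
        function(i) {
          err_one(substr(hap_str[[hap[i]]], starts[i], starts[i] + read_length - 1L))
        },
        character(1)
      )
      dna <- tibble(
        pos = starts, cigar = paste0(read_length, "M"), seq = seqs
      )
    }

    # --- RNA library: spliced reads from 4 transcript classes ----------
    incl_exons <- model$exons
    excl_exons <- model$exons[-model$cassette_exon, ]
    tx_len <- function(ex) sum(ex$end - ex$start)
    class_tbl <- tibble(
      hap = c("ref", "ref", "alt", "alt"),
      skip = c(FALSE, TRUE, FALSE, TRUE),
      weight = c(
        (1 - truth$theta_rna) * (1 - truth$psi_ref),
        (1 - truth$theta_rna) * truth$psi_ref,
        truth$theta_rna * (1 - truth$psi_alt),
        truth$theta_rna * truth$psi_alt
      )
    )
    rna <- NULL
    for (ci in seq_len(nrow(class_tbl))) {
      ex <- if (class_tbl$skip[ci]) excl_exons else incl_exons
      tl <- tx_len(ex)
      if (tl < read_length) {
        abort("read_length exceeds transcript length; shorten reads")
      }
      n_reads <- rpois(1L, truth$depth_rna * class_tbl$weight[ci] * tl / read_length)
      if (n_reads == 0L) next
      tx_str <- spliced_transcript(hap_str[[class_tbl$hap[ci]]], ex)
      tstarts <- sample.int(tl - read_length + 1L, n_reads, replace = TRUE)
      aln <- map(tstarts, function(ts) tx_to_genome(ex, ts - 1L, read_length))
      seqs <- vapply(
        seq_len(n_reads),
        function(i) {
          err_one(substr(tx_str, tstarts[i], tstarts[i] + read_length - 1L))
        },
        character(1)
      )
      rna <- bind_rows(rna, tibble(
        pos = map_int(aln, "pos"),
        cigar = map_chr(aln, "cigar"),
        seq = seqs
      ))
    }

    out <- list(
      dna_sam = file.path(dir, paste0(prefix, ".dna.sam")),
      rna_sam = file.path(dir, paste0(prefix, ".rna.sam")),
      truth_vcf = file.path(dir, paste0(prefix, ".truth.vcf")),
      truth_json = file.path(dir, paste0(prefix, ".truth.json")),
      contig = model$contig, contig_length = contig_len, truth = truth
    )
    write_sam(dna, model$contig, contig_len, sample, "dna", out$dna_sam)
    write_sam(rna, model$contig, contig_len, sample, "rna", out$rna_sam)

    het <- if (truth$theta_dna > 0 && truth$theta_dna < 1) {
      model$snvs
    } else {
      model$snvs[0, , drop = FALSE]
    }
    write_site_vcf(out$truth_vcf, model$contig, het, gt = "0/1")
    jsonlite::write_json(
      c(
        unclass(truth),
        list(
          sample = sample, read_length = read_length,
          contig = model$contig, contig_length = contig_len
        )
      ),
      out$truth_json,
      auto_unbox = TRUE, digits = NA
    )
    structure(out, class = "sim_alignments")
  })
}

# transcript sequence of one isoform from a haplotype's genomic sequence
spliced_transcript <- function(hap_string, exons) {
  paste(
    mapply(substr, exons$start + 1L, exons$end, MoreArgs = list(x = hap_string)),
    collapse = ""
  )
}

# map a 0-based transcript interval [tstart, tstart + len) onto genome blocks;
# returns the 1-based SAM POS and a CIGAR with M blocks split by N gaps
tx_to_genome <- function(exons, tstart, len) {
  widths <- exons$end - exons$start
  offs <- cumsum(c(0L, widths))
  g_start <- integer(0)
  g_len <- integer(0)
  remaining <- len
  cur <- tstart
  while (remaining > 0L) {
    i <- findInterval(cur, offs, rightmost.closed = FALSE)
    within <- cur - offs[i]
    take <- min(remaining, widths[i] - within)
    g_start <- c(g_start, exons$start[i] + within)
    g_len <- c(g_len, take)
    cur <- cur + take
    remaining <- remaining - take
  }
  ops <- paste0(g_len[1], "M")
  if (length(g_len) > 1L) {
    for (j in 2:length(g_len)) {
      gap <- g_start[j] - (g_start[j - 1] + g_len[j - 1])
      ops <- paste0(ops, gap, "N", g_len[j], "M")
    }
  }
  list(pos = as.integer(g_start[1] + 1L), cigar = ops)
}

# write single-end reads as coordinate-sorted SAM text
write_sam <- function(reads, contig, contig_len, sample, lib, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len),
    sprintf("@RG\tID:%s.%s\tSM:%s", sample, lib, sample),
    "@PG\tID:aseskip\tPN:aseskip"
  )
  lines <- header
  if (!is.null(reads) && nrow(reads) > 0) {
    o <- order(reads$pos)
    reads <- reads[o, ]
    qual <- strrep("F", nchar(reads$seq[1]))
    lines <- c(lines, sprintf(
      "%s.%s.%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tRG:Z:%s.%s",
      sample, lib, seq_len(nrow(reads)), contig, reads$pos, reads$cigar,
      reads$seq, qual, sample, lib
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# minimal VCF 4.2 writer for a handful of SNV sites; `sites` may carry its own
# contig column, otherwise the scalar `contig` is used for every row
write_site_vcf <- function(path, contig, sites, gt = "0/1", sample = "sample1") {
  row_contig <- if ("contig" %in% names(sites)) sites$contig else
    rep(contig, nrow(sites))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(c(row_contig, contig))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample
    )
  )
  body <- character(0)
  if (nrow(sites) > 0) {
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
      row_contig, sites$pos, sites$ref, sites$alt, gt
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}
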
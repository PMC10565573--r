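#' Define a cassette-exon gene model
#'
#' A gene model is the minimal description the pipeline needs of a multi-exon
#' gene containing one cassette (skippable) exon: exon intervals, which exon is
#' the cassette, and the heterozygous-candidate SNV sites that tag the two
#' haplotypes. Exon coordinates are 0-based half-open; SNV positions are
#' 1-based (the convention of count tables and VCF). The three informative
#' junctions (upstream->cassette, cassette->downstream, upstream->downstream)
#' are derived from the exon set and stored as (donor end, acceptor start)
#' 0-based coordinate pairs.
#'
#' @param contig Contig/chromosome name.
#' @param exons Data frame with integer columns `start`, `end` (0-based
#'   half-open), sorted, non-overlapping.
#' @param cassette_exon Integer index (1-based, into the exon rows) of the
#'   cassette exon; must be interior.
#' @param snvs Data frame with columns `pos` (1-based), `ref`, `alt`
#'   (single bases, `ref != alt`); every site must fall inside an exon.
#' @param strand `"+"` or `"-"`; a label only, all counting is
#'   strand-collapsed.
#' @return An object of class `gene_model`.
#' @examples
#' m <- example_gene_model()
#' m$junctions
#' @export
gene_model <- function(contig, exons, cassette_exon, snvs, strand = "+") {
  exons <- as_tibble(exons)
  snvs <- as_tibble(snvs)
  stopifnot(
    is.character(contig), length(contig) == 1L,
    all(c("start", "end") %in% names(exons)),
    all(c("pos", "ref", "alt") %in% names(snvs)),
    strand %in% c("+", "-")
  )
  if (any(exons$end <= exons$start)) abort("exons must have end > start")
  if (is.unsorted(exons$start, strictly = TRUE)) {
    abort("exons must be sorted by start")
  }
  if (any(utils::head(exons$end, -1) > utils::tail(exons$start, -1))) {
    abort("exons must be non-overlapping")
  }
  ne <- nrow(exons)
  if (cassette_exon <= 1L || cassette_exon >= ne) {
    abort("cassette exon must be interior (flanked on both sides)")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(snvs$ref %in% bases) || !all(snvs$alt %in% bases)) {
    abort("SNV ref/alt must be single bases A/C/G/T")
  }
  if (any(snvs$ref == snvs$alt)) abort("SNV ref and alt bases must differ")
  pos0 <- snvs$pos - 1L
  in_exon <- vapply(
    pos0,
    function(p) any(p >= exons$start & p < exons$end),
    logical(1)
  )
  if (!all(in_exon)) {
    abort(sprintf(
      "SNV position(s) outside exons: %s",
      paste(snvs$pos[!in_exon], collapse = ", ")
    ))
  }
  up <- cassette_exon - 1L
  dn <- cassette_exon + 1L
  junctions <- tibble(
    junction = c("inclusion_upstream", "inclusion_downstream", "exclusion"),
    donor_end = c(exons$end[up], exons$end[cassette_exon], exons$end[up]),
    acceptor_start = c(
      exons$start[cassette_exon], exons$start[dn], exons$start[dn]
    )
  )
  structure(
    list(
      contig = contig, exons = exons, cassette_exon = as.integer(cassette_exon),
      snvs = snvs, junctions = junctions, strand = strand
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(
    "<gene_model> ", x$contig, " (", x$strand, "): ", nrow(x$exons),
    " exons, cassette = exon ", x$cassette_exon, ", ", nrow(x$snvs),
    " SNV site(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Built-in toy cassette-exon gene model
#'
#' A five-exon gene on a synthetic contig with the middle exon (exon 3) as the
#' cassette, mimicking an exon flanked like MET exon 14 by exons 13 and 15.
#' Eight heterozygous-candidate SNV sites are placed in the four constitutive
#' exons (none in the cassette exon, so per-site RNA depth does not depend on
#' the skipping rate and pooled allele fractions estimate the RNA haplotype
#' fraction directly).
#'
#' @param contig Contig name for the toy gene.
#' @return A `gene_model`.
#' @export
example_gene_model <- function(contig = "geneA_contig") {
  exons <- tibble(
    start = c(100L, 700L, 1400L, 2100L, 2900L),
    end   = c(350L, 950L, 1541L, 2350L, 3200L)
  )
  snvs <- tibble(
    pos = c(150L, 301L, 750L, 901L, 2150L, 2301L, 2950L, 3101L),
    ref = c("A", "C", "G", "T", "A", "G", "C", "T"),
    alt = c("G", "T", "A", "C", "C", "A", "A", "G")
  )
  gene_model(contig, exons, cassette_exon = 3L, snvs = snvs)
}

#' Write / read a gene model's exons as BED
#'
#' Exons are exported one per line in BED format (0-based half-open), with the
#' cassette exon labelled `cassette` in the name column and constitutive exons
#' labelled `exon<i>`. SNV sites travel separately (VCF or a sites table);
#' `read_model_bed()` accepts them via `snvs`.
#'
#' @param model A `gene_model`.
#' @param path Output BED file path.
#' @return `write_model_bed()` returns `path` invisibly; `read_model_bed()`
#'   returns a `gene_model`.
#' @export
write_model_bed <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  nm <- paste0("exon", seq_len(nrow(model$exons)))
  nm[model$cassette_exon] <- "cassette"
  gr <- GenomicRanges::GRanges(
    model$contig,
    IRanges::IRanges(start = model$exons$start + 1L, end = model$exons$end),
    strand = model$strand,
    name = nm,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_model_bed
#' @param snvs SNV site table (`pos`, `ref`, `alt`) to attach on read.
#' @export
read_model_bed <- function(path, snvs) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  exons <- tibble(
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  cassette <- which(gr$name == "cassette")
  if (length(cassette) != 1L) {
    abort("BED model must label exactly one exon 'cassette'")
  }
  strand <- as.character(GenomicRanges::strand(gr)[1])
  if (strand == "*") strand <- "+"
  gene_model(
    as.character(GenomicRanges::seqnames(gr)[1]), exons, cassette,
    snvs = snvs, strand = strand
  )
}
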
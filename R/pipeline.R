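#' Run the full ASE + exon-skipping pipeline
#'
#' Orchestrates, per sample: DNA genotyping, RNA allelic-imbalance testing at
#' the heterozygous sites, percent-skipping estimation from junction counts,
#' and — when a matched normal is supplied — the tumor/normal contrast with
#' the tumor-specific ASE flag. Produces the per-sample classification table
#' (het-site count, imbalance verdict, pooled fraction, percent skipping,
#' tumor-specific flag). A failure in one sample is recorded in its row and
#' does not abort the others.
#'
#' @param config A named list or path to a YAML/JSON file with elements:
#'   \describe{
#'     \item{samples}{list of sample blocks; each has `label` and either
#'       in-memory tibbles or file paths: `dna_counts`, `rna_counts`
#'       (count tables, see [read_counts_tsv()]), `junctions` (junction-count
#'       table) or `rna_bam` + a gene model for junction extraction, and
#'       optionally `normal` (a nested block with `dna_counts`,
#'       `rna_counts`).}
#'     \item{model}{optional [gene_model()] or BED path (needed only when
#'       junctions are extracted from alignments).}
#'     \item{params}{optional overrides: `het_window`, `min_depth`, `alpha`,
#'       `effect_floor`, `hom_cut`, `genotype_alpha`, `min_overhang`,
#'       `min_total`.}
#'   }
#' @param out_dir Optional directory; when given, intermediate TSV/VCF/JSON
#'   files are written there.
#' @param quiet Suppress per-stage log messages.
#' @return A tibble of class `sample_report`, one row per sample: `sample`,
#'   `n_het_sites`, `imbalance_verdict`, `pooled_alt_fraction`,
#'   `psi_skip_pct`, `normal_verdict`, `tumor_specific`, `error`. Per-sample
#'   detail objects are attached as attribute `details`; run parameters and
#'   input hashes as attribute `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- load_config(config)
  if (is.null(config$samples) || length(config$samples) == 0) {
    abort("config must name at least one sample")
  }
  params <- pipeline_params(config$params)
  model <- config$model
  if (is.character(model)) {
    abort("BED model paths need SNV sites; pass a gene_model object instead")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  details <- list()
  rows <- map(config$samples, function(s) {
    label <- s$label %||% "sample"
    tryCatch(
      {
        res <- run_one_sample(s, model, params, out_dir, quiet)
        details[[label]] <<- res
        res$row
      },
      error = function(e) {
        tibble(
          sample = label, n_het_sites = NA_integer_,
          imbalance_verdict = NA_character_,
          pooled_alt_fraction = NA_real_, psi_skip_pct = NA_real_,
          normal_verdict = NA_character_, tumor_specific = NA,
          error = conditionMessage(e)
        )
      }
    )
  })
  report <- bind_rows(rows)
  attr(report, "details") <- details
  attr(report, "provenance") <- list(
    package = as.character(packageVersion("aseskip")),
    params = params,
    input_hashes = config_hashes(config)
  )
  class(report) <- c("sample_report", class(report))
  report
}

run_one_sample <- function(s, model, params, out_dir, quiet) {
  label <- s$label %||% "sample"
  log_stage <- function(stage, detail) {
    if (!quiet) message(sprintf("[%s] %s: %s", label, stage, detail))
  }
  dna <- load_counts(s$dna_counts, "dna_counts")
  rna <- load_counts(s$rna_counts, "rna_counts")
  if (is.null(dna)) abort(sprintf("sample '%s': missing dna_counts", label))
  if (is.null(rna)) abort(sprintf("sample '%s': missing rna_counts", label))

  # germline genotype: prefer matched-normal DNA when available
  normal <- s$normal
  geno_src <- dna
  germline_src <- "tumor DNA (no matched normal; caveat recorded)"
  if (!is.null(normal) && !is.null(normal$dna_counts)) {
    geno_src <- load_counts(normal$dna_counts, "normal dna_counts")
    germline_src <- "matched normal DNA"
  }
  calls <- genotype_region(
    geno_src,
    het_window = params$het_window, min_depth = params$min_depth,
    alpha = params$genotype_alpha, hom_cut = params$hom_cut,
    out_vcf = if (!is.null(out_dir)) {
      file.path(out_dir, paste0(label, ".het.vcf"))
    }
  )
  log_stage("genotype", sprintf(
    "%d/%d het sites from %s",
    sum(calls$call == "het"), nrow(calls), germline_src
  ))

  imb <- allele_fraction(rna, calls) |>
    test_imbalance(
      alpha = params$alpha, effect_floor = params$effect_floor,
      min_depth = params$min_depth
    )
  summ <- summarize_sample(imb, alpha = params$alpha)
  log_stage("ase", sprintf(
    "pooled alt fraction %.3f, verdict %s",
    summ$pooled_fraction, summ$verdict
  ))

  junctions <- if (!is.null(s$junctions)) {
    load_table(s$junctions)
  } else if (!is.null(s$rna_bam)) {
    if (is.null(model)) abort("junction extraction from alignments needs a gene model")
    extract_junction_counts(
      s$rna_bam, model, min_overhang = params$min_overhang, sample = label
    )
  } else {
    NULL
  }
  psi <- if (!is.null(junctions)) {
    compute_psi(junctions, min_total = params$min_total)
  } else {
    tibble(sample = label, psi_skip = NA_real_, psi_skip_pct = NA_real_)
  }
  log_stage("psi", sprintf("percent skipping %.1f", psi$psi_skip_pct[1]))

  contrast <- NULL
  normal_verdict <- NA_character_
  tumor_specific <- NA
  if (!is.null(normal) && !is.null(normal$rna_counts)) {
    nrna <- load_counts(normal$rna_counts, "normal rna_counts")
    nimb <- allele_fraction(nrna, calls) |>
      test_imbalance(
        alpha = params$alpha, effect_floor = params$effect_floor,
        min_depth = params$min_depth
      )
    contrast <- compare_tumor_normal(imb, nimb, alpha = params$alpha)
    normal_verdict <- contrast$normal_summary$verdict
    tumor_specific <- contrast$tumor_specific
    log_stage("contrast", sprintf(
      "normal %s; tumor-specific ASE: %s", normal_verdict, tumor_specific
    ))
  }

  if (!is.null(out_dir)) {
    write_counts_tsv(dna, file.path(out_dir, paste0(label, ".dna.counts.tsv")))
    write_counts_tsv(rna, file.path(out_dir, paste0(label, ".rna.counts.tsv")))
    readr::write_tsv(imb, file.path(out_dir, paste0(label, ".ase.tsv")))
    jsonlite::write_json(
      c(as.list(summ), list(psi_skip_pct = psi$psi_skip_pct[1])),
      file.path(out_dir, paste0(label, ".summary.json")),
      auto_unbox = TRUE, digits = NA
    )
  }

  list(
    row = tibble(
      sample = label,
      n_het_sites = as.integer(sum(calls$call == "het")),
      imbalance_verdict = summ$verdict,
      pooled_alt_fraction = summ$pooled_fraction,
      psi_skip_pct = psi$psi_skip_pct[1],
      normal_verdict = normal_verdict,
      tumor_specific = tumor_specific,
      error = NA_character_
    ),
    calls = calls, imbalance = imb, summary = summ, psi = psi,
    contrast = contrast, germline_source = germline_src
  )
}

pipeline_params <- function(p) {
  defaults <- list(
    het_window = c(0.2, 0.8), min_depth = 14, genotype_alpha = 0.001,
    hom_cut = 0.02, alpha = 0.05, effect_floor = 0.15,
    min_overhang = 6, min_total = 10
  )
  if (is.null(p)) return(defaults)
  for (nm in names(p)) defaults[[nm]] <- p[[nm]]
  defaults
}

load_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    abort("malformed config: expected a list or a YAML/JSON path")
  }
}

load_counts <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(as_tibble(x))
  if (is.character(x)) {
    if (!file.exists(x)) abort(sprintf("missing %s file: %s", what, x))
    return(read_counts_tsv(x))
  }
  abort(sprintf("%s must be a tibble or a TSV path", what))
}

load_table <- function(x) {
  if (is.data.frame(x)) return(as_tibble(x))
  readr::read_tsv(x, show_col_types = FALSE)
}

config_hashes <- function(config) {
  paths <- unlist(lapply(config$samples, function(s) {
    unlist(Filter(
      function(v) is.character(v) && length(v) == 1 && file.exists(v),
      s
    ))
  }))
  if (length(paths) == 0) return(character(0))
  tools::md5sum(paths)
}
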
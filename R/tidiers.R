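#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a tumor/normal contrast
#'
#' @param x A `tn_contrast` from [compare_tumor_normal()].
#' @param ... Unused.
#' @return Per-site tibble with both samples' fractions, verdicts, and the
#'   Fisher exact p-value.
#' @method tidy tn_contrast
#' @export
tidy.tn_contrast <- function(x, ...) {
  x$sites |>
    select(
      "contig", "pos", "ref", "alt",
      "f_rna_tumor", "f_rna_normal",
      "verdict_tumor", "verdict_normal", "fisher_p"
    )
}

#' @rdname tidy.tn_contrast
#' @return `glance()`: one-row tibble with the two pooled fractions and
#'   verdicts and the tumor-specific ASE flag.
#' @method glance tn_contrast
#' @export
glance.tn_contrast <- function(x, ...) {
  tibble(
    n_shared_sites = nrow(x$sites),
    tumor_pooled_fraction = x$tumor_summary$pooled_fraction,
    tumor_verdict = x$tumor_summary$verdict,
    normal_pooled_fraction = x$normal_summary$pooled_fraction,
    normal_verdict = x$normal_summary$verdict,
    tumor_specific = x$tumor_specific
  )
}
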
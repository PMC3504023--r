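#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a RAD run into per-sample summary rows
#'
#' @param x A `rad_run`.
#' @param ... Unused.
#' @return The per-sample summary tibble (reads, megabases, tags, contigs,
#'   mean length, N50, length range, putative SNPs, het fraction, ts/tv,
#'   SNP density).
#' @export
tidy.rad_run <- function(x, ...) x$sample_summary

#' One-row summary of a RAD run
#'
#' @inheritParams tidy.rad_run
#' @return One-row tibble with run-level totals.
#' @export
glance.rad_run <- function(x, ...) {
  vs <- x$variant_summary
  tibble(
    n_pairs = sum(x$sample_summary$n_pairs),
    n_rejected = x$demux_rejected,
    n_clusters = nrow(x$unitags),
    n_contigs = nrow(x$contigs),
    reference_sample = x$reference_sample,
    n_sites = if (!is.null(vs)) vs$totals$n_sites else 0L,
    het_pct = if (!is.null(vs)) vs$totals$het_pct else NA_real_,
    tstv_ratio = if (!is.null(x$tstv)) x$tstv$ratio else NA_real_,
    n_assayable = nrow(x$markers),
    n_plexes = if (nrow(x$markers)) max(x$markers$plex) else 0L,
    n_fixed_het = sum(x$fixed_het$fixed_het))
}

#' Tidy a shotgun run into per-class SSR rows
#'
#' @param x A `shotgun_run`.
#' @param ... Unused.
#' @return The per-class SSR count tibble.
#' @export
tidy.shotgun_run <- function(x, ...) x$ssr_summary$per_class

#' One-row summary of a shotgun run
#'
#' @inheritParams tidy.shotgun_run
#' @return One-row tibble with assembly, call and SSR totals.
#' @export
glance.shotgun_run <- function(x, ...) {
  vs <- x$variant_summary
  n_snp <- if (!is.null(vs)) vs$totals$n_sites else 0L
  tibble(
    n_contigs = nrow(x$contigs),
    total_bp = x$assembly$total_bp[1],
    n50 = x$assembly$n50[1],
    n_snps = n_snp,
    n_indels = nrow(dplyr::distinct(
      dplyr::filter(x$calls, .data$is_indel),
      .data$contig_id, .data$pos, .data$alt)),
    n_ssrs = x$ssr_summary$totals$n_total,
    pal_pct = x$ssr_summary$totals$pal_pct)
}

#' Tidy methods for summary objects
#'
#' @param x A `variant_summary`, `ssr_summary` or `genotyping_qc` object.
#' @param ... Unused.
#' @return A tibble: substitution classes, per-class SSR counts, or
#'   per-sample error rates respectively; `glance()` returns the one-row
#'   totals.
#' @export
tidy.variant_summary <- function(x, ...) x$classes

#' @rdname tidy.variant_summary
#' @export
glance.variant_summary <- function(x, ...) x$totals

#' @rdname tidy.variant_summary
#' @export
tidy.ssr_summary <- function(x, ...) x$per_class

#' @rdname tidy.variant_summary
#' @export
glance.ssr_summary <- function(x, ...) x$totals

#' @rdname tidy.variant_summary
#' @export
tidy.genotyping_qc <- function(x, ...) x$per_sample

#' @rdname tidy.variant_summary
#' @export
glance.genotyping_qc <- function(x, ...) {
  dplyr::bind_cols(
    x$overall %>%
      select("ado_rate", "fa_rate", "positive_pcr_rate"),
    tibble(mean_ho = x$ho$mean_ho, mna = x$mna_value,
           polymorphic_pct = x$polymorphic$percent))
}
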
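#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_col labs facet_wrap theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Contig length distribution of a RAD run
#'
#' Histogram of assembled contig lengths per sample, with each sample's N50
#' marked.
#'
#' @param object A `rad_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rad_run <- function(object, ...) {
  n50s <- object$contigs %>%
    group_by(.data$sample) %>%
    summarise(n50 = n50(.data$length), .groups = "drop")
  ggplot(object$contigs, aes(x = .data$length)) +
    geom_histogram(binwidth = 10, fill = "grey35") +
    geom_vline(data = n50s, aes(xintercept = .data$n50),
               linetype = "dashed", colour = "firebrick") +
    facet_wrap(~sample) +
    labs(x = "contig length (bp)", y = "contigs",
         title = "RAD locus assembly",
         subtitle = "dashed line: per-sample N50") +
    theme_minimal()
}

#' Microsatellite class counts of a shotgun run
#'
#' @param object A `shotgun_run` or `ssr_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_summary <- function(object, ...) {
  d <- object$per_class %>%
    tidyr::pivot_longer(c("n", "n_pal"), names_to = "what",
                        values_to = "count") %>%
    mutate(what = ifelse(.data$what == "n", "all", "PAL"))
  ggplot(d, aes(x = .data$class, y = .data$count, fill = .data$what)) +
    geom_col(position = position_dodge()) +
    labs(x = "repeat class", y = "loci", fill = NULL,
         title = "Microsatellites by motif class") +
    theme_minimal()
}

#' @rdname autoplot.ssr_summary
#' @export
autoplot.shotgun_run <- function(object, ...) {
  autoplot(object$ssr_summary, ...)
}

#' Per-sample genotyping error rates
#'
#' Allelic-dropout and false-allele rates per sample from a replicate QC
#' report.
#'
#' @param object A `genotyping_qc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotyping_qc <- function(object, ...) {
  d <- object$per_sample %>%
    select("sample", "ado_rate", "fa_rate") %>%
    tidyr::pivot_longer(c("ado_rate", "fa_rate"), names_to = "rate_type",
                        values_to = "rate") %>%
    mutate(rate_type = dplyr::recode(.data$rate_type,
                                     ado_rate = "allelic dropout",
                                     fa_rate = "false allele"))
  ggplot(d, aes(x = .data$sample, y = .data$rate, fill = .data$rate_type)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "rate per positive PCR", fill = NULL,
         title = "Replicate genotyping error rates") +
    theme_minimal()
}
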
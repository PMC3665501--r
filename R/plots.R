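#' @export
autoplot.roc_curve <- function(object, ...) {
  fr <- roc_fractions(object)
  df <- tibble::tibble(fpr = fr[, 1L], tpr = fr[, 2L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate (x0 / t0)",
                  y = "true positive rate (x1 / t1)",
                  title = "Prevalence-mapping ROC curve")
}

#' Plot a pair ROC curve against its two marginal curves
#'
#' The visual form of the gain test: the pair's 9-piece curve (red) always
#' dominates the two 3-piece single-SNP curves; a large gap is what GSS
#' quantifies.
#'
#' @param pair_roc,roc1,roc2 [build_roc()] curves on the same samples.
#' @return A ggplot object.
#' @export
plot_roc_gain <- function(pair_roc, roc1, roc2) {
  mk <- function(roc, label) {
    fr <- roc_fractions(roc)
    tibble::tibble(fpr = fr[, 1L], tpr = fr[, 2L], curve = label)
  }
  df <- dplyr::bind_rows(mk(pair_roc, "pair"), mk(roc1, "SNP 1"),
                         mk(roc2, "SNP 2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(pair = "firebrick",
                                            `SNP 1` = "steelblue",
                                            `SNP 2` = "seagreen")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL)
}

#' @export
autoplot.power_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$power,
                                   colour = .data$filter,
                                   linetype = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(family ~ maf,
                        labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "sample size (cases + controls)",
                  y = "power at the Bonferroni threshold")
}

#' Bar chart of per-SNP pair-membership counts
#'
#' @param records tibble of pair records (see [snp_frequency_report()]).
#' @param top show only the `top` most frequent SNPs.
#' @return A ggplot object.
#' @export
plot_snp_frequency <- function(records, top = 50L) {
  freq <- head(snp_frequency_report(records), top)
  freq$snp_id <- factor(freq$snp_id, levels = rev(freq$snp_id))
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$snp_id, y = .data$n_pairs)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "pairs containing the SNP")
}

#' Scatter of log2 odds ratio versus critical sens/spec
#'
#' Reference lines mark the minimum-coverage requirement (critical
#' sens/spec = 2%) and odds ratios of 2 and 1/2.
#'
#' @param records tibble with `odds_ratio`, `critical_sens_spec`,
#'   `direction` (e.g. [gss_stage()] output).
#' @return A ggplot object.
#' @export
plot_or_sensspec <- function(records) {
  rep <- or_sensspec_report(records)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$critical_sens_spec,
                                    y = .data$log2_or,
                                    colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0.02, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "critical sens/spec", y = "log2 odds ratio",
                  colour = NULL)
}
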
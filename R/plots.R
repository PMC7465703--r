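#' @include AllClasses.R
NULL

#' Manhattan plot of combined association results
#'
#' Combined -log10 p against genomic position, chromosomes concatenated in
#' order, with horizontal lines at the Bonferroni and soft thresholds.
#'
#' @param combined a [CombinedResult-class].
#' @return a ggplot object.
#' @export
plotManhattan <- function(combined) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  st <- combined@stats
  chroms <- unique(st$chrom[order(st$chrom)])
  st <- st[order(match(st$chrom, chroms), st$pos), ]
  offsets <- c(0, cumsum(tapply(st$pos, factor(st$chrom, levels = chroms),
                                max)))
  st$x <- st$pos + offsets[match(st$chrom, chroms)]
  st$logp <- -log10(pmax(st$combined_p, .Machine$double.xmin))
  th <- combined@thresholds
  ggplot2::ggplot(st, ggplot2::aes(x = x, y = logp, colour = chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(th[["bonferroni"]]),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(th[["soft"]]),
                        colour = "grey40", linetype = 2) +
    ggplot2::labs(x = "position (chromosomes concatenated)",
                  y = expression(-log[10] * " combined p")) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("x", "logp", "chrom"))
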
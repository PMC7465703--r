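#' @include AllClasses.R
NULL

#' VNIIMK glucosinolate content classification
#'
#' Low: below 15 umol/g fresh weight; middle: 15 to 25 inclusive; high:
#' above 25.  The three classes partition the non-negative axis with no
#' gaps or overlaps.
#'
#' @param value glucosinolate content, umol/g fresh weight (vectorized,
#'   non-negative).
#' @return factor with levels `low`, `middle`, `high`.
#' @export
#' @examples
#' classifyGsl(c(11.0, 16.3, 35.8))
classifyGsl <- function(value) {
  value <- as.numeric(value)
  if (any(is.na(value)) || any(value < 0))
    stop("glucosinolate values must be non-negative")
  cls <- ifelse(value < 15, "low", ifelse(value <= 25, "middle", "high"))
  factor(cls, levels = c("low", "middle", "high"))
}

#' Cross-year phenotype agreement
#'
#' Pairwise-complete Pearson correlation of line values for every year
#' pair, plus cohort summaries.  The cohort mean is reported both as the
#' grand mean over all line-by-year values and as the mean of per-line
#' means (the two differ when years are unbalanced).
#'
#' @param pheno phenotype data.frame (`line_id`, `year`, `gsl_umol_g`).
#' @return list with `correlations` (data.frame `year_a`, `year_b`, `r`,
#'   `n`), `line_means` (named vector), `grand_mean`,
#'   `mean_of_line_means`, `min`, `max`.
#' @export
yearCorrelations <- function(pheno) {
  years <- sort(unique(pheno$year))
  if (length(years) < 2L) stop("at least two years required")
  wide <- stats::reshape(
    pheno[, c("line_id", "year", "gsl_umol_g")],
    idvar = "line_id", timevar = "year", direction = "wide")
  vals <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(vals) <- sub("^gsl_umol_g\\.", "", colnames(vals))
  comb <- utils::combn(years, 2L)
  cors <- apply(comb, 2L, function(pr) {
    x <- vals[, pr[1L]]; y <- vals[, pr[2L]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) stop("fewer than 3 shared lines for years ",
                           pr[1L], " and ", pr[2L])
    c(r = stats::cor(x[ok], y[ok]), n = sum(ok))
  })
  lm_ <- rowMeans(vals, na.rm = TRUE)
  names(lm_) <- wide$line_id
  list(correlations = data.frame(year_a = comb[1L, ], year_b = comb[2L, ],
                                 r = cors["r", ], n = as.integer(cors["n", ]),
                                 stringsAsFactors = FALSE),
       line_means = lm_,
       grand_mean = mean(pheno$gsl_umol_g),
       mean_of_line_means = mean(lm_),
       min = min(pheno$gsl_umol_g), max = max(pheno$gsl_umol_g))
}
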
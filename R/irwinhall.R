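#' @include AllClasses.R
NULL

#' Irwin-Hall density and distribution function
#'
#' The Irwin-Hall distribution is the law of the sum of `n` independent
#' Uniform(0,1) variables.  Closed forms:
#' density `f_n(x) = 1/(n-1)! * sum_{k=0}^{floor(x)} (-1)^k C(n,k) (x-k)^(n-1)`
#' and CDF `F_n(x) = 1/n! * sum_{k=0}^{floor(x)} (-1)^k C(n,k) (x-k)^n`
#' on `[0, n]`; 0 below and (for the CDF) 1 above.
#'
#' With `n` per-environment p-values that are null-uniform, the CDF at
#' their sum is the combined significance used to rank SNPs across years.
#'
#' @param x quantile(s), vectorized.
#' @param n number of uniform summands (years), `n >= 1`.
#' @return density / probability values.
#' @export
#' @examples
#' irwinHallPdf(1.5, 3)   # 0.75
#' irwinHallCdf(1.5, 3)   # 0.5
irwinHallPdf <- function(x, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  vapply(x, function(xx) {
    if (!is.finite(xx) || xx < 0 || xx > n) return(0)
    k <- 0:floor(min(xx, n))
    sum((-1)^k * choose(n, k) * (xx - k)^(n - 1)) / factorial(n - 1)
  }, 0)
}

#' @rdname irwinHallPdf
#' @export
irwinHallCdf <- function(x, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  vapply(x, function(xx) {
    if (!is.finite(xx)) return(NA_real_)
    if (xx <= 0) return(0)
    if (xx >= n) return(1)
    k <- 0:floor(xx)
    min(1, max(0, sum((-1)^k * choose(n, k) * (xx - k)^n) / factorial(n)))
  }, 0)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.  The reporting layer prints it rounded to two
#'   significant figures (0.05 / 12226 prints as "0.0000041").
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (missing(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a positive count")
  alpha / m
}

#' Combine per-year association scans via the Irwin-Hall distribution
#'
#' For each SNP the yearly p-values are summed; the combined p-value is the
#' Irwin-Hall CDF of the sum for `n` = number of years (the density at the
#' sum is reported alongside — on the left tail the two rank identically,
#' but only the CDF is a probability comparable to a Bonferroni-corrected
#' alpha).  Significance flags are set against `alpha / m` (with `m` the
#' number of SNPs) and the soft threshold.
#'
#' @param results list of per-year [AssociationResult-class] objects (or
#'   data.frames with `snp_id` and `p`); identical SNP sets required.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param soft soft significance threshold on the combined p-value.
#' @return A [CombinedResult-class].
#' @export
combineYears <- function(results, alpha = 0.05, soft = 5e-4) {
  tabs <- lapply(results, function(r)
    if (is(r, "AssociationResult")) r@stats else as.data.frame(r))
  ny <- length(tabs)
  if (ny < 2L) stop("at least two yearly scans required")
  ids <- tabs[[1L]]$snp_id
  for (j in 2L:ny) {
    if (!setequal(ids, tabs[[j]]$snp_id)) {
      dd <- union(setdiff(ids, tabs[[j]]$snp_id),
                  setdiff(tabs[[j]]$snp_id, ids))
      stop("SNP sets differ between scans; symmetric difference: ",
           paste(utils::head(dd, 10L), collapse = ", "),
           if (length(dd) > 10L) ", ..." else "")
    }
    tabs[[j]] <- tabs[[j]][match(ids, tabs[[j]]$snp_id), ]
  }
  P <- sapply(tabs, function(t) t$p)
  colnames(P) <- paste0("p", seq_len(ny))
  S <- rowSums(P)
  dens <- irwinHallPdf(S, ny)
  cp <- irwinHallCdf(S, ny)
  m <- length(ids)
  bon <- bonferroniThreshold(alpha, m)
  st <- data.frame(snp_id = ids,
                   chrom = tabs[[1L]]$chrom %||% NA_character_,
                   pos = tabs[[1L]]$pos %||% NA_integer_,
                   P, S = S, density = dens, combined_p = cp,
                   sig_bonferroni = cp < bon, sig_soft = cp < soft,
                   row.names = NULL, stringsAsFactors = FALSE)
  new("CombinedResult", stats = st,
      thresholds = c(alpha = alpha, m = m, bonferroni = bon, soft = soft))
}
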
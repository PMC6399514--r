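#' Pearson correlation of two paired series
#'
#' Product-moment r with the two-sided t-test p-value
#' (t = r * sqrt(n - 2) / sqrt(1 - r^2)). Pairs with a missing member are
#' dropped (count reported via message when any are).
#'
#' @param x,y numeric vectors of equal length.
#' @return data.frame with `r`, `p`, `n` (pairs used).
#' @export
pearson_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (sum(!keep) > 0L) message(sum(!keep), " pair(s) with missing values dropped")
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("zero variance in x series")
  if (stats::var(y) == 0) stop("zero variance in y series")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

.stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Per-site correlation of methylation with a phenotype
#'
#' Correlates each CpG site's per-group methylation rate with a per-group
#' phenotype series (expression or color), optionally with Benjamini-Hochberg
#' adjustment across sites. Sites with undefined rates in more than half of
#' the groups are excluded with a warning.
#'
#' @param site_rates groups x sites matrix of per-site rates (e.g.
#'   `coef(fit)`).
#' @param phenotype numeric vector, one value per group (row order).
#' @param adjust `"none"` (the default, one unadjusted p per site) or `"bh"`.
#' @return data.frame `site`, `r`, `p`, `adjusted_p` (NA when
#'   `adjust = "none"`), `n`, `stars`, sorted by site ordinal.
#' @export
site_correlation_table <- function(site_rates, phenotype,
                                   adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(nrow(site_rates) == length(phenotype))
  ns <- ncol(site_rates)
  half <- floor(nrow(site_rates) / 2)
  rows <- lapply(seq_len(ns), function(s) {
    rate <- site_rates[, s]
    if (sum(!is.finite(rate)) > half) {
      warning("site ", s, " excluded: rate undefined in more than half the groups")
      return(NULL)
    }
    res <- pearson_assoc(rate, phenotype)
    data.frame(site = s, r = res$r, p = res$p, n = res$n)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (adjust == "bh") stats::p.adjust(out$p, "BH") else NA_real_
  out$stars <- .stars(out$p)
  out[order(out$site), c("site", "r", "p", "adjusted_p", "n", "stars")]
}

#' Flag candidate key regulatory CpG sites
#'
#' A site is flagged when it is both significantly *negatively* correlated
#' with expression at level `alpha` and covered by a predicted transcription
#' factor binding site.
#'
#' @param correlations table from [site_correlation_table()] (methylation vs
#'   expression).
#' @param covered_sites integer vector of site ordinals lying inside
#'   predicted TF binding sites (see [overlap_cpg()]).
#' @param alpha significance level.
#' @param use_adjusted use the BH-adjusted p column instead of raw p.
#' @return sorted integer vector of flagged site ordinals.
#' @export
flag_key_sites <- function(correlations, covered_sites, alpha = 0.05,
                           use_adjusted = FALSE) {
  p <- if (use_adjusted) correlations$adjusted_p else correlations$p
  sig <- correlations$site[correlations$r < 0 & p < alpha]
  sort(intersect(sig, covered_sites))
}
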
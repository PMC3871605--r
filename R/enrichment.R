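check_counts <- function(nf, n, Nf, N) {
  v <- c(nf = nf, n = n, Nf = Nf, N = N)
  if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nf > n) stop("inconsistent counts: nf > n", call. = FALSE)
  if (nf > Nf) stop("inconsistent counts: nf > Nf", call. = FALSE)
  if (n > N) stop("inconsistent counts: n > N", call. = FALSE)
  if (Nf > N) stop("inconsistent counts: Nf > N", call. = FALSE)
  if (nf < n + Nf - N) {
    stop("inconsistent counts: nf below the hypergeometric support",
         call. = FALSE)
  }
  invisible(v)
}

#' Two-sided Fisher's exact test on a 2x2 category table
#'
#' Tests whether a gene category is over- or under-represented among
#' flagged (e.g. differentially expressed) genes. The table is: `nf`
#' flagged genes inside the category, out of `n` category genes, with `Nf`
#' flagged among `N` background genes. Two-sidedness follows the
#' minimum-likelihood convention: the p-value sums the hypergeometric
#' probabilities of every table (with the same margins) whose probability
#' does not exceed that of the observed table. An empty category or empty
#' background carries no information and returns p = 1.
#'
#' @param nf flagged genes within the category.
#' @param n total genes within the category.
#' @param Nf flagged genes in the whole background.
#' @param N total genes in the background.
#' @return two-sided exact p-value in (0, 1].
#' @examples
#' fisher_two_sided(2, 2, 2, 4)  # 1/3
#' @export
fisher_two_sided <- function(nf, n, Nf, N) {
  check_counts(nf, n, Nf, N)
  if (n == 0L || Nf == 0L || N == 0L || n == N || Nf == N) return(1)
  lo <- max(0L, n + Nf - N)
  hi <- min(n, Nf)
  d <- stats::dhyper(lo:hi, Nf, N - Nf, n)
  # relative tolerance guards ties degraded by floating-point rounding
  p <- sum(d[d <= d[nf - lo + 1L] * (1 + 1e-7)])
  min(p, 1)
}

#' Pearson chi-squared p-value on a 2x2 category table
#'
#' Companion classification test to [fisher_two_sided()]: the Pearson
#' chi-squared statistic on the category-by-flagged 2x2 table, 1 degree of
#' freedom, no continuity correction. A zero margin (empty or exhaustive
#' category, no or all genes flagged) carries no information and returns
#' p = 1 by convention.
#'
#' @inheritParams fisher_two_sided
#' @return p-value in [0, 1].
#' @export
chi_square_p <- function(nf, n, Nf, N) {
  check_counts(nf, n, Nf, N)
  if (n == 0L || n == N || Nf == 0L || Nf == N) return(1)
  a <- nf; b <- n - nf; c <- Nf - nf; d <- N - n - Nf + nf
  stat <- N * (a * d - b * c)^2 / (as.numeric(n) * (N - n) * Nf * (N - Nf))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Empirical Fisher-versus-chi-squared false discovery rate
#'
#' A single global FDR for a batch of category tests, defined as
#' `1 - Nk / T` where `T` is the number of categories tested and `Nk` the
#' number whose Fisher p-value is strictly below its paired chi-squared
#' p-value. The scalar applies to the batch as a whole.
#'
#' @param p_fisher,p_chi2 paired p-value vectors of equal positive length.
#' @return a single FDR value in [0, 1].
#' @examples
#' empirical_fdr(c(.01, .2, .03, .5), c(.02, .3, .01, .6))  # 1 - 3/4
#' @export
empirical_fdr <- function(p_fisher, p_chi2) {
  if (length(p_fisher) == 0L || length(p_fisher) != length(p_chi2)) {
    stop("need equal-length, non-empty p-value vectors", call. = FALSE)
  }
  1 - sum(p_fisher < p_chi2) / length(p_fisher)
}

#' Enrichment ratio Re
#'
#' The proportion of flagged genes inside a category relative to the
#' proportion flagged in the whole background:
#' `Re = (nf / n) / (Nf / N)`. Values above 1 indicate over-representation.
#'
#' @inheritParams fisher_two_sided
#' @return non-negative enrichment ratio.
#' @examples
#' enrichment_ratio(5, 10, 50, 1000)  # 10
#' @export
enrichment_ratio <- function(nf, n, Nf, N) {
  check_counts(nf, n, Nf, N)
  for (z in c(n = n, Nf = Nf, N = N)) if (z == 0L) {
    bad <- names(which(c(n = n, Nf = Nf, N = N) == 0L))[1]
    stop("count '", bad, "' must be positive for the enrichment ratio",
         call. = FALSE)
  }
  (nf / n) / (Nf / N)
}

#' Category enrichment of a selected gene list
#'
#' For every category with at least one background gene, builds the 2x2
#' counts from set intersections and computes the two-sided Fisher p, the
#' Pearson chi-squared p, the enrichment ratio Re, a BH adjustment of the
#' Fisher p-values, and the global empirical Fisher-versus-chi-squared FDR
#' (attached identically to every record). Records are sorted by ascending
#' Fisher p, ties broken by category ID.
#'
#' @param selected_genes character vector of flagged gene IDs; must be a
#'   subset of `background_genes`.
#' @param annotation data.frame with columns `gene` and `category`, one
#'   pair per row.
#' @param background_genes the gene universe; by default every annotated
#'   gene in `annotation`.
#' @return data.frame with columns `category`, `nf`, `n`, `Nf`, `N`,
#'   `p_fisher`, `p_chi2`, `fdr_empirical`, `fdr_bh`, `re`.
#' @export
enrich <- function(selected_genes, annotation,
                   background_genes = unique(annotation$gene)) {
  if (!all(c("gene", "category") %in% names(annotation))) {
    stop("'annotation' needs columns 'gene' and 'category'", call. = FALSE)
  }
  background_genes <- unique(background_genes)
  selected_genes <- unique(selected_genes)
  stray <- setdiff(selected_genes, background_genes)
  if (length(stray)) {
    stop("selected genes absent from background: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  ann <- annotation[annotation$gene %in% background_genes, , drop = FALSE]
  ann <- unique(ann[, c("gene", "category")])
  if (nrow(ann) == 0L) {
    stop("annotation covers no background gene", call. = FALSE)
  }
  N <- length(background_genes)
  Nf <- length(selected_genes)
  cats <- sort(unique(ann$category))
  flagged <- ann$gene %in% selected_genes
  n <- as.integer(table(factor(ann$category, levels = cats)))
  nf <- as.integer(table(factor(ann$category[flagged], levels = cats)))
  p_f <- mapply(fisher_two_sided, nf, n, MoreArgs = list(Nf = Nf, N = N))
  p_c <- mapply(chi_square_p, nf, n, MoreArgs = list(Nf = Nf, N = N))
  re <- if (Nf > 0) (nf / n) / (Nf / N) else rep(NA_real_, length(cats))
  out <- data.frame(
    category = cats, nf = nf, n = n, Nf = Nf, N = N,
    p_fisher = unname(p_f), p_chi2 = unname(p_c),
    fdr_empirical = empirical_fdr(p_f, p_c),
    fdr_bh = adjust_fdr(unname(p_f)),
    re = re,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_fisher, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
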
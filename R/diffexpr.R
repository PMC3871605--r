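split_conditions <- function(matrix, design) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix", call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("gene and sample identifiers must be unique", call. = FALSE)
  }
  if (!all(c("sample", "condition") %in% names(design))) {
    stop("'design' needs columns 'sample' and 'condition'", call. = FALSE)
  }
  labs <- sort(unique(design$condition))
  if (length(labs) != 2L) {
    stop("'design' must contain exactly two condition labels", call. = FALSE)
  }
  missing <- setdiff(design$sample, colnames(matrix))
  if (length(missing)) {
    stop("design samples absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- design$sample[design$condition == labs[1]]
  b <- design$sample[design$condition == labs[2]]
  for (cc in list(c(labs[1], length(a)), c(labs[2], length(b)))) {
    if (as.integer(cc[2]) == 0L) {
      stop("condition '", cc[1], "' has no samples", call. = FALSE)
    }
  }
  list(a = matrix[, a, drop = FALSE], b = matrix[, b, drop = FALSE],
       labels = labs)
}

#' Per-gene log2 fold change between two conditions
#'
#' The effect is the second condition's mean log2 intensity minus the
#' first's (conditions ordered by sorted label, so `"B"` minus `"A"`).
#'
#' @param matrix numeric genes x samples matrix of log2 intensities with
#'   unique row and column names.
#' @param design data.frame with columns `sample` and `condition` (exactly
#'   two labels).
#' @return named numeric vector of log2 fold changes, one per gene.
#' @examples
#' m <- rbind(g1 = c(8, 8, 10, 10))
#' colnames(m) <- c("s1", "s2", "s3", "s4")
#' d <- data.frame(sample = colnames(m), condition = c("A", "A", "B", "B"))
#' log2_fold_change(m, d)  # 2
#' @export
log2_fold_change <- function(matrix, design) {
  g <- split_conditions(matrix, design)
  rowMeans(g$b) - rowMeans(g$a)
}

#' Welch two-sample t-test p-values, one gene per row
#'
#' Unequal-variance t-test on log2 values, vectorised across genes. With
#' zero variance in both groups the p-value is 1 when the means agree
#' (no evidence of a difference) and 0 when they differ (an exact,
#' noiseless separation). Requires at least two samples per condition.
#'
#' @inheritParams log2_fold_change
#' @return named numeric vector of two-sided p-values in [0, 1].
#' @export
test_differential <- function(matrix, design) {
  g <- split_conditions(matrix, design)
  na <- ncol(g$a); nb <- ncol(g$b)
  if (na < 2L || nb < 2L) {
    stop("each condition needs >= 2 samples for the per-gene test",
         call. = FALSE)
  }
  ma <- rowMeans(g$a); mb <- rowMeans(g$b)
  va <- apply(g$a, 1L, stats::var)
  vb <- apply(g$b, 1L, stats::var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & (mb - ma) == 0] <- 1
  p[degenerate & (mb - ma) != 0] <- 0
  names(p) <- rownames(matrix)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validating wrapper over
#' [stats::p.adjust()] so the selection rule in [select_degs()] has one
#' documented entry point.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted values in [0, 1], same order and names as `p`.
#' @export
adjust_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Build the per-gene differential-expression table
#'
#' Combines fold change, raw Welch p-value and BH-adjusted FDR, then
#' applies the selection gates of [select_degs()].
#'
#' @inheritParams log2_fold_change
#' @param fc_threshold minimum linear fold change `2^|log2fc|` (default 2,
#'   the classic two-fold gate).
#' @param fdr_threshold select only genes with adjusted FDR strictly below
#'   this (default 0.05; 0.10 is the other conventional choice).
#' @param p_threshold optional additional gate on the raw p-value.
#' @return data.frame with columns `gene`, `log2fc`, `fold_change`,
#'   `p_raw`, `fdr`, `direction` (`"up"`/`"down"`) and logical `selected`.
#' @export
differential_expression <- function(matrix, design, fc_threshold = 2,
                                    fdr_threshold = 0.05,
                                    p_threshold = NULL) {
  lfc <- log2_fold_change(matrix, design)
  p <- test_differential(matrix, design)
  rec <- data.frame(
    gene = rownames(matrix),
    log2fc = unname(lfc),
    fold_change = 2^abs(unname(lfc)),
    p_raw = unname(p),
    fdr = unname(adjust_fdr(p)),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  select_degs(rec, fc_threshold, fdr_threshold, p_threshold)
}

#' Apply fold-change and FDR selection gates
#'
#' A record is selected iff `fold_change >= fc_threshold` and
#' `fdr < fdr_threshold` and, when `p_threshold` is given,
#' `p_raw < p_threshold`.
#'
#' @param records data.frame with at least `fold_change`, `fdr`, and
#'   `p_raw` when `p_threshold` is used.
#' @inheritParams differential_expression
#' @return `records` with a recomputed logical `selected` column.
#' @export
select_degs <- function(records, fc_threshold = 2, fdr_threshold = 0.05,
                        p_threshold = NULL) {
  sel <- records$fold_change >= fc_threshold & records$fdr < fdr_threshold
  if (!is.null(p_threshold)) sel <- sel & records$p_raw < p_threshold
  records$selected <- sel
  records
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct target, treated - Ct reference, treated) -
#' (Ct target, control - Ct reference, control); the returned value is
#' 2^-ddCt, the expression of the target in the treated sample relative to
#' the control after normalising to the reference gene.
#'
#' @param ct_target_treated,ct_reference_treated,ct_target_control,ct_reference_control
#'   cycle-threshold values (finite numerics, vectorised).
#' @return relative expression `2^-ddCt`.
#' @examples
#' ddct_fold_change(20, 15, 22, 15)  # ddCt = -2 -> 4
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  if (!all(is.finite(cts))) {
    stop("all Ct values must be finite", call. = FALSE)
  }
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Deterministic ordering of genes and samples for heatmap reporting
#'
#' Average-linkage agglomerative clustering on 1 - Pearson correlation,
#' applied to rows (genes) and columns (samples) separately. Ties are
#' broken by input order; with fewer than two genes the input order is
#' returned unchanged.
#'
#' @param matrix numeric genes x samples matrix (typically restricted to
#'   selected genes).
#' @return list with character vectors `genes` and `samples`, each a
#'   permutation of the corresponding input names.
#' @export
cluster_order <- function(matrix) {
  ord1 <- function(m) {
    if (nrow(m) < 2L) return(rownames(m))
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
    h <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    rownames(m)[h$order]
  }
  list(genes = ord1(matrix), samples = ord1(t(matrix)))
}
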
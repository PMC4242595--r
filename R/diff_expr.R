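#' Audic-Claverie exact test for a tag-count difference
#'
#' For a gene with `x` tags in a library of `N1` clean tags and `y` tags in
#' a library of `N2`, the conditional distribution of `y` given `x` under
#' equal underlying expression is
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},}
#' a negative binomial with size `x + 1` and success probability
#' `N1 / (N1 + N2)`. The two-sided p-value doubles the smaller of the two
#' tails `P(Y <= y)` and `P(Y >= y)` and caps at 1. Tails are evaluated
#' through the regularized incomplete beta function, so there is no
#' overflow for counts up to at least 1e7.
#'
#' @param x,y non-negative integer tag counts (vectorized).
#' @param N1,N2 positive library denominators of `x` and `y`.
#' @return two-sided p-value(s) in (0, 1].
#' @export
audic_claverie_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y)))
    stopf("counts must be integers")
  if (any(N1 <= 0) || any(N2 <= 0)) stopf("library sizes must be positive")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  r <- N2 / N1
  p_lo <- pbeta(1 / (1 + r), x + 1, y + 1)          # P(Y <= y)
  p_hi <- ifelse(y == 0, 1, pbeta(r / (1 + r), pmax(y, 1), x + 1)) # P(Y >= y)
  pmin(1, 2 * pmin(p_lo, p_hi))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values, input order preserved.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values in \[0, 1\].
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-pair differential expression call
#'
#' Tests every gene of one tumor/normal pair with the Audic-Claverie exact
#' test on raw counts, adjusts across the pair's whole gene universe by
#' Benjamini-Hochberg, and calls a gene deregulated when both the fold
#' filter (|log2ratio| > `fold_threshold`) and the FDR filter
#' (q < `fdr_threshold`) hold. The signed log2 ratio is computed from
#' pseudocounted normalized expression,
#' `log2(((y + 1)/N2) / ((x + 1)/N1))` (one extra tag in each library), so
#' zeros are defined; the p-value uses the raw counts, which handle zeros
#' natively.
#'
#' @param tumor_counts,normal_counts named count vectors over the same gene
#'   universe, or two [map_tags()] results.
#' @param fold_threshold minimum |log2ratio| (default 1, i.e. 2-fold).
#' @param fdr_threshold maximum q (default 0.001, i.e. FDR < 0.1%).
#' @param N1,N2 library denominators of the normal and tumor library;
#'   default to the uniquely mapped totals.
#' @return data frame of class `pair_de`: gene_id, x (normal), y (tumor),
#'   N1, N2, log2ratio, fold, p, q, is_de, direction, detected.
#' @export
call_pair <- function(tumor_counts, normal_counts, fold_threshold = 1,
                      fdr_threshold = 0.001, N1 = NULL, N2 = NULL) {
  if (inherits(normal_counts, "library_counts")) {
    N1 <- N1 %||% normal_counts$unique_mapped_total
    normal_counts <- normal_counts$gene_counts
  }
  if (inherits(tumor_counts, "library_counts")) {
    N2 <- N2 %||% tumor_counts$unique_mapped_total
    tumor_counts <- tumor_counts$gene_counts
  }
  genes <- names(normal_counts)
  if (is.null(genes) || !identical(sort(genes), sort(names(tumor_counts))))
    stopf("tumor and normal counts must share one named gene universe")
  if (length(genes) == 0) stopf("empty gene universe")
  tumor_counts <- tumor_counts[genes]
  N1 <- N1 %||% sum(normal_counts)
  N2 <- N2 %||% sum(tumor_counts)

  x <- as.numeric(normal_counts); y <- as.numeric(tumor_counts)
  log2ratio <- log2(((y + 1) / N2) / ((x + 1) / N1))
  p <- audic_claverie_pvalue(x, y, N1, N2)
  q <- bh_fdr(p)
  is_de <- abs(log2ratio) > fold_threshold & q < fdr_threshold
  res <- data.frame(
    gene_id = genes, x = x, y = y, N1 = N1, N2 = N2,
    log2ratio = log2ratio, fold = abs(log2ratio), p = p, q = q,
    is_de = is_de,
    direction = ifelse(log2ratio > 0, "up",
                       ifelse(log2ratio < 0, "down", "none")),
    detected = x + y > 0,
    stringsAsFactors = FALSE
  )
  class(res) <- c("pair_de", "data.frame")
  res
}

#' @export
print.pair_de <- function(x, ...) {
  cat(sprintf("Pairwise DE: %d genes tested (N1 = %g, N2 = %g); %d deregulated (%d up, %d down)\n",
              nrow(x), x$N1[1], x$N2[1], sum(x$is_de),
              sum(x$is_de & x$direction == "up"),
              sum(x$is_de & x$direction == "down")))
  invisible(x)
}

#' Recurrently deregulated genes across a patient cohort
#'
#' A gene is recurrent when it is called deregulated in at least
#' `min_cases` pairs and the absolute mean signed log2 ratio over all
#' patients exceeds `min_avg_fold`. Direction follows the sign of the mean;
#' genes whose deregulated pairs disagree in sign are additionally flagged
#' mixed.
#'
#' @param pair_results list of [call_pair()] results (one per patient) over
#'   the same gene universe.
#' @param min_cases minimum number of deregulated pairs; defaults to half
#'   the cohort, rounded up (5 of 10).
#' @param min_avg_fold minimum |mean log2ratio| over all patients.
#' @return data frame of class `recurrence`: gene_id, n_de_pairs,
#'   mean_log2ratio, direction, mixed, is_recurrent.
#' @export
recurrent_genes <- function(pair_results, min_cases = NULL,
                            min_avg_fold = 1) {
  stopifnot(length(pair_results) >= 1)
  genes <- pair_results[[1]]$gene_id
  for (pr in pair_results)
    if (!identical(pr$gene_id, genes))
      stopf("all pair results must share one gene universe, in order")
  np <- length(pair_results)
  min_cases <- min_cases %||% ceiling(0.5 * np)

  l2r <- matrix(unlist(lapply(pair_results, `[[`, "log2ratio")),
                nrow = length(genes))
  de <- matrix(unlist(lapply(pair_results, `[[`, "is_de")),
               nrow = length(genes))
  n_de <- rowSums(de)
  mean_l2r <- rowMeans(l2r)
  mixed <- vapply(seq_along(genes), function(g) {
    s <- sign(l2r[g, de[g, ]])
    length(unique(s[s != 0])) > 1
  }, logical(1))
  res <- data.frame(
    gene_id = genes, n_de_pairs = n_de, mean_log2ratio = mean_l2r,
    direction = ifelse(mean_l2r > 0, "up",
                       ifelse(mean_l2r < 0, "down", "none")),
    mixed = mixed,
    is_recurrent = n_de >= min_cases & abs(mean_l2r) > min_avg_fold,
    stringsAsFactors = FALSE
  )
  attr(res, "min_cases") <- min_cases
  attr(res, "min_avg_fold") <- min_avg_fold
  attr(res, "n_patients") <- np
  class(res) <- c("recurrence", "data.frame")
  res
}

#' @export
print.recurrence <- function(x, ...) {
  rec <- x[x$is_recurrent, ]
  cat(sprintf("Recurrence over %d patients (>= %d cases, |avg log2ratio| > %g):\n",
              attr(x, "n_patients"), attr(x, "min_cases"),
              attr(x, "min_avg_fold")))
  cat(sprintf("  %d recurrent genes: %d up, %d down (%d mixed-sign)\n",
              nrow(rec), sum(rec$direction == "up"),
              sum(rec$direction == "down"), sum(rec$mixed)))
  invisible(x)
}

#' qPCR concordance with sequencing calls
#'
#' Computes `-ddCt = -(dCt_tumor - dCt_normal)` per gene x patient (dCt
#' values already normalized to the reference small RNA) and scores a pair
#' concordant when the sign of `-ddCt` matches the sign of the sequencing
#' log2 ratio; zero on either side is discordant.
#'
#' @param delta_ct_tumor,delta_ct_normal numeric matrices (genes x
#'   patients) of dCt values, with dimnames.
#' @param pair_results named list of [call_pair()] results; names must
#'   cover the dCt matrix columns.
#' @return list with `fraction` (concordant / total) and `table` (per
#'   gene x patient: minus_ddct, log2ratio, concordant).
#' @export
qpcr_concordance <- function(delta_ct_tumor, delta_ct_normal, pair_results) {
  stopifnot(identical(dim(delta_ct_tumor), dim(delta_ct_normal)),
            identical(dimnames(delta_ct_tumor), dimnames(delta_ct_normal)))
  genes <- rownames(delta_ct_tumor); pats <- colnames(delta_ct_tumor)
  if (!all(pats %in% names(pair_results)))
    stopf("pair_results missing patient(s): %s",
          paste(setdiff(pats, names(pair_results)), collapse = ", "))
  rows <- list()
  for (p in pats) {
    pr <- pair_results[[p]]
    m <- match(genes, pr$gene_id)
    if (anyNA(m))
      stopf("missing log2ratio for gene(s) %s in patient %s",
            paste(genes[is.na(m)], collapse = ", "), p)
    mddct <- -(delta_ct_tumor[, p] - delta_ct_normal[, p])
    l2r <- pr$log2ratio[m]
    rows[[p]] <- data.frame(gene_id = genes, patient = p,
                            minus_ddct = mddct, log2ratio = l2r,
                            concordant = sign(mddct) == sign(l2r) &
                              sign(mddct) != 0,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fraction = mean(tab$concordant), table = tab)
}
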
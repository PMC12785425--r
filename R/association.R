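#' Pairwise marker / behavior correlations
#'
#' Computes the requested correlations with two-sided p-values via
#' [stats::cor.test()] on complete pairs. Pearson is the default; Spearman
#' (midrank ties, t-approximation for the p-value) is required whenever the
#' ordinal coat-state score is involved and is forced for such pairs.
#'
#' @param table data.frame holding all variables (e.g. markers joined with
#'   end-of-study behavioral measures).
#' @param pairs data.frame with columns `a`, `b` and optionally `method`
#'   (`"pearson"`/`"spearman"`). If `NULL`, all unique pairs of `variables`
#'   are used.
#' @param variables variables for the all-pairs default (default: all
#'   numeric columns).
#' @param min_n minimum complete pairs (default 3); pairs below it yield a
#'   missing coefficient and are flagged in the output.
#' @param fdr_family `"all"` (default) adjusts the whole result as one BH
#'   family.
#' @return data.frame of class `correlation_result` with columns `a`, `b`,
#'   `method`, `coefficient`, `p`, `q`, `n_used`.
#' @export
correlate_pairs <- function(table, pairs = NULL, variables = NULL,
                            min_n = 3, fdr_family = "all") {
  if (is.null(pairs)) {
    if (is.null(variables))
      variables <- names(table)[vapply(table, is.numeric, logical(1))]
    idx <- utils::combn(variables, 2)
    pairs <- data.frame(a = idx[1, ], b = idx[2, ],
                        stringsAsFactors = FALSE)
  }
  if (is.null(pairs$method)) pairs$method <- "pearson"
  pairs$method[pairs$a == "coat_state" | pairs$b == "coat_state"] <-
    "spearman"

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]; method <- pairs$method[i]
    x <- table[[a]]; y <- table[[b]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    out <- data.frame(a = a, b = b, method = method,
                      coefficient = NA_real_, p = NA_real_,
                      n_used = n, stringsAsFactors = FALSE)
    if (n < min_n) {
      message("pair ", a, " ~ ", b, ": only ", n,
              " complete cases; skipped")
      return(out)
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("pair ", a, " ~ ", b, ": constant variable")
      return(out)
    }
    if (identical(a, b)) {          # self-pair: r = 1 by definition
      out$coefficient <- 1; out$p <- 0
      return(out)
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    out$coefficient <- unname(ct$estimate)
    out$p <- ct$p.value
    out
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  has_p <- !is.na(res$p)
  if (any(has_p)) res$q[has_p] <- bh_fdr(res$p[has_p])
  class(res) <- c("correlation_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values (BH-adjusted p), capped at 1.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' PCA of the marker panel
#'
#' Columns are standardized (mean 0, SD 1) before the decomposition, as the
#' markers are on heterogeneous percent-of-control scales. Each component is
#' oriented so its largest-magnitude loading is positive, making the output
#' deterministic. Per-marker score-PC Pearson correlations are reported for
#' the first `n_report` components.
#'
#' @param table expression table with no missing marker values (apply
#'   [impute_group_mean()] first).
#' @param n_report components to report marker-PC correlations for
#'   (default 3).
#' @return list of class `marker_pca`: `scores` (animals x PCs), `loadings`
#'   (markers x PCs), `variance_explained` (percent per PC, sums to 100),
#'   `marker_pc_cor` (markers x first `n_report` PCs).
#' @export
pca_markers <- function(table, n_report = 3) {
  markers <- marker_columns(table)
  X <- as.matrix(table[markers])
  if (anyNA(X))
    stop("missing values present; impute before PCA")
  if (nrow(X) < 2)
    stop("at least 2 animals are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance marker(s): ",
         paste(markers[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  n_report <- min(n_report, ncol(pc$x))
  mp_cor <- stats::cor(X, pc$x[, seq_len(n_report), drop = FALSE])
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, marker_pc_cor = mp_cor),
            class = "marker_pca")
}

#' @export
print.marker_pca <- function(x, ...) {
  k <- min(3, length(x$variance_explained))
  cat("Marker PCA:", nrow(x$scores), "animals,", nrow(x$loadings),
      "markers\n")
  cat("  variance explained (first", k, "PCs):",
      paste(sprintf("%.1f%%", x$variance_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
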
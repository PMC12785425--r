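#' Normalize Western-blot densitometry to percent of control
#'
#' Each band intensity is divided by the lane's total-protein signal, and the
#' resulting ratios are expressed as a percentage of the mean ratio of the
#' control group, so that the control-group mean is 100 by construction.
#'
#' @param band numeric vector of band intensities (arbitrary densitometry
#'   units).
#' @param total_protein numeric vector of total-protein signals, same length,
#'   all strictly positive.
#' @param group character/factor vector of group labels, same length.
#' @param control_group label of the reference group (default `"CRS0"`).
#' @return numeric vector of percent-of-control values; `NA` inputs propagate.
#' @export
#' @examples
#' normalize_western(c(4, 2, 8), c(1, 1, 2), c("CRS0", "CRS7", "CRS0"))
normalize_western <- function(band, total_protein, group,
                              control_group = "CRS0") {
  n <- length(band)
  if (length(total_protein) != n || length(group) != n)
    stop("'band', 'total_protein' and 'group' must have equal length")
  if (any(!is.na(total_protein) & total_protein <= 0))
    stop("non-positive total_protein signal")
  ratio <- band / total_protein
  ctrl <- ratio[group == control_group & !is.na(ratio)]
  if (length(ctrl) == 0L)
    stop("control group '", control_group, "' is empty")
  100 * ratio / mean(ctrl)
}

#' Normalize qPCR threshold cycles to percent of control
#'
#' Relative expression is computed against the geometric mean of three
#' reference-gene Ct values (delta-Ct): `rel = 2^-(ct_target - geomean(refs))`,
#' then expressed as a percentage of the control-group mean relative
#' expression.
#'
#' @param ct_target numeric vector of target-gene threshold cycles.
#' @param ct_refs numeric matrix with 3 columns (one per reference gene,
#'   e.g. actin, GAPDH, cyclophilin G), one row per sample.
#' @param group group labels, one per sample.
#' @param control_group label of the reference group.
#' @return numeric vector of percent-of-control values.
#' @export
#' @examples
#' refs <- rbind(c(20, 21, 22), c(20, 21, 22))
#' normalize_qpcr(c(21, 22), refs, c("CRS0", "CRS7"))
normalize_qpcr <- function(ct_target, ct_refs, group,
                           control_group = "CRS0") {
  ct_refs <- as.matrix(ct_refs)
  n <- length(ct_target)
  if (nrow(ct_refs) != n || length(group) != n)
    stop("'ct_target', 'ct_refs' and 'group' must agree in length")
  if (ncol(ct_refs) != 3L)
    stop("exactly 3 reference Ct values are required per sample")
  complete <- !is.na(ct_target)
  if (any(complete & rowSums(is.na(ct_refs)) > 0))
    stop("missing reference Ct value")
  if (any(complete & (ct_target <= 0 | rowSums(ct_refs <= 0) > 0)))
    stop("threshold cycles must be positive")
  geo <- exp(rowMeans(log(ct_refs)))  # geometric mean of the reference Cts
  rel <- 2^-(ct_target - geo)
  ctrl <- rel[group == control_group & !is.na(rel)]
  if (length(ctrl) == 0L)
    stop("control group '", control_group, "' is empty")
  100 * rel / mean(ctrl)
}

## Grubbs critical value for the two-sided single-outlier test
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Flag a single significant outlier within a group (Grubbs test)
#'
#' Two-sided Grubbs test for one outlier: the most extreme value is flagged
#' when `G = max|x - mean| / sd` exceeds the t-based critical value at level
#' `alpha`. At most one value is flagged per call, matching a
#' single-outlier-removal policy.
#'
#' @param values numeric vector of a marker's values within one group
#'   (`NA` allowed, ignored).
#' @param ids identifiers parallel to `values` (default indices).
#' @param alpha significance level (default 0.05).
#' @return ids of flagged values (length 0 or 1).
#' @export
#' @examples
#' flag_outliers(c(100, 102, 98, 101, 99, 250))
flag_outliers <- function(values, ids = seq_along(values), alpha = 0.05) {
  if (length(ids) != length(values))
    stop("'ids' must be parallel to 'values'")
  keep <- !is.na(values)
  x <- values[keep]; id <- ids[keep]
  n <- length(x)
  if (n < 3L)
    stop("Grubbs test needs at least 3 non-missing values")
  s <- stats::sd(x)
  if (s == 0) return(id[0])           # constant column: nothing to flag
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  if (g > grubbs_critical(n, alpha)) id[which.max(dev)] else id[0]
}

#' Impute missing marker values with the group (x sex) mean
#'
#' Every missing marker value is replaced by the mean of the non-missing
#' values of the same marker within the same stratum. Stratifying by
#' group and sex (the default) prevents sex effects from leaking into
#' sex-split downstream analyses.
#'
#' @param table an expression table (see [read_expression_csv()] for the
#'   column contract).
#' @param markers marker columns to impute; defaults to every non-metadata
#'   column.
#' @param by stratification columns (default `c("group", "sex")`; use
#'   `"group"` for pooled-sex imputation).
#' @return the table with no missing marker values.
#' @export
impute_group_mean <- function(table, markers = NULL,
                              by = c("group", "sex")) {
  meta <- c("animal_id", "sex", "group")
  if (is.null(markers)) markers <- setdiff(names(table), meta)
  strata <- interaction(table[by], drop = TRUE)
  for (m in markers) {
    x <- table[[m]]
    miss <- is.na(x)
    if (!any(miss)) next
    mu <- tapply(x, strata, mean, na.rm = TRUE)
    fill <- mu[as.character(strata[miss])]
    if (any(!is.finite(fill)))
      stop("marker '", m, "' is entirely missing in stratum ",
           paste(unique(strata[miss][!is.finite(fill)]), collapse = ", "))
    x[miss] <- fill
    table[[m]] <- x
  }
  table
}
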
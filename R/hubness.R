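## Kleinberg hub score by power iteration on a symmetric non-negative
## adjacency: principal eigenvector (non-negative by Perron-Frobenius),
## rescaled so the maximum is 1. All-zero adjacency gives all zeros.
kleinberg_hubscore <- function(adjacency, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(adjacency)
  if (all(adjacency == 0)) {
    message("all-zero adjacency: hub scores are 0")
    return(stats::setNames(rep(0, n), rownames(adjacency)))
  }
  ## spectral shift: A + sI has the same eigenvectors but a strictly
  ## dominant top eigenvalue even on bipartite graphs (+/- lambda pairs),
  ## so the iteration always converges to the Perron vector
  shift <- max(rowSums(adjacency))
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- as.vector(adjacency %*% x) + shift * x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) <= tol * max(abs(y))) { x <- y; break }
    x <- y
  }
  x <- abs(x)
  stats::setNames(x / max(x), rownames(adjacency))
}

#' Node centrality metrics of a group network
#'
#' Degree counts incident edges passing the inclusion rule (`|r| >=`
#' `degree_threshold`, so degree is not trivially n-1 on a dense correlation
#' graph), strength sums all incident weights, and the hub score is
#' Kleinberg's centrality: the principal eigenvector of the full weighted
#' adjacency, max-normalized to 1.
#'
#' @param network a [build_group_network()] result.
#' @param degree_threshold edge-inclusion threshold on `|r|` for the degree
#'   metric (default 0.3).
#' @return data.frame of class `node_metrics` with columns `marker`,
#'   `degree`, `strength`, `hubscore`.
#' @export
node_metrics <- function(network, degree_threshold = 0.3) {
  adj <- network$adjacency
  structure(
    data.frame(marker = network$markers,
               degree = as.integer(rowSums(adj >= degree_threshold)),
               strength = rowSums(adj),
               hubscore = kleinberg_hubscore(adj),
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("node_metrics", "data.frame"))
}

#' Permutation test for hub-score change versus the control group
#'
#' Per marker, the observed statistic is the hub-score difference between
#' the stress group and the same-sex control cell. The null permutes animal
#' labels between the two cells (original sizes preserved), rebuilds both
#' networks and recomputes the differences. The two-sided empirical p-value
#' uses the add-one estimator
#' `(#\{|null| >= |observed|\} + 1) / (n_perm + 1)`.
#'
#' @param table expression table with no missing marker values.
#' @param group stress group to test.
#' @param sex `"M"`, `"F"`, or `NULL` to pool sexes.
#' @param reference_group control group (default `"CRS0"`).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return object of class `hub_change`: list with `group`, `sex`,
#'   `reference_group`, `metrics` (data.frame marker, hubscore,
#'   hubscore_ref, observed_diff, p), `null` (n_perm x markers matrix),
#'   `n_perm`, `seed`, `n_redrawn`.
#' @export
hub_change_test <- function(table, group, sex = NULL,
                            reference_group = "CRS0", n_perm = 10000,
                            seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical p")
  net_g <- build_group_network(table, group, sex)
  net_r <- build_group_network(table, reference_group, sex)
  hub_g <- kleinberg_hubscore(net_g$adjacency)
  hub_r <- kleinberg_hubscore(net_r$adjacency)
  observed <- hub_g - hub_r

  rows_g <- table$group == group
  rows_r <- table$group == reference_group
  if (!is.null(sex)) {
    rows_g <- rows_g & table$sex == sex
    rows_r <- rows_r & table$sex == sex
  }
  X <- rbind(as.matrix(table[rows_g, net_g$markers, drop = FALSE]),
             as.matrix(table[rows_r, net_g$markers, drop = FALSE]))
  n_g <- net_g$n_samples

  set.seed(seed)
  null <- matrix(NA_real_, n_perm, length(observed))
  colnames(null) <- net_g$markers
  redrawn <- 0L
  for (i in seq_len(n_perm)) {
    repeat {
      idx <- sample.int(nrow(X), n_g)
      A <- X[idx, , drop = FALSE]
      B <- X[-idx, , drop = FALSE]
      if (!any(apply(A, 2, stats::sd) == 0) &&
          !any(apply(B, 2, stats::sd) == 0)) break
      redrawn <- redrawn + 1L
    }
    adj_a <- abs(stats::cor(A)); diag(adj_a) <- 0
    adj_b <- abs(stats::cor(B)); diag(adj_b) <- 0
    null[i, ] <- kleinberg_hubscore(adj_a) - kleinberg_hubscore(adj_b)
  }
  if (redrawn > 0)
    message(redrawn, " degenerate permutation draw(s) redrawn")

  p <- (colSums(sweep(abs(null), 2, abs(observed), ">=")) + 1) /
    (n_perm + 1)
  metrics <- data.frame(marker = net_g$markers,
                        hubscore = unname(hub_g),
                        hubscore_ref = unname(hub_r),
                        observed_diff = unname(observed),
                        p = unname(p), row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(group = group, sex = sex,
                 reference_group = reference_group, metrics = metrics,
                 null = null, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_redrawn = redrawn),
            class = "hub_change")
}

#' @export
print.hub_change <- function(x, ...) {
  cat(sprintf("Hub-score change %s vs %s%s (n_perm = %d)\n", x$group,
              x$reference_group,
              if (is.null(x$sex)) "" else paste0(", sex ", x$sex),
              x$n_perm))
  print(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Stouffer p-value meta-analysis with directions
#'
#' Converts each two-sided p-value to a signed z
#' (`z = direction * qnorm(1 - p/2)`), averages
#' (`Z = sum(z) / sqrt(k)`) and returns the two-sided combined p
#' (`2 * (1 - pnorm(|Z|))`) with the combined direction `sign(Z)`.
#'
#' @param p_values two-sided p-values in `(0, 1]`.
#' @param directions `+1`/`-1` (or 0) per p-value.
#' @param zero_sub substitution for p = 0 (warned).
#' @return list with `p`, `z`, `direction`.
#' @export
#' @examples
#' stouffer_meta(c(0.1, 0.1), c(1, 1))
stouffer_meta <- function(p_values, directions, zero_sub = 1e-12) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (length(directions) != length(p_values))
    stop("one direction per p-value is required")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p = 0 clamped to ", zero_sub)
    p_values[p_values == 0] <- zero_sub
  }
  z <- sign(directions) * stats::qnorm(1 - p_values / 2)
  Z <- sum(z) / sqrt(length(z))
  list(p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE), z = Z,
       direction = sign(Z))
}

#' Compartment-level hub-score trajectory
#'
#' Per compartment and stress group: the mean hub score over the
#' compartment's markers, and the Stouffer combination of the compartment's
#' marker-level empirical p-values (signed by the observed hub-score
#' differences) against the control group.
#'
#' @param results named list of [hub_change_test()] results, one per stress
#'   group.
#' @param panel a [marker_panel].
#' @return data.frame with `group`, `compartment`, `mean_hubscore`,
#'   `mean_hubscore_ref`, `meta_p`, `direction`.
#' @export
compartment_trajectory <- function(results, panel = default_panel()) {
  comps <- unique(panel$compartment)
  out <- list()
  for (gname in names(results)) {
    hc <- results[[gname]]
    met <- hc$metrics
    for (cp in comps) {
      mk <- intersect(compartment_markers(panel, cp), met$marker)
      if (length(mk) == 0L) {
        message("compartment ", cp, " has no tested marker in ", gname)
        next
      }
      rows <- met[met$marker %in% mk, ]
      st <- stouffer_meta(rows$p, sign(rows$observed_diff),
                          zero_sub = 1 / (hc$n_perm + 1))
      out[[length(out) + 1L]] <- data.frame(
        group = hc$group, compartment = cp,
        mean_hubscore = mean(rows$hubscore),
        mean_hubscore_ref = mean(rows$hubscore_ref),
        meta_p = st$p, direction = st$direction,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
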
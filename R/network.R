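#' Build one group's co-expression network
#'
#' Pairwise Pearson correlation of all markers across the animals of one
#' duration x sex cell, together with the Fisher z-transform
#' (`z = atanh(r)`, clamped at `atanh(1 - 1e-12)` for perfect correlations)
#' and the weighted adjacency `|r|` with zero diagonal.
#'
#' @param table expression table with no missing marker values.
#' @param group,sex cell selectors; `sex = NULL` pools both sexes.
#' @param min_n minimum animals required in the cell (default 4).
#' @return object of class `group_network`: list with `group`, `sex`,
#'   `markers`, `r` (correlation matrix), `z` (Fisher z), `adjacency`,
#'   `n_samples`.
#' @export
build_group_network <- function(table, group, sex = NULL, min_n = 4) {
  rows <- table$group == group
  if (!is.null(sex)) rows <- rows & table$sex == sex
  markers <- marker_columns(table)
  X <- as.matrix(table[rows, markers, drop = FALSE])
  if (anyNA(X))
    stop("missing marker values in cell ", group,
         if (!is.null(sex)) paste0("/", sex), "; impute first")
  if (nrow(X) < min_n)
    stop("cell ", group, if (!is.null(sex)) paste0("/", sex),
         " has ", nrow(X), " animals (minimum ", min_n, ")")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant marker(s) in cell: ",
         paste(markers[sds == 0], collapse = ", "))
  r <- stats::cor(X)
  zcap <- 1 - 1e-12
  if (any(abs(r[upper.tri(r)]) >= zcap))
    message("perfect correlation clamped for Fisher z")
  z <- atanh(pmin(pmax(r, -zcap), zcap))
  diag(z) <- NA
  adj <- abs(r)
  diag(adj) <- 0
  structure(list(group = group, sex = sex, markers = markers, r = r,
                 z = z, adjacency = adj, n_samples = nrow(X)),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat(sprintf("Co-expression network %s%s: %d markers, %d animals\n",
              x$group, if (is.null(x$sex)) "" else paste0("/", x$sex),
              length(x$markers), x$n_samples))
  invisible(x)
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Markers are clustered by average linkage on the signed correlation
#' dissimilarity `d = 1 - r`; the dendrogram is cut at
#' `cut_fraction * max(merge height)` and branches with at least `min_size`
#' markers become modules (labels contiguous from 1, in order of first
#' marker appearance); smaller branches are left unassigned (label 0).
#'
#' @param network a [build_group_network()] result.
#' @param min_size minimum module size (default 3).
#' @param cut_fraction fraction of the maximum merge height at which the
#'   dendrogram is cut (default 0.7).
#' @return object of class `module_partition`: named integer vector
#'   (marker -> module label, 0 = unassigned).
#' @export
detect_modules <- function(network, min_size = 3, cut_fraction = 0.7) {
  r <- network$r
  markers <- network$markers
  labels <- stats::setNames(integer(length(markers)), markers)
  if (length(markers) >= min_size && length(markers) >= 2) {
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = cut_fraction * max(hc$height))
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= min_size])
    next_label <- 0L
    for (m in markers) {                       # relabel in marker order
      cm <- cl[m]
      if (cm %in% keep && labels[m] == 0L) {
        next_label <- next_label + 1L
        labels[names(cl)[cl == cm]] <- next_label
      }
    }
  }
  structure(labels, min_size = min_size, cut_fraction = cut_fraction,
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  k <- max(x)
  cat("Module partition:", k, "module(s),", sum(x == 0), "unassigned\n")
  for (m in seq_len(k))
    cat(sprintf("  module %d: %s\n", m,
                paste(names(x)[x == m], collapse = ", ")))
  if (any(x == 0))
    cat("  unassigned:", paste(names(x)[x == 0], collapse = ", "), "\n")
  invisible(x)
}

#' Module preservation between two partitions
#'
#' For each module M of `p_a`, the preservation is the best proportion of
#' its markers recovered in a single module of `p_b`:
#' `max_N |M intersect N| / |M|` over modules N of `p_b` (unassigned markers
#' never count as shared). Ties are broken toward the larger N, then the
#' lower label.
#'
#' @param p_a,p_b [detect_modules()] partitions over the same markers.
#' @return named numeric vector, one preservation proportion in `[0, 1]`
#'   per module of `p_a` (empty if `p_a` has none).
#' @export
module_preservation <- function(p_a, p_b) {
  if (!identical(sort(names(p_a)), sort(names(p_b))))
    stop("partitions must share the same marker universe")
  ka <- max(p_a)
  if (ka == 0L) {
    message("first partition has no modules")
    return(stats::setNames(numeric(0), character(0)))
  }
  kb <- max(p_b)
  out <- stats::setNames(numeric(ka), paste0("module", seq_len(ka)))
  for (m in seq_len(ka)) {
    M <- names(p_a)[p_a == m]
    if (kb == 0L) { out[m] <- 0; next }
    shared <- vapply(seq_len(kb), function(nb)
      sum(M %in% names(p_b)[p_b == nb]), numeric(1))
    sizes <- vapply(seq_len(kb), function(nb) sum(p_b == nb), numeric(1))
    best <- order(-shared, -sizes, seq_len(kb))[1]
    out[m] <- shared[best] / length(M)
  }
  out
}

#' Fisher p-value meta-analysis
#'
#' Combines k p-values via `X2 = -2 * sum(log(p))`, referred to the upper
#' tail of a chi-square distribution with 2k degrees of freedom.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param zero_sub substitution for p = 0 (e.g. the permutation floor
#'   `1/(n_perm + 1)`); zeros trigger a warning.
#' @return the combined p-value.
#' @export
#' @examples
#' fisher_meta(c(0.05, 0.05))
fisher_meta <- function(p_values, zero_sub = 1e-12) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p = 0 clamped to ", zero_sub)
    p_values[p_values == 0] <- zero_sub
  }
  x2 <- -2 * sum(log(p_values))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

## order module labels of a partition by (size desc, label asc); used for
## rank-matching observed modules to permuted-partition modules
module_rank_order <- function(p) {
  k <- max(p)
  if (k == 0L) return(integer(0))
  sizes <- vapply(seq_len(k), function(m) sum(p == m), numeric(1))
  order(-sizes, seq_len(k))
}

## split pooled rows into two pseudo-cells and build both partitions;
## returns NULL if a pseudo-cell has a constant marker (degenerate draw)
permuted_partitions <- function(X, n_a, min_size, cut_fraction) {
  idx <- sample.int(nrow(X), n_a)
  A <- X[idx, , drop = FALSE]
  B <- X[-idx, , drop = FALSE]
  if (any(apply(A, 2, stats::sd) == 0) || any(apply(B, 2, stats::sd) == 0))
    return(NULL)
  part <- function(M) {
    r <- stats::cor(M)
    net <- list(r = r, markers = colnames(M))
    class(net) <- "group_network"
    detect_modules(net, min_size = min_size, cut_fraction = cut_fraction)
  }
  list(a = part(A), b = part(B))
}

#' Monte-Carlo module-preservation test between two groups
#'
#' Tests whether the co-expression modules of `group_a` are less preserved
#' in `group_b` than expected if the two cells were exchangeable (the null
#' hypothesis that the modules are identical). Animals of the two cells are
#' pooled and randomly re-split into pseudo-cells of the original sizes;
#' both networks and partitions are rebuilt per draw and per-module
#' preservation recomputed. Pseudo-partition modules are matched to the
#' observed modules by rank (size descending, then label); a draw whose
#' pseudo-partition has no module at a given rank contributes preservation
#' 1 for that rank. The empirical p-value per module is the one-sided
#' add-one estimate toward low preservation,
#' `(#\{null <= observed\} + 1) / (n_perm + 1)`, and the pair-level p is the
#' Fisher combination of the module p-values.
#'
#' @param table expression table with no missing marker values.
#' @param group_a,group_b group labels to compare.
#' @param sex `"M"`, `"F"`, or `NULL` to pool sexes.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed RNG seed; the test is deterministic given the seed.
#' @param min_size,cut_fraction module-detection parameters.
#' @return object of class `preservation_test`: list with `group_a`,
#'   `group_b`, `sex`, `observed` (per-module preservation), `null` (matrix
#'   n_perm x modules), `p_module`, `fisher_p`, `n_perm`, `seed`,
#'   `n_redrawn` (degenerate draws redrawn).
#' @export
preservation_permutation_test <- function(table, group_a, group_b,
                                          sex = NULL, n_perm = 10000,
                                          seed = 1, min_size = 3,
                                          cut_fraction = 0.7) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical p")
  net_a <- build_group_network(table, group_a, sex)
  net_b <- build_group_network(table, group_b, sex)
  part_a <- detect_modules(net_a, min_size, cut_fraction)
  part_b <- detect_modules(net_b, min_size, cut_fraction)
  observed <- module_preservation(part_a, part_b)
  obs_order <- module_rank_order(part_a)
  k <- length(obs_order)

  res <- list(group_a = group_a, group_b = group_b, sex = sex,
              partition_a = part_a, partition_b = part_b,
              observed = observed, n_perm = as.integer(n_perm),
              seed = as.integer(seed))
  if (k == 0L) {
    message("no modules in ", group_a, "; preservation test is empty")
    res$null <- matrix(numeric(0), n_perm, 0)
    res$p_module <- numeric(0)
    res$fisher_p <- NA_real_
    res$n_redrawn <- 0L
    class(res) <- "preservation_test"
    return(res)
  }

  rows_a <- table$group == group_a
  rows_b <- table$group == group_b
  if (!is.null(sex)) {
    rows_a <- rows_a & table$sex == sex
    rows_b <- rows_b & table$sex == sex
  }
  X <- rbind(as.matrix(table[rows_a, net_a$markers, drop = FALSE]),
             as.matrix(table[rows_b, net_a$markers, drop = FALSE]))
  n_a <- net_a$n_samples

  set.seed(seed)
  null <- matrix(NA_real_, n_perm, k)
  redrawn <- 0L
  for (i in seq_len(n_perm)) {
    repeat {
      pp <- permuted_partitions(X, n_a, min_size, cut_fraction)
      if (!is.null(pp)) break
      redrawn <- redrawn + 1L
    }
    pres <- module_preservation(pp$a, pp$b)
    ranked <- pres[module_rank_order(pp$a)]
    null[i, ] <- c(ranked, rep(1, k))[seq_len(k)]
  }
  if (redrawn > 0)
    message(redrawn, " degenerate permutation draw(s) redrawn")

  obs_ranked <- observed[obs_order]
  p_mod <- (colSums(sweep(null, 2, obs_ranked, "<=")) + 1) / (n_perm + 1)
  names(p_mod) <- names(observed)[obs_order]
  res$null <- null
  res$p_module <- p_mod
  res$fisher_p <- fisher_meta(p_mod, zero_sub = 1 / (n_perm + 1))
  res$n_redrawn <- redrawn
  class(res) <- "preservation_test"
  res
}

#' @export
print.preservation_test <- function(x, ...) {
  cat(sprintf("Module preservation %s vs %s%s (n_perm = %d)\n",
              x$group_a, x$group_b,
              if (is.null(x$sex)) "" else paste0(", sex ", x$sex),
              x$n_perm))
  if (length(x$p_module)) {
    for (m in names(x$p_module))
      cat(sprintf("  %s: preservation %.3f, p = %.4g\n", m,
                  x$observed[m], x$p_module[m]))
    cat(sprintf("  pair-level Fisher p = %.4g\n", x$fisher_p))
  } else cat("  no modules in the first group\n")
  invisible(x)
}

#' All pairwise group comparisons for one sex
#'
#' Runs [preservation_permutation_test()] for every unordered pair of stress
#' durations within one sex (15 pairs for the full design) and applies BH
#' correction across the pair-level Fisher p-values.
#'
#' @inheritParams preservation_permutation_test
#' @param groups group labels to compare (default all six durations).
#' @return list of class `preservation_set`: `tests` (named list of
#'   `preservation_test`) and `summary` data.frame with `group_a`,
#'   `group_b`, `fisher_p`, `q`.
#' @export
compare_all_groups <- function(table, sex = NULL, n_perm = 10000, seed = 1,
                               groups = crs_groups(), min_size = 3,
                               cut_fraction = 0.7) {
  pairs <- utils::combn(groups, 2)
  tests <- list()
  summ <- data.frame(group_a = character(), group_b = character(),
                     fisher_p = numeric(), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    t_j <- tryCatch(
      preservation_permutation_test(table, ga, gb, sex = sex,
                                    n_perm = n_perm, seed = seed + j,
                                    min_size = min_size,
                                    cut_fraction = cut_fraction),
      error = function(e) {
        message("pair ", ga, " vs ", gb, " skipped: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(t_j)) next
    tests[[paste(ga, gb, sep = "_vs_")]] <- t_j
    summ <- rbind(summ, data.frame(group_a = ga, group_b = gb,
                                   fisher_p = t_j$fisher_p,
                                   stringsAsFactors = FALSE))
  }
  summ$q <- NA_real_
  ok <- !is.na(summ$fisher_p)
  if (any(ok)) summ$q[ok] <- bh_fdr(summ$fisher_p[ok])
  structure(list(tests = tests, summary = summ, sex = sex,
                 n_perm = n_perm, seed = seed),
            class = "preservation_set")
}

#' @export
print.preservation_set <- function(x, ...) {
  cat(sprintf("Pairwise module preservation%s: %d pair(s), n_perm = %d\n",
              if (is.null(x$sex)) "" else paste0(" (sex ", x$sex, ")"),
              nrow(x$summary), x$n_perm))
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Export a network for visualization
#'
#' Writes the network in SIF (plain-text, intra-module edges only,
#' unassigned markers as isolated nodes) or GraphML (via igraph, with
#' `compartment` and `module` node attributes and `weight = |r|` edge
#' attributes).
#'
#' @param network a `group_network`.
#' @param partition a `module_partition` over the same markers.
#' @param path output file.
#' @param format `"SIF"` or `"GraphML"`.
#' @param panel a [marker_panel] for compartment annotation.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, partition, path,
                           format = c("SIF", "GraphML"),
                           panel = default_panel()) {
  format <- match.arg(format)
  markers <- network$markers
  intra <- outer(partition[markers], partition[markers], "==") &
    outer(partition[markers], partition[markers],
          function(a, b) a > 0 & b > 0)
  intra[lower.tri(intra, diag = TRUE)] <- FALSE
  edges <- which(intra, arr.ind = TRUE)

  if (format == "SIF") {
    lines <- character(0)
    if (nrow(edges))
      lines <- sprintf("%s\tcoexpr\t%s", markers[edges[, 1]],
                       markers[edges[, 2]])
    isolated <- markers[!markers %in%
                          c(markers[edges[, 1]], markers[edges[, 2]])]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(lines, isolated), con)
    return(invisible(path))
  }

  g <- igraph::make_empty_graph(n = length(markers), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = markers)
  comp <- stats::setNames(panel$compartment, panel$marker)
  g <- igraph::set_vertex_attr(g, "compartment",
                               value = unname(comp[markers]))
  g <- igraph::set_vertex_attr(g, "module",
                               value = as.integer(partition[markers]))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
    g <- igraph::set_edge_attr(
      g, "weight", value = network$adjacency[edges])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
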
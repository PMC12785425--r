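# shared fixtures and independent oracles used across test files

# tiny expression table: 2 groups x 2 sexes x n animals, 4 markers with a
# planted 2 + 2 block structure (no stress effects)
tiny_expression <- function(n = 6, seed = 1, rho = 0.8) {
  set.seed(seed)
  markers <- c("M1", "M2", "M3", "M4")
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- rho
  R[3, 4] <- R[4, 3] <- rho
  cells <- expand.grid(sex = c("M", "F"), group = c("CRS0", "CRS35"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    vals <- MASS::mvrnorm(n, mu = rep(100, 4), Sigma = 100 * R)
    colnames(vals) <- markers
    data.frame(animal_id = sprintf("%s%s%02d", cells$group[i],
                                   cells$sex[i], seq_len(n)),
               sex = cells$sex[i], group = cells$group[i], vals,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# brute-force BH step-up: independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# exhaustive best-overlap preservation: direct double loop over modules
preservation_oracle <- function(p_a, p_b) {
  ka <- max(p_a)
  out <- numeric(ka)
  for (m in seq_len(ka)) {
    M <- names(p_a)[p_a == m]
    best <- 0
    for (nb in seq_len(max(p_b, 1))) {
      if (max(p_b) == 0) break
      best <- max(best, sum(M %in% names(p_b)[p_b == nb]))
    }
    out[m] <- best / length(M)
  }
  out
}

# principal-eigenvector hub score via dense eigendecomposition
hubscore_oracle <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

# random symmetric non-negative adjacency with zero diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
  a
}

# random module partition over given markers (labels 0 = unassigned)
random_partition <- function(markers, max_modules = 3) {
  p <- sample(0:max_modules, length(markers), replace = TRUE)
  names(p) <- markers
  # relabel so modules are contiguous from 1
  labs <- sort(unique(p[p > 0]))
  q <- integer(length(p))
  names(q) <- markers
  for (i in seq_along(labs)) q[p == labs[i]] <- i
  q
}
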
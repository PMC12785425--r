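#' Configuration for the synthetic CRS cohort generator
#'
#' Encodes the study design (6 restraint-stress durations x 2 sexes x
#' `n_per_cell` animals) and the statistical structure of the simulated
#' data: graded stress effects on marker means (percent-of-control units),
#' additive sex offsets, compartment-structured residual correlation
#' (within-compartment `block_rho`, between-compartment `cross_rho`),
#' programmed behavioral shifts, and per-cell modulation of the correlation
#' structure (`network_effects`, multiplier on `block_rho`) used to emulate
#' network fragmentation under prolonged stress.
#'
#' Default effect profiles are fixtures shaped like the study's qualitative
#' findings, not estimates: marker declines are graded with duration (the
#' presynaptic marker VGLUT1 early, SYN1/PSD95 late), the shelter-time
#' increase is present from the first stressed week, the sucrose deficit is
#' programmed only for the 35-day group, and female within-compartment
#' correlation degrades at 28-35 days.
#'
#' @param n_per_cell animals per group x sex cell (default 8; the study
#'   design gives 6 x 2 x 8 = 96 animals).
#' @param seed integer RNG seed; identical configurations generate identical
#'   cohorts.
#' @param panel a [marker_panel].
#' @param marker_effects numeric matrix (marker x group) of mean shifts in
#'   percent-of-control units.
#' @param sex_offsets named numeric vector per marker, added for males.
#' @param block_rho,cross_rho residual correlation within / between
#'   compartments.
#' @param noise_sd residual SD in percent units.
#' @param behavior_effects data.frame with one row per group and columns
#'   `shelter_min` (minutes added per post-challenge bin), `sucrose_shift`,
#'   `coat_shift`, `weight_shift` (end-of-study magnitudes; effects ramp
#'   with cumulative stress exposure).
#' @param network_effects numeric matrix (group x sex) multiplying
#'   `block_rho` in that cell.
#' @param missing_rate per-cell marker missingness probability.
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_per_cell = 8, seed = 1, panel = default_panel(),
                       marker_effects = default_marker_effects(panel),
                       sex_offsets = default_sex_offsets(panel),
                       block_rho = 0.5, cross_rho = 0.1, noise_sd = 15,
                       behavior_effects = default_behavior_effects(),
                       network_effects = default_network_effects(),
                       missing_rate = 0.02) {
  if (n_per_cell < 0) stop("n_per_cell must be >= 0")
  cfg <- list(n_per_cell = as.integer(n_per_cell), seed = as.integer(seed),
              groups = crs_groups(), sexes = crs_sexes(), panel = panel,
              marker_effects = marker_effects, sex_offsets = sex_offsets,
              block_rho = block_rho, cross_rho = cross_rho,
              noise_sd = noise_sd, behavior_effects = behavior_effects,
              network_effects = network_effects,
              missing_rate = missing_rate)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic CRS cohort configuration\n")
  cat(sprintf("  %d groups x %d sexes x %d animals = %d animals, seed %d\n",
              length(x$groups), length(x$sexes), x$n_per_cell,
              length(x$groups) * length(x$sexes) * x$n_per_cell, x$seed))
  cat(sprintf("  block_rho %.2f, cross_rho %.2f, noise_sd %.1f, missing %.1f%%\n",
              x$block_rho, x$cross_rho, x$noise_sd, 100 * x$missing_rate))
  invisible(x)
}

#' @rdname sim_config
#' @export
default_marker_effects <- function(panel = default_panel()) {
  g <- crs_groups()
  eff <- rbind(
    GAD67  = c(0,   0,  -5, -10, -15, -20),
    SST    = c(0,   0,  -5, -10, -15, -20),
    PV     = c(0,   0,   0,  -5, -10, -15),
    VIP    = c(0,   0,   0,   0,  -5, -10),
    VGLUT1 = c(0, -10, -15, -20, -25, -30),
    PSD95  = c(0,   0,   0,  -5, -10, -15),
    SYN1   = c(0,   0,   0,  -5, -10, -20),
    GPHN   = c(0,   0,  -5,  -5, -10, -10),
    GLT1   = c(0,  -5, -10, -15, -20, -25),
    GFAP   = c(0,  -5, -10, -10, -15, -20),
    GS     = c(0,   0,  -5, -10, -10, -15))
  colnames(eff) <- g
  eff[panel$marker, , drop = FALSE]
}

#' @rdname sim_config
#' @export
default_sex_offsets <- function(panel = default_panel()) {
  off <- stats::setNames(rep(0, nrow(panel)), panel$marker)
  off["GAD67"] <- 5    # modest male offsets; fixtures, not estimates
  off["SST"] <- -5
  off
}

#' @rdname sim_config
#' @export
default_behavior_effects <- function() {
  data.frame(
    group = crs_groups(),
    shelter_min   = c(0,  6,  9, 12, 15, 18),
    sucrose_shift = c(0,  0,  0,  0,  0, -10),
    coat_shift    = c(0,  1, 1.5,  2, 2.5,  3),
    weight_shift  = c(0, -2, -3, -4, -5, -6))
}

#' @rdname sim_config
#' @export
default_network_effects <- function() {
  ne <- matrix(1, 6, 2, dimnames = list(crs_groups(), crs_sexes()))
  ne["CRS28", "F"] <- 0.6
  ne["CRS35", "F"] <- 0.3
  ne
}

#' Read / write a simulation configuration as YAML
#'
#' Serializes every [sim_config()] field (effect matrices as per-marker /
#' per-group maps) so that a cohort configuration can be versioned next to
#' its outputs. The panel travels inside the file.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config_yaml` returns a [sim_config()];
#'   `write_sim_config_yaml` returns `path` invisibly.
#' @export
write_sim_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  me <- apply(config$marker_effects, 1, as.list, simplify = FALSE)
  ne <- apply(config$network_effects, 1, as.list, simplify = FALSE)
  yaml::write_yaml(list(
    n_per_cell = config$n_per_cell, seed = config$seed,
    panel = list(marker = config$panel$marker,
                 compartment = config$panel$compartment,
                 assay = config$panel$assay),
    marker_effects = me,
    sex_offsets = as.list(config$sex_offsets),
    block_rho = config$block_rho, cross_rho = config$cross_rho,
    noise_sd = config$noise_sd,
    behavior_effects = as.list(config$behavior_effects),
    network_effects = ne,
    missing_rate = config$missing_rate), path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- marker_panel(y$panel$marker, y$panel$compartment, y$panel$assay)
  me <- t(vapply(y$marker_effects[panel$marker],
                 function(r) unlist(r)[crs_groups()],
                 numeric(length(crs_groups()))))
  ne <- t(vapply(y$network_effects[crs_groups()],
                 function(r) unlist(r)[crs_sexes()],
                 numeric(2)))
  dimnames(ne) <- list(crs_groups(), crs_sexes())
  sim_config(n_per_cell = y$n_per_cell, seed = y$seed, panel = panel,
             marker_effects = me,
             sex_offsets = unlist(y$sex_offsets)[panel$marker],
             block_rho = y$block_rho, cross_rho = y$cross_rho,
             noise_sd = y$noise_sd,
             behavior_effects = as.data.frame(y$behavior_effects,
                                              stringsAsFactors = FALSE),
             network_effects = ne,
             missing_rate = y$missing_rate)
}

## compartment-block correlation matrix for one cell; errors if not PD
block_correlation <- function(panel, block_rho, cross_rho) {
  comp <- panel$compartment
  same <- outer(comp, comp, "==")
  R <- ifelse(same, block_rho, cross_rho)
  diag(R) <- 1
  dimnames(R) <- list(panel$marker, panel$marker)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop(sprintf(paste0("correlation parameters block_rho = %.3f, ",
                        "cross_rho = %.3f do not yield a positive-definite ",
                        "covariance (min eigenvalue %.2e)"),
                 block_rho, cross_rho, ev))
  R
}

## fraction of a group's total stress completed by week w (0..5)
stress_ramp <- function(group, week) {
  days <- c(CRS0 = 0, CRS7 = 7, CRS14 = 14, CRS21 = 21, CRS28 = 28,
            CRS35 = 35)[group]
  ifelse(days == 0, 0, pmin(week * 7, days) / days)
}

#' Simulate a synthetic CRS cohort
#'
#' Generates an expression table, a weekly behavior table and PhenoTyper
#' zone-time traces with the configured design: marker values are
#' `100 + effect(marker, group) + sex offset + multivariate Gaussian noise`
#' with compartment-block covariance, truncated at 0; behavioral measures
#' carry the programmed group shifts, ramping with cumulative stress
#' exposure; missingness is applied to marker cells at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return an object of class `crs_cohort`: a list with elements
#'   `expression` (animals x markers), `behavior` (animal-weeks), `traces`
#'   (long zone-time records) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_cell = 2, seed = 42))
#' nrow(cohort$expression)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  markers <- panel$marker
  cells <- expand.grid(sex = config$sexes, group = config$groups,
                       stringsAsFactors = FALSE)

  expr_rows <- list(); beh_rows <- list(); trace_rows <- list()
  aid <- 0L
  for (ci in seq_len(nrow(cells))) {
    g <- cells$group[ci]; sx <- cells$sex[ci]
    n <- config$n_per_cell
    if (n == 0L) next
    rho <- config$block_rho * config$network_effects[g, sx]
    R <- block_correlation(panel, rho, config$cross_rho)
    Sigma <- config$noise_sd^2 * R
    mu <- 100 + config$marker_effects[markers, g] +
      if (sx == "M") config$sex_offsets[markers] else 0
    vals <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    vals <- pmax(matrix(vals, nrow = n), 0)
    colnames(vals) <- markers
    if (config$missing_rate > 0)
      vals[matrix(stats::runif(length(vals)) < config$missing_rate,
                  nrow = n)] <- NA
    ids <- sprintf("%s_%s_%02d", g, sx, seq_len(n) + 0L)
    aid <- aid + n
    expr_rows[[ci]] <- data.frame(animal_id = ids, sex = sx, group = g,
                                  vals, stringsAsFactors = FALSE,
                                  check.names = FALSE)

    be <- config$behavior_effects[config$behavior_effects$group == g, ]
    for (w in 0:5) {
      ramp <- stress_ramp(g, w)
      coat_raw <- pmin(pmax(stats::rnorm(n, 0.5 + be$coat_shift * ramp, 0.5),
                            0), 7)
      coat <- round(coat_raw * 2) / 2
      wg <- stats::rnorm(n, 2 * w + be$weight_shift * ramp, 2)
      suc <- pmin(pmax(stats::rnorm(n, 70 + be$sucrose_shift * ramp, 8),
                       0), 100)
      beh_rows[[length(beh_rows) + 1L]] <-
        data.frame(animal_id = ids, sex = sx, group = g, week = w,
                   coat_state = coat, weight_gain_pct = wg,
                   sucrose_pref_pct = suc, stringsAsFactors = FALSE)
      trace_rows[[length(trace_rows) + 1L]] <-
        simulate_traces(ids, w, be$shelter_min * ramp)
    }
  }

  expression <- if (length(expr_rows)) do.call(rbind, expr_rows) else
    empty_expression(markers)
  behavior <- if (length(beh_rows)) do.call(rbind, beh_rows) else
    data.frame(animal_id = character(), sex = character(),
               group = character(), week = integer(),
               coat_state = numeric(), weight_gain_pct = numeric(),
               sucrose_pref_pct = numeric())
  traces <- if (length(trace_rows)) do.call(rbind, trace_rows) else
    data.frame(animal_id = character(), week = integer(),
               bin_start_hour = integer(), zone = character(),
               minutes = numeric())
  rownames(expression) <- rownames(behavior) <- rownames(traces) <- NULL

  if (nrow(behavior)) {
    meta <- expression[c("animal_id", "sex", "group")]
    for (zone in c("SZ", "FZ")) {
      ra <- residual_avoidance(traces, meta, zone = zone)
      names(ra)[names(ra) == "ra"] <- if (zone == "SZ") "ra_sz" else "ra_fz"
      behavior <- merge(behavior, ra, by = c("animal_id", "week"),
                        sort = FALSE)
    }
    behavior <- behavior[order(behavior$week, behavior$animal_id), ]
    rownames(behavior) <- NULL
    behavior$z_emotionality <- z_emotionality(behavior)
  } else {
    behavior$ra_sz <- behavior$ra_fz <- behavior$z_emotionality <- numeric(0)
  }

  structure(list(expression = expression, behavior = behavior,
                 traces = traces, config = config),
            class = "crs_cohort")
}

## overnight session 7 p.m. - 8 a.m.; light challenge 11 p.m. for 1 h;
## stress adds shelter minutes only in the 5 h post-challenge window
simulate_traces <- function(ids, week, shelter_add) {
  hours <- c(19:23, 0:7)
  post <- post_window_hours()
  n <- length(ids); nb <- length(hours)
  sz <- matrix(30 * stats::rbeta(n * nb, 2, 2), n, nb)
  fz <- matrix(20 * stats::rbeta(n * nb, 2, 2), n, nb)
  add <- matrix(0, n, nb)
  add[, hours %in% post] <- shelter_add
  sz <- pmin(sz + add, 60)
  fz <- pmin(fz, 60 - sz)
  data.frame(
    animal_id = rep(ids, times = 2 * nb),
    week = week,
    bin_start_hour = rep(rep(hours, each = n), 2),
    zone = rep(c("SZ", "FZ"), each = n * nb),
    minutes = c(as.vector(sz), as.vector(fz)),
    stringsAsFactors = FALSE)
}

empty_expression <- function(markers) {
  tab <- data.frame(animal_id = character(), sex = character(),
                    group = character(), stringsAsFactors = FALSE)
  for (m in markers) tab[[m]] <- numeric(0)
  tab
}

#' @export
print.crs_cohort <- function(x, ...) {
  cat("Synthetic CRS cohort:",
      nrow(x$expression), "animals,",
      length(marker_columns(x$expression)), "markers,",
      nrow(x$behavior), "behavior rows,",
      nrow(x$traces), "trace records\n")
  invisible(x)
}

#' Simulate a null cohort (no group or sex effects)
#'
#' As [simulate_cohort()] with every marker effect, behavioral shift, sex
#' offset and network modulation forced to zero/identity; used to calibrate
#' the type-I error of the permutation tests.
#'
#' @param config a [sim_config()]; effect fields are overridden.
#' @return a `crs_cohort`.
#' @export
simulate_null <- function(config = sim_config()) {
  config$marker_effects[] <- 0
  config$sex_offsets[] <- 0
  config$behavior_effects$shelter_min <- 0
  config$behavior_effects$sucrose_shift <- 0
  config$behavior_effects$coat_shift <- 0
  config$behavior_effects$weight_shift <- 0
  config$network_effects[] <- 1
  simulate_cohort(config)
}

#' Expression table with planted correlation modules
#'
#' Draws one group's worth of animals from a multivariate normal whose
#' population correlation is block-structured by the given partition:
#' `within_r` inside a block, `between_r` across blocks. Used as a
#' module-recovery fixture with known ground truth.
#'
#' @param partition named vector mapping marker to block label.
#' @param within_r,between_r population correlations (`within_r > between_r`).
#' @param n number of animals.
#' @param seed RNG seed.
#' @return an expression table (group `"CRS0"`, sex `"M"`).
#' @export
#' @examples
#' part <- setNames(rep(1:3, c(4, 4, 3)), default_panel()$marker)
#' tab <- planted_module_dataset(part, 0.8, 0, n = 50, seed = 1)
planted_module_dataset <- function(partition, within_r, between_r, n,
                                   seed = 1) {
  if (within_r <= between_r)
    stop("within_r must exceed between_r")
  markers <- names(partition)
  same <- outer(partition, partition, "==")
  R <- ifelse(same, within_r, between_r)
  diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop(sprintf("within_r = %.3f, between_r = %.3f give a non-positive-definite correlation (min eigenvalue %.2e)",
                 within_r, between_r, ev))
  set.seed(seed)
  vals <- pmax(MASS::mvrnorm(n, mu = rep(100, length(markers)),
                             Sigma = 100 * R), 0)
  colnames(vals) <- markers
  data.frame(animal_id = sprintf("P%03d", seq_len(n)), sex = "M",
             group = "CRS0", vals, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a cohort's three tables as CSV files
#'
#' @param cohort a `crs_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.csv"),
             behavior = file.path(dir, "behavior.csv"),
             traces = file.path(dir, "traces.csv"))
  write_expression_csv(cohort$expression, paths["expression"])
  utils::write.csv(cohort$behavior, paths["behavior"], row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$traces, paths["traces"], row.names = FALSE,
                   na = "")
  invisible(paths)
}
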
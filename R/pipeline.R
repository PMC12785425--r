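#' Pipeline configuration
#'
#' Bundles the inputs (either an ingested CSV trio or a [sim_config()] for
#' a synthetic cohort), the output directory, the global seed (propagated
#' to every stochastic stage as derived sub-seeds), permutation counts and
#' stage toggles.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()], or `NULL` when reading CSVs.
#' @param expression_csv,behavior_csv,traces_csv input paths (all three
#'   required when `sim` is `NULL`).
#' @param n_perm permutations for the network and hubness tests.
#' @param seed global seed.
#' @param sexes sexes to analyze separately.
#' @param stages character subset of
#'   `c("data", "normalize", "behavior", "association", "network",
#'   "hubness")`.
#' @param panel a [marker_panel].
#' @param min_size,cut_fraction,degree_threshold network parameters.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            expression_csv = NULL, behavior_csv = NULL,
                            traces_csv = NULL, n_perm = 500, seed = 1,
                            sexes = crs_sexes(),
                            stages = c("data", "normalize", "behavior",
                                       "association", "network",
                                       "hubness"),
                            panel = default_panel(), min_size = 3,
                            cut_fraction = 0.7, degree_threshold = 0.3) {
  if (is.null(sim) &&
      (is.null(expression_csv) || is.null(behavior_csv) ||
       is.null(traces_csv)))
    stop("either a simulation config or all three input CSVs are required")
  structure(list(out_dir = out_dir, sim = sim,
                 expression_csv = expression_csv,
                 behavior_csv = behavior_csv, traces_csv = traces_csv,
                 n_perm = n_perm, seed = as.integer(seed), sexes = sexes,
                 stages = stages, panel = panel, min_size = min_size,
                 cut_fraction = cut_fraction,
                 degree_threshold = degree_threshold),
            class = "pipeline_config")
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Stages: acquire data (simulate or ingest) -> outlier screen and
#' group-mean imputation -> behavioral scoring (RA recomputed from traces
#' when absent, Z-emotionality) -> correlation and PCA analyses ->
#' per-sex pairwise network preservation tests -> hubness analysis. All
#' result tables are written as CSV under `config$out_dir`, networks as
#' SIF/GraphML, plus a timestamped log and a YAML run manifest. A stage
#' failure skips the downstream stages but keeps completed outputs, and is
#' recorded in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the output directory, the per-stage status
#'   and the in-memory result objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out, "pipeline.log"), "w")
  on.exit(close(log_con))
  status <- list()
  results <- list()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed || !(name %in% config$stages)) {
      status[[name]] <<- if (failed) "skipped" else "disabled"
      return(invisible(NULL))
    }
    pipeline_log(log_con, "stage ", name, " started")
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      pipeline_log(log_con, "stage ", name, " FAILED: ",
                   conditionMessage(res))
      status[[name]] <<- paste("failed:", conditionMessage(res))
      failed <<- TRUE
      return(invisible(NULL))
    }
    pipeline_log(log_con, "stage ", name, " done")
    status[[name]] <<- "ok"
    res
  }

  ## --- data ---------------------------------------------------------
  dat <- run_stage("data", function() {
    if (!is.null(config$sim)) {
      cohort <- simulate_cohort(config$sim)
    } else {
      cohort <- list(
        expression = read_expression_csv(config$expression_csv,
                                         config$panel),
        behavior = utils::read.csv(config$behavior_csv,
                                   stringsAsFactors = FALSE,
                                   colClasses = c(animal_id = "character"),
                                   na.strings = ""),
        traces = utils::read.csv(config$traces_csv,
                                 stringsAsFactors = FALSE,
                                 colClasses = c(animal_id = "character"),
                                 na.strings = ""))
    }
    write_expression_csv(cohort$expression,
                         file.path(out, "expression_raw.csv"))
    cohort
  })
  if (!is.null(dat)) results$cohort <- dat

  ## --- normalize: outlier screen + imputation -----------------------
  expr <- run_stage("normalize", function() {
    tab <- dat$expression
    markers <- marker_columns(tab)
    for (m in markers) for (g in unique(tab$group)) {
      rows <- which(tab$group == g & !is.na(tab[[m]]))
      if (length(rows) < 3) next
      flagged <- flag_outliers(tab[[m]][rows], ids = rows)
      if (length(flagged)) tab[[m]][flagged] <- NA
    }
    tab <- impute_group_mean(tab)
    write_expression_csv(tab, file.path(out, "expression_clean.csv"))
    tab
  })
  if (!is.null(expr)) results$expression <- expr

  ## --- behavior scores ----------------------------------------------
  beh <- run_stage("behavior", function() {
    b <- dat$behavior
    meta <- dat$expression[c("animal_id", "sex", "group")]
    if (!all(c("ra_sz", "ra_fz") %in% names(b)) &&
        nrow(dat$traces) > 0) {
      for (zone in c("SZ", "FZ")) {
        ra <- residual_avoidance(dat$traces, meta, zone = zone)
        names(ra)[names(ra) == "ra"] <-
          if (zone == "SZ") "ra_sz" else "ra_fz"
        b <- merge(b, ra, by = c("animal_id", "week"), sort = FALSE)
      }
    }
    if (!"z_emotionality" %in% names(b))
      b$z_emotionality <- z_emotionality(b)
    utils::write.csv(b, file.path(out, "behavior_scores.csv"),
                     row.names = FALSE, na = "")
    b
  })
  if (!is.null(beh)) results$behavior <- beh

  ## --- association --------------------------------------------------
  assoc <- run_stage("association", function() {
    markers <- marker_columns(expr)
    final_week <- max(beh$week)
    bw <- beh[beh$week == final_week,
              c("animal_id", "coat_state", "weight_gain_pct",
                "sucrose_pref_pct", "ra_sz", "ra_fz", "z_emotionality")]
    joined <- merge(expr, bw, by = "animal_id", sort = FALSE)
    mm <- correlate_pairs(joined, variables = markers)
    behaviors <- setdiff(names(bw), "animal_id")
    mb_pairs <- expand.grid(a = markers, b = behaviors,
                            stringsAsFactors = FALSE)
    mb <- correlate_pairs(joined, pairs = mb_pairs)
    utils::write.csv(mm, file.path(out, "correlations_markers.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(mb, file.path(out, "correlations_behavior.csv"),
                     row.names = FALSE, na = "")
    pca <- pca_markers(expr)
    utils::write.csv(
      data.frame(animal_id = expr$animal_id, pca$scores),
      file.path(out, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(marker = rownames(pca$loadings), pca$loadings),
      file.path(out, "pca_loadings.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(component = seq_along(pca$variance_explained),
                 variance_pct = pca$variance_explained),
      file.path(out, "pca_variance.csv"), row.names = FALSE)
    list(marker_marker = mm, marker_behavior = mb, pca = pca)
  })
  if (!is.null(assoc)) results$association <- assoc

  ## --- networks ------------------------------------------------------
  nets <- run_stage("network", function() {
    per_sex <- list()
    for (sx in config$sexes) {
      cmp <- compare_all_groups(expr, sex = sx, n_perm = config$n_perm,
                                seed = config$seed + match(sx, config$sexes) * 1000L,
                                min_size = config$min_size,
                                cut_fraction = config$cut_fraction)
      utils::write.csv(cmp$summary,
                       file.path(out, paste0("preservation_", sx, ".csv")),
                       row.names = FALSE, na = "")
      for (g in crs_groups()) {
        net <- tryCatch(build_group_network(expr, g, sx),
                        error = function(e) NULL)
        if (is.null(net)) next
        part <- detect_modules(net, config$min_size, config$cut_fraction)
        export_network(net, part,
                       file.path(out, sprintf("network_%s_%s.sif", g, sx)),
                       "SIF", config$panel)
        export_network(net, part,
                       file.path(out,
                                 sprintf("network_%s_%s.graphml", g, sx)),
                       "GraphML", config$panel)
      }
      per_sex[[sx]] <- cmp
    }
    per_sex
  })
  if (!is.null(nets)) results$networks <- nets

  ## --- hubness -------------------------------------------------------
  hub <- run_stage("hubness", function() {
    rows <- list()
    for (sx in config$sexes) {
      tests <- list()
      for (g in setdiff(crs_groups(), "CRS0")) {
        t_g <- tryCatch(
          hub_change_test(expr, g, sex = sx, n_perm = config$n_perm,
                          seed = config$seed + 5000L +
                            match(g, crs_groups())),
          error = function(e) NULL)
        if (is.null(t_g)) next
        tests[[g]] <- t_g
        met <- t_g$metrics
        met$sex <- sx; met$group <- g
        rows[[length(rows) + 1L]] <- met
      }
      if (length(tests)) {
        traj <- compartment_trajectory(tests, config$panel)
        traj$sex <- sx
        utils::write.csv(traj,
                         file.path(out, paste0("hubness_compartments_",
                                               sx, ".csv")),
                         row.names = FALSE, na = "")
      }
    }
    marker_tab <- do.call(rbind, rows)
    utils::write.csv(marker_tab, file.path(out, "hubness_markers.csv"),
                     row.names = FALSE, na = "")
    marker_tab
  })
  if (!is.null(hub)) results$hubness <- hub

  manifest <- list(seed = config$seed, n_perm = config$n_perm,
                   sexes = config$sexes, stages = status,
                   simulated = !is.null(config$sim),
                   files = list.files(out))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(list(out_dir = out, status = status, results = results))
}

#' Validate a trio of input CSVs
#'
#' Report-only schema, label and cross-key checks across the expression,
#' behavior and trace files: required columns, recognized group/sex labels,
#' duplicate animal ids, animals missing from a companion table.
#'
#' @param expression_csv,behavior_csv,traces_csv file paths.
#' @return data.frame with columns `file`, `row`, `message` (zero rows when
#'   everything is consistent).
#' @export
validate_inputs <- function(expression_csv, behavior_csv, traces_csv) {
  viol <- data.frame(file = character(), row = integer(),
                     message = character(), stringsAsFactors = FALSE)
  add <- function(file, row, message)
    viol <<- rbind(viol, data.frame(file = file, row = row,
                                    message = message,
                                    stringsAsFactors = FALSE))
  read1 <- function(path) utils::read.csv(path, stringsAsFactors = FALSE,
                                          na.strings = "")
  expr <- read1(expression_csv)
  beh <- read1(behavior_csv)
  tr <- read1(traces_csv)

  need <- c("animal_id", "sex", "group")
  for (col in setdiff(need, names(expr)))
    add("expression", NA, paste("missing column", col))
  if (all(need %in% names(expr))) {
    for (i in which(!expr$group %in% crs_groups()))
      add("expression", i + 1L,
          paste0("unknown group label '", expr$group[i], "'"))
    for (i in which(!expr$sex %in% crs_sexes()))
      add("expression", i + 1L,
          paste0("unknown sex label '", expr$sex[i], "'"))
    for (i in which(duplicated(expr$animal_id)))
      add("expression", i + 1L,
          paste0("duplicate animal_id '", expr$animal_id[i], "'"))
  }
  for (col in setdiff(c("animal_id", "week"), names(beh)))
    add("behavior", NA, paste("missing column", col))
  for (col in setdiff(c("animal_id", "week", "bin_start_hour", "zone",
                        "minutes"), names(tr)))
    add("traces", NA, paste("missing column", col))
  if ("zone" %in% names(tr))
    for (i in which(!tr$zone %in% c("SZ", "FZ")))
      add("traces", i + 1L, paste0("unknown zone '", tr$zone[i], "'"))

  if ("animal_id" %in% names(expr) && "animal_id" %in% names(beh)) {
    for (id in setdiff(expr$animal_id, beh$animal_id))
      add("behavior", NA,
          paste0("animal '", id, "' in expression but not behavior"))
    for (id in setdiff(beh$animal_id, expr$animal_id))
      add("expression", NA,
          paste0("animal '", id, "' in behavior but not expression"))
  }
  if ("animal_id" %in% names(expr) && "animal_id" %in% names(tr))
    for (id in setdiff(expr$animal_id, tr$animal_id))
      add("traces", NA,
          paste0("animal '", id, "' in expression but not traces"))
  viol
}
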
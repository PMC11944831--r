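#' Assemble a pipeline run configuration
#'
#' Bundles per-stage parameter blocks for [run_tpp_pipeline()]. Stages can
#' be toggled via `stages`; defaults run the full simulate - fit - nparc -
#' annotate - integrate chain on a seeded simulation and the packaged
#' compound tables.
#'
#' @param output_dir Directory for all output tables and the run summary.
#' @param stages Character subset of
#'   `c("simulate", "fit", "nparc", "annotate", "integrate")`.
#' @param simulate A [sim_config()]; its seed is overridden by `seed`.
#' @param melt_table Optional path to an existing melt table; used by the
#'   fit/nparc stages instead of the simulation output.
#' @param fit List: `r2_min`, `plateau_max`, `extrapolation_margin`.
#' @param nparc List: `df_mode`, `alpha`, `marked_alpha`, `adj_alpha`.
#' @param annotate List: `negative_path`, `positive_path` (default:
#'   packaged tables), `score_min`, `ratio_min`, `ppm_tol`.
#' @param integrate List: `docking_path` (default packaged table),
#'   `edge_list_path` (optional), `target_list_paths` (optional named
#'   character), `xp_max`, `dg_max`.
#' @param seed Integer seed governing all randomness in the run.
#' @return A `tpp_run_config` list.
#' @export
run_config <- function(output_dir,
                       stages = c("simulate", "fit", "nparc", "annotate",
                                  "integrate"),
                       simulate = sim_config(),
                       melt_table = NULL,
                       fit = list(r2_min = 0.8, plateau_max = 0.3,
                                  extrapolation_margin = 5),
                       nparc = list(df_mode = "empirical", alpha = 0.05,
                                    marked_alpha = 0.01, adj_alpha = 0.1),
                       annotate = list(negative_path = NULL,
                                       positive_path = NULL,
                                       score_min = 80, ratio_min = 20,
                                       ppm_tol = 5),
                       integrate = list(docking_path = NULL,
                                        edge_list_path = NULL,
                                        target_list_paths = NULL,
                                        xp_max = -6, dg_max = -30),
                       seed = 1L) {
  structure(list(output_dir = output_dir, stages = stages,
                 simulate = simulate, melt_table = melt_table,
                 fit = fit, nparc = nparc, annotate = annotate,
                 integrate = integrate, seed = as.integer(seed)),
            class = "tpp_run_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `tpp_run_config`.
#' @return Character vector of violations, each naming the offending field
#'   and constraint; empty when the configuration is usable.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  known <- c("simulate", "fit", "nparc", "annotate", "integrate")
  chk(is.character(config$stages) && all(config$stages %in% known),
      paste0("stages: must be a subset of ", paste(known, collapse = ", ")))
  chk(is.character(config$output_dir) && length(config$output_dir) == 1,
      "output_dir: must be a single path")
  if ("simulate" %in% config$stages) {
    v <- c(v, validate_sim_config(config$simulate))
  }
  for (f in c("alpha", "marked_alpha", "adj_alpha")) {
    val <- config$nparc[[f]]
    chk(is.numeric(val) && length(val) == 1 && val > 0 && val <= 1,
        paste0("nparc$", f, ": must lie in (0, 1]"))
  }
  chk(config$nparc$df_mode %in% c("empirical", "theoretical"),
      "nparc$df_mode: must be 'empirical' or 'theoretical'")
  chk(is.numeric(config$fit$r2_min) && config$fit$r2_min <= 1,
      "fit$r2_min: must be numeric and <= 1")
  chk(is.numeric(config$fit$plateau_max) && config$fit$plateau_max > 0,
      "fit$plateau_max: must be positive")
  paths <- c(melt_table = config$melt_table,
             annotate_negative = config$annotate$negative_path,
             annotate_positive = config$annotate$positive_path,
             integrate_docking = config$integrate$docking_path,
             integrate_edge_list = config$integrate$edge_list_path,
             config$integrate$target_list_paths)
  for (i in seq_along(paths)) {
    chk(file.exists(paths[[i]]),
        paste0(names(paths)[i], ": file does not exist: ", paths[[i]]))
  }
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        is.finite(config$seed),
      "seed: must be a single integer")
  v
}

#' Run the TPP analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every table to
#' `output_dir` together with the resolved configuration
#' (`run_config.yaml`) and a machine-readable summary
#' (`run_summary.json`). Identical configuration and seed give identical
#' outputs. A failing stage is recorded in the summary (`status =
#' "failed"`), downstream dependent stages are skipped, and the summary's
#' `ok` flag is `FALSE`.
#'
#' @param config A [run_config()] object.
#' @return A `tpp_run_summary` list: per-stage record counts, hit-tier
#'   counts, thresholds used, package version and seed.
#' @export
run_tpp_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    abort(paste0("invalid pipeline configuration:\n",
                 paste0("- ", violations, collapse = "\n")),
          class = "tppshift_config_error")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  summary <- list(
    package_version = as.character(utils::packageVersion("tppshift")),
    seed = config$seed, stages = list(), ok = TRUE)
  run_stage <- function(name, deps_ok, fun) {
    if (!name %in% config$stages) {
      summary$stages[[name]] <<- list(status = "disabled")
      return(invisible(NULL))
    }
    if (!deps_ok) {
      summary$stages[[name]] <<- list(status = "skipped (failed dependency)")
      summary$ok <<- FALSE
      return(invisible(NULL))
    }
    rec <- tryCatch(c(list(status = "ok"), fun()),
                    error = function(e) {
                      summary$ok <<- FALSE
                      list(status = "failed", error = conditionMessage(e))
                    })
    summary$stages[[name]] <<- rec
    invisible(NULL)
  }
  state <- new.env(parent = emptyenv())

  run_stage("simulate", TRUE, function() {
    cfg <- config$simulate
    cfg$seed <- config$seed
    sim <- simulate_tpp(cfg)
    state$profiles <- sim$profiles
    state$truth <- sim$truth
    write_melt_table(sim$profiles, out("melt_table.tsv"))
    readr::write_tsv(sim$truth, out("ground_truth.tsv"))
    list(n_proteins = cfg$n_proteins, n_rows = nrow(sim$profiles),
         n_true_shifters = sum(sim$truth$shifter) / 2L)
  })

  need_profiles <- function() {
    if (is.null(state$profiles)) {
      if (is.null(config$melt_table)) {
        stop("no melt table available: enable the simulate stage or set melt_table")
      }
      state$profiles <- read_melt_table(config$melt_table)
    }
    state$profiles
  }

  sim_ok <- !"simulate" %in% config$stages ||
    identical(summary$stages$simulate$status, "ok")

  run_stage("fit", sim_ok, function() {
    profiles <- need_profiles()
    fits <- fit_melt_curves(profiles, config$fit$extrapolation_margin) |>
      curve_quality_filter(config$fit$r2_min, config$fit$plateau_max)
    state$fits <- fits
    readr::write_tsv(fits, out("melt_fits.tsv"))
    dt <- delta_tm(fits, conditions = unique(profiles$condition)[1:2])
    readr::write_tsv(dt, out("delta_tm.tsv"))
    list(n_fits = nrow(fits), n_valid = sum(fits$valid),
         n_quality_pass = sum(fits$quality_pass), n_delta_tm = nrow(dt),
         r2_min = config$fit$r2_min, plateau_max = config$fit$plateau_max)
  })

  fit_ok <- !"fit" %in% config$stages ||
    identical(summary$stages$fit$status, "ok")

  run_stage("nparc", sim_ok && fit_ok, function() {
    profiles <- need_profiles()
    res <- nparc_test(profiles,
                      conditions = unique(profiles$condition)[1:2],
                      df_mode = config$nparc$df_mode,
                      alpha = config$nparc$alpha,
                      marked_alpha = config$nparc$marked_alpha,
                      adj_alpha = config$nparc$adj_alpha)
    state$nparc <- res
    readr::write_tsv(tibble::as_tibble(res), out("nparc_results.tsv"))
    hs <- hit_summary(res, config$nparc$alpha, config$nparc$marked_alpha,
                      config$nparc$adj_alpha)
    jsonlite::write_json(as.list(hs), out("nparc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    c(as.list(hs), list(df_mode = config$nparc$df_mode,
                        alpha = config$nparc$alpha,
                        marked_alpha = config$nparc$marked_alpha,
                        adj_alpha = config$nparc$adj_alpha))
  })

  run_stage("annotate", TRUE, function() {
    neg_path <- config$annotate$negative_path %||%
      tppshift_example("table1_negative.tsv")
    pos_path <- config$annotate$positive_path %||%
      tppshift_example("table2_positive.tsv")
    neg <- read_compound_table(neg_path) |>
      annotate_theoretical_mz(config$annotate$ppm_tol)
    pos <- read_compound_table(pos_path) |>
      annotate_theoretical_mz(config$annotate$ppm_tol)
    neg_kept <- filter_main_components(neg, config$annotate$score_min,
                                       config$annotate$ratio_min)
    pos_kept <- filter_main_components(pos, config$annotate$score_min,
                                       config$annotate$ratio_min)
    uniq <- deduplicate_across_modes(neg_kept, pos_kept)
    state$compounds <- uniq
    readr::write_tsv(uniq, out("compounds_unique.tsv"))
    list(n_negative = nrow(neg), n_negative_kept = nrow(neg_kept),
         n_positive = nrow(pos), n_positive_kept = nrow(pos_kept),
         n_unique = nrow(uniq),
         n_mz_ok = sum(neg_kept$mz_ok) + sum(pos_kept$mz_ok),
         score_min = config$annotate$score_min,
         ratio_min = config$annotate$ratio_min,
         ppm_tol = config$annotate$ppm_tol)
  })

  run_stage("integrate", TRUE, function() {
    rec <- list(xp_max = config$integrate$xp_max,
                dg_max = config$integrate$dg_max)
    dock_path <- config$integrate$docking_path %||%
      tppshift_example("table4_docking.tsv")
    dock <- readr::read_tsv(dock_path, show_col_types = FALSE) |>
      docking_threshold_filter(config$integrate$xp_max,
                               config$integrate$dg_max)
    readr::write_tsv(dock, out("docking_flagged.tsv"))
    rec$n_docked <- nrow(dock)
    rec$n_stable_binding <- sum(dock$stable_binding)
    lists <- list()
    if (!is.null(config$integrate$target_list_paths)) {
      lists <- lapply(config$integrate$target_list_paths, read_target_list)
    }
    if (!is.null(state$nparc)) {
      sig <- state$nparc$protein_id[!is.na(state$nparc$p_value) &
                                      state$nparc$p_value < config$nparc$alpha]
      lists$tpp_significant <- sig
    }
    if (length(lists) > 0) {
      merged <- merge_target_lists(lists)
      readr::write_tsv(merged, out("targets_merged.tsv"))
      rec$n_targets <- nrow(merged)
    }
    if (!is.null(config$integrate$edge_list_path)) {
      net <- interaction_network(
        read_edge_list(config$integrate$edge_list_path)) |>
        isolate_filter()
      rank <- degree_ranking(net)
      readr::write_tsv(rank, out("degree_ranking.tsv"))
      rec$n_network_nodes <- nrow(rank)
      rec$top_target <- rank$symbol[1]
    }
    rec
  })

  yaml::write_yaml(serialize_config(config), out("run_config.yaml"))
  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(summary, class = "tpp_run_summary")
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$simulate <- unclass(x$simulate)
  x
}

#' @export
print.tpp_run_summary <- function(x, ...) {
  cat("<tpp_run_summary> seed", x$seed,
      if (isTRUE(x$ok)) "(ok)" else "(FAILED)", "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    counts <- st[setdiff(names(st), c("status", "error"))]
    cat(sprintf("  %-9s %s  %s\n", nm, st$status,
                paste(names(counts), unlist(counts), sep = "=",
                      collapse = " ")))
  }
  invisible(x)
}
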
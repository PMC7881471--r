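# End-to-end orchestration: simulate -> featurize -> select -> train ->
# sweep -> report, driven by a YAML/list run configuration. Each stage
# writes its artifacts under the output directory; any stage error aborts
# with a stage-labeled message.

#' Named feature configurations
#'
#' The seven model configurations compared by the package: each names the
#' feature block(s) entering the ROI and network kernels. Single-block
#' configurations pin the kernel weight beta to 0 or 1.
#'
#' @return Named list; each element has `roi_block` and `net_block`.
#' @export
feature_presets <- function() {
  list(
    net_L4     = list(roi_block = NULL,     net_block = "net_L4"),
    net_L3     = list(roi_block = NULL,     net_block = "net_L3"),
    net_L2     = list(roi_block = NULL,     net_block = "net_L2"),
    net_all    = list(roi_block = NULL,     net_block = "net_all"),
    roi_L4     = list(roi_block = "roi_L4", net_block = NULL),
    roi_net_L4 = list(roi_block = "roi_L4", net_block = "net_L4"),
    multilevel = list(roi_block = "roi_L4", net_block = "net_all")
  )
}

default_run_config <- function() {
  list(
    seed = 1L,
    out = "hiernet_run",
    atlas = "aal78",
    cohort = NULL,
    simulate = list(n_per_group = 34, roi_effects = NULL, edge_effects = NULL),
    configuration = "multilevel",
    cv = list(),
    selection = list(),
    beta_grid = seq(0, 1, by = 0.1),
    top_k = 15
  )
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "hiernet_pipeline_error")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_run_config(), config)
  if (!cfg$configuration %in% names(feature_presets())) {
    abort(paste0("unknown configuration: ", cfg$configuration,
                 " (expected one of ",
                 paste(names(feature_presets()), collapse = ", "), ")"),
          class = "hiernet_pipeline_error")
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", name, "] ", conditionMessage(e)),
          class = "hiernet_pipeline_error", parent = e)
  })
}

#' Run the classification pipeline from a configuration
#'
#' Executes the requested stages in order: `simulate` draws a synthetic
#' cohort (skipped when `config$cohort` points at an existing cohort
#' directory), `featurize` assembles the feature blocks and writes them as
#' wide CSVs plus a JSON feature manifest, `select` runs the cascade once on
#' the full cohort (an exploratory trace; the cross-validated runs refit it
#' per fold), `train` runs [nested_cv()] under the chosen feature
#' configuration, `sweep` runs [weight_sweep()], and `report` renders the
#' metric and frequency tables. A provenance block (config echo, seed,
#' package version) is always written.
#'
#' @param config A run configuration: a YAML file path or a named list.
#'   Recognised fields: `seed`, `out`, `atlas`, `cohort`, `simulate`
#'   (`n_per_group`, `roi_effects`, `edge_effects`), `configuration` (one of
#'   [feature_presets()]), `cv`, `selection` (argument lists for
#'   [cv_config()] / [selection_config()]), `beta_grid`, `top_k`.
#' @param steps Which stages to run.
#' @return Invisibly, a list with the artifacts produced (`cohort`, `blocks`,
#'   `report`, `sweep`, paths).
#' @export
run_pipeline <- function(config,
                         steps = c("simulate", "featurize", "train",
                                   "report")) {
  cfg <- load_run_config(config)
  steps <- match.arg(steps, c("simulate", "featurize", "select", "train",
                              "sweep", "report"), several.ok = TRUE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  atlas <- stage("atlas", load_atlas(cfg$atlas))
  out <- list(out_dir = cfg$out)

  provenance <- list(
    package = "hiernet",
    version = as.character(utils::packageVersion("hiernet")),
    seed = cfg$seed,
    configuration = cfg$configuration,
    config = cfg[setdiff(names(cfg), "out")]
  )
  jsonlite::write_json(provenance, file.path(cfg$out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cohort <- NULL
  if (!is.null(cfg$cohort)) {
    cohort <- stage("load", read_cohort(cfg$cohort, atlas))
  } else if ("simulate" %in% steps) {
    cohort <- stage("simulate", {
      as_effects <- function(x) {
        if (is.null(x)) NULL else dplyr::bind_rows(x)
      }
      sc <- sim_config(
        n_per_group = cfg$simulate$n_per_group %||% 34,
        roi_effects = as_effects(cfg$simulate$roi_effects),
        edge_effects = as_effects(cfg$simulate$edge_effects)
      )
      co <- simulate_cohort(sc, atlas, seed = cfg$seed)
      write_cohort(co, file.path(cfg$out, "cohort"))
      co
    })
  }
  if (is.null(cohort)) {
    abort("[input] no cohort: supply config$cohort or include the simulate step",
          class = "hiernet_pipeline_error")
  }
  out$cohort <- cohort

  preset <- feature_presets()[[cfg$configuration]]
  need <- unique(c("roi_L4", "net_all", preset$roi_block, preset$net_block))
  blocks <- stage("featurize", assemble_blocks(cohort, atlas, blocks = need))
  out$blocks <- blocks
  if ("featurize" %in% steps) {
    stage("featurize", {
      for (b in names(blocks$blocks)) {
        readr::write_csv(block_tibble(blocks, b),
                         file.path(cfg$out, paste0("features_", b, ".csv")),
                         progress = FALSE)
      }
      jsonlite::write_json(blocks$manifest,
                           file.path(cfg$out, "feature_manifest.json"),
                           dataframe = "rows", digits = NA)
    })
  }

  sel_cfg <- do.call(selection_config, cfg$selection)
  cv_cfg <- do.call(cv_config, c(cfg$cv, list(
    selection = sel_cfg,
    roi_block = preset$roi_block, net_block = preset$net_block)))

  if ("select" %in% steps) {
    stage("select", {
      y <- blocks$labels
      for (role in c("roi", "net")) {
        bn <- cv_cfg[[paste0(role, "_block")]]
        if (is.null(bn)) next
        casc <- with_seed(cfg$seed,
                          run_cascade(blocks$blocks[[bn]], y, sel_cfg))
        readr::write_csv(tibble::tibble(feature = casc$selected),
                         file.path(cfg$out, paste0("selected_", bn, ".csv")),
                         progress = FALSE)
        jsonlite::write_json(
          list(block = bn, rfe_keep = casc$trace$rfe_keep,
               survivors = casc$trace$survivors),
          file.path(cfg$out, paste0("selection_trace_", bn, ".json")),
          digits = NA)
      }
    })
  }

  if ("train" %in% steps) {
    report <- stage("train", nested_cv(blocks, cv_cfg, seed = cfg$seed))
    out$report <- report
    stage("train", {
      readr::write_csv(report$per_rep,
                       file.path(cfg$out, "cv_metrics_per_rep.csv"),
                       progress = FALSE)
      jsonlite::write_json(
        list(summary = report$summary, fits = report$fits,
             frequencies = report$frequencies,
             n_fits = report$n_fits, seed = cfg$seed),
        file.path(cfg$out, "cv_report.json"),
        dataframe = "rows", digits = NA)
    })
    if ("report" %in% steps) {
      stage("report", render_report(report, dir = cfg$out,
                                    top_k = cfg$top_k,
                                    label = cfg$configuration))
    }
  }

  if ("sweep" %in% steps) {
    sw <- stage("sweep", weight_sweep(blocks, cfg$beta_grid, cv_cfg,
                                      seed = cfg$seed))
    out$sweep <- sw
    readr::write_csv(sw, file.path(cfg$out, "weight_sweep.csv"),
                     progress = FALSE)
  }
  invisible(out)
}

#' Render metric and frequency tables from a cross-validation report
#'
#' Produces the human-readable summary of a [nested_cv()] run: one metric
#' row (mean over repetitions of ACC, AUC, SEN, SPE, Y, F, BAC, as
#' percentages) and the top-k selection-frequency tables for the regional
#' and network features. Markdown and CSV outputs contain identical numbers.
#'
#' @param report A `cv_report`.
#' @param dir Optional output directory; when given, writes
#'   `report_metrics.csv`, `report_roi_frequencies.csv`,
#'   `report_net_frequencies.csv` and `report.md`.
#' @param top_k Rows per frequency table.
#' @param label Row label for the metric table.
#' @return Invisibly, a list with `metrics`, `roi_frequencies`,
#'   `net_frequencies` and the markdown lines.
#' @export
render_report <- function(report, dir = NULL, top_k = 15,
                          label = "multilevel") {
  stopifnot(inherits(report, "cv_report"))
  if (nrow(report$per_rep) == 0) {
    abort("empty report", class = "hiernet_pipeline_error")
  }
  means <- setNames(report$summary$mean, report$summary$metric)
  metrics <- dplyr::bind_cols(
    tibble::tibble(configuration = label),
    tibble::as_tibble(as.list(round(100 * means, 2)))
  )
  freq <- list(roi = NULL, net = NULL)
  for (role in c("roi", "net")) {
    if (!is.null(report$config[[paste0(role, "_block")]])) {
      freq[[role]] <- frequency_table(report, role, top_k = top_k)
    }
  }
  md <- c(
    paste0("# Classification report (", label, ")"),
    "",
    paste0("Subjects: ", report$n_subjects, "; repetitions: ",
           report$config$repetitions, " x ", report$config$outer_folds,
           "-fold."),
    "",
    "## Performance (%, mean over repetitions)",
    "",
    md_table(metrics)
  )
  for (role in c("roi", "net")) {
    if (!is.null(freq[[role]])) {
      tab <- freq[[role]]
      show <- tab[c("rank", "feature", "frequency", "roi_i_name",
                    "roi_i_hemi", "roi_j_name", "roi_j_hemi", "measure")]
      md <- c(md, "",
              paste0("## Top ", nrow(tab), " ",
                     if (role == "roi") "regional" else "network",
                     " features by selection frequency (of ",
                     report$n_fits, " fold-fits)"),
              "", md_table(show))
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(metrics, file.path(dir, "report_metrics.csv"),
                     progress = FALSE)
    if (!is.null(freq$roi)) {
      readr::write_csv(freq$roi, file.path(dir, "report_roi_frequencies.csv"),
                       progress = FALSE)
    }
    if (!is.null(freq$net)) {
      readr::write_csv(freq$net, file.path(dir, "report_net_frequencies.csv"),
                       progress = FALSE)
    }
    writeLines(md, file.path(dir, "report.md"))
  }
  invisible(list(metrics = metrics, roi_frequencies = freq$roi,
                 net_frequencies = freq$net, markdown = md))
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  fmt[is.na(fmt) | fmt == "NA"] <- ""
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
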
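# End-to-end orchestration: simulate (or load) -> features -> selection ->
# factor analysis -> strategy comparison -> report, with every intermediate
# artifact written beside a resolved copy of the configuration.

#' Pipeline run configuration
#'
#' @param input list describing the input source: `list(type =
#'   "simulation", n_per_type =, seed =)` for the built-in generator,
#'   `list(type = "images", paths =)` for image files, or `list(type =
#'   "features", path =)` for a pre-computed feature CSV.
#' @param scan box-scan and local-scan settings (`n_sizes`, `n_offsets`,
#'   `seed`, `window_sizes`, `sample_stride`).
#' @param selection thresholds (`r_threshold`, `explvar_min`,
#'   `loading_min`).
#' @param k_range candidate cluster counts.
#' @param strategies clustering strategies to compare.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = list(type = "simulation", n_per_type = 50,
                                    seed = 1),
                       scan = list(n_sizes = 10, n_offsets = 12, seed = 1,
                                   window_sizes = c(5, 9, 17, 33),
                                   sample_stride = 2),
                       selection = list(r_threshold = 0.7, explvar_min = 3,
                                        loading_min = 0.70, n_factors = 5),
                       k_range = 2:7,
                       strategies = c("factor_scores", "top_mmi_params",
                                      "factor_loading_params"),
                       out_dir = "cytofractal_run") {
  cfg <- structure(list(input = input, scan = scan, selection = selection,
                        k_range = k_range, strategies = strategies,
                        out_dir = out_dir),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config` to validate; errors describe the offending
#'   field.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg$input) || is.null(cfg$input$type) ||
      !cfg$input$type %in% c("simulation", "images", "features"))
    stop("config: input$type must be simulation, images or features")
  if (cfg$input$type == "simulation" &&
      (is.null(cfg$input$n_per_type) || cfg$input$n_per_type < 1))
    stop("config: simulation input needs n_per_type >= 1")
  if (cfg$input$type == "images" && is.null(cfg$input$paths))
    stop("config: images input needs paths")
  if (cfg$input$type == "features" && is.null(cfg$input$path))
    stop("config: features input needs path")
  for (f in c("n_sizes", "n_offsets", "seed", "sample_stride"))
    if (!is.numeric(cfg$scan[[f]]) || cfg$scan[[f]] < 1)
      stop("config: scan$", f, " must be a positive number")
  if (length(cfg$scan$window_sizes) < 3)
    stop("config: scan$window_sizes needs >= 3 sizes")
  if (cfg$selection$r_threshold <= 0 || cfg$selection$r_threshold > 1)
    stop("config: selection$r_threshold must be in (0, 1]")
  if (any(cfg$k_range < 2)) stop("config: k_range must be >= 2")
  if (!all(cfg$strategies %in% c("factor_scores", "top_mmi_params",
                                 "factor_loading_params")))
    stop("config: unknown strategy")
  invisible(TRUE)
}

#' Save / load a run configuration as YAML
#'
#' Round-trips through [yaml::write_yaml()]; `load_run_config` validates on
#' read.
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- structure(raw, class = "run_config")
  cfg$k_range <- as.integer(unlist(cfg$k_range))
  cfg$strategies <- as.character(unlist(cfg$strategies))
  cfg$scan$window_sizes <- as.numeric(unlist(cfg$scan$window_sizes))
  validate_run_config(cfg)
  cfg
}

# fixed-precision number formatting so repeated runs are byte-identical
fmt_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

#' Run the full classification pipeline
#'
#' Executes every stage on the configured input and writes
#' `features.csv`, `selection.json`, `factors.json`, `eval.json`,
#' `summary.md` and the resolved `config.yaml` into `out_dir`. A failing
#' stage aborts with the stage name; artifacts of completed stages are
#' kept.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly) list with `features`, `selection`, `comparison`,
#'   `population` (if simulated), and `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %-10s %6.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }

  fstage <- stage("features", {
    if (cfg$input$type == "features") {
      list(features = read_features_csv(cfg$input$path),
           population = NULL)
    } else {
      population <- NULL
      images <- if (cfg$input$type == "simulation") {
        population <- generate_population(morphotype_presets(),
                                          cfg$input$n_per_type,
                                          seed = cfg$input$seed)
        population$images
      } else {
        lapply(cfg$input$paths, load_binary_image)
      }
      list(features = compute_feature_table(
        images, n_sizes = cfg$scan$n_sizes, n_offsets = cfg$scan$n_offsets,
        seed = cfg$scan$seed, window_sizes = cfg$scan$window_sizes,
        sample_stride = cfg$scan$sample_stride),
        population = population)
    }
  })
  features <- fstage$features
  population <- fstage$population
  write_features_csv(features, file.path(cfg$out_dir, "features.csv"))

  selection <- stage("selection", {
    correlation_filter(zscore(features), cfg$selection$r_threshold)
  })
  fmt_json(list(mmi = as.list(selection$mmi),
                retained = selection$retained,
                dropped = selection$dropped),
           file.path(cfg$out_dir, "selection.json"))

  comparison <- stage("cluster", {
    compare_strategies(zscore(features), mmi = selection$mmi,
                       retained = selection$retained,
                       k_range = cfg$k_range,
                       strategies = cfg$strategies,
                       explvar_min = cfg$selection$explvar_min,
                       loading_min = cfg$selection$loading_min,
                       n_factors = cfg$selection$n_factors)
  })
  fmt_json(list(loadings = as.data.frame(comparison$factor_model$loadings),
                explained_variance =
                  as.list(comparison$factor_model$explained_variance),
                communalities =
                  as.list(comparison$factor_model$communalities),
                retained_factors =
                  comparison$factor_selection$retained_factors,
                chosen = as.list(comparison$factor_selection$chosen)),
           file.path(cfg$out_dir, "factors.json"))
  w <- comparison$winner
  fmt_json(list(report = comparison$report,
                winner = list(strategy = w$strategy, k = w$k),
                D2 = as.data.frame(w$evaluation$D2),
                F = as.data.frame(w$evaluation$F),
                F_average = w$evaluation$F_average,
                D2_average = w$evaluation$D2_average,
                df = w$evaluation$df,
                wilks = w$evaluation$wilks$per_variable,
                tukey = lapply(w$evaluation$tukey, function(t)
                  t$significant[, c("g1", "g2", "p_adj")])),
           file.path(cfg$out_dir, "eval.json"))

  stage("summary", write_summary(cfg, features, selection, comparison,
                                 population))
  say("run complete: %s", cfg$out_dir)
  invisible(list(features = features, selection = selection,
                 comparison = comparison, population = population,
                 out_dir = cfg$out_dir))
}

write_summary <- function(cfg, features, selection, comparison,
                          population) {
  w <- comparison$winner
  labels <- w$solution$labels
  lines <- c(
    "# cytofractal run summary", "",
    sprintf("- cells: %d, parameters measured: %d", nrow(features$values),
            ncol(features$values)),
    sprintf("- retained after correlation filter (|r| < %.2f): %d (%s)",
            selection$r_threshold, length(selection$retained),
            paste(selection$retained, collapse = ", ")),
    sprintf("- retained factors: %s",
            paste(comparison$factor_selection$retained_factors,
                  collapse = ", ")),
    sprintf("- parameters loading factors: %s",
            paste(sprintf("%s<-%s",
                          names(comparison$factor_selection$chosen),
                          comparison$factor_selection$chosen),
                  collapse = ", ")),
    sprintf("- winner: strategy %s, k = %d (average F %.2f, average D2 %.2f, df %d,%d)",
            w$strategy, w$k, w$evaluation$F_average,
            w$evaluation$D2_average, w$evaluation$df[1],
            w$evaluation$df[2]),
    "", "## Strategy ranking (by average F)", "",
    knit_table(head(comparison$report, 10)), "",
    "## Per-type feature means +/- SE (winning solution)", "")

  disp <- feature_display_names[colnames(features$values)]
  means <- lapply(sort(unique(labels)), function(g) {
    vals <- features$values[labels == g, , drop = FALSE]
    sprintf("%.3g +/- %.2g", colMeans(vals),
            apply(vals, 2, sd) / sqrt(nrow(vals)))
  })
  tab <- data.frame(parameter = unname(disp),
                    setNames(means, paste0("type_", sort(unique(labels)))),
                    check.names = FALSE)
  lines <- c(lines, knit_table(tab), "",
             "## Tukey-Kramer inter-type differences (winning features)",
             "")
  for (v in names(w$evaluation$tukey)) {
    sig <- w$evaluation$tukey[[v]]$significant
    lines <- c(lines, sprintf("- %s: %s",
                              feature_display_names[v] %||% v,
                              if (nrow(sig) == 0) "none" else
                                paste(sprintf("%d-%d", sig$g1, sig$g2),
                                      collapse = ", ")))
  }
  if (!is.null(population)) {
    ari <- adjusted_rand_index(population$true_labels, labels)
    lines <- c(lines, "",
               sprintf("- adjusted Rand index vs planted morphotypes: %.3f",
                       ari))
  }
  writeLines(lines, file.path(cfg$out_dir, "summary.md"))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

knit_table <- function(df) {
  hdr <- paste0("| ", paste(colnames(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(format(r, trim = TRUE), collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 for identical
#' partitions (up to label permutation), about 0 for independent ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return the index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
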
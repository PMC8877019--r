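#' Pipeline configuration
#'
#' Settings for the end-to-end workflow: rank genes, run IFS for each
#' classifier, refit the optimal classifiers, mine rules from the optimal
#' decision tree, and run the noise-robustness protocol. A single master
#' seed fans out to the stage seeds by fixed offsets (rank +1, RF +2, DT +3,
#' folds +4, SMOTE +5, noise +6), all recorded in the manifest.
#'
#' @param step,cap IFS subset-size increment and cap.
#' @param classifiers which classifiers to run IFS with (`"DT"`, `"RF"`).
#' @param n_folds cross-validation folds.
#' @param k_neighbors SMOTE neighbor count, or `NULL` to disable balancing.
#' @param cell_fraction,magnitude,n_repeats robustness protocol settings.
#' @param rank_method,rank_params feature-ranking backend and overrides.
#' @param balance_final SMOTE-balance the training matrix of the final
#'   (rule-mining) fit; off by default so passed counts refer to real cells.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(step = 5L, cap = 1000L,
                            classifiers = c("DT", "RF"), n_folds = 10L,
                            k_neighbors = 5L, cell_fraction = 0.10,
                            magnitude = 0.10, n_repeats = 10L,
                            rank_method = "xgboost", rank_params = list(),
                            balance_final = FALSE, seed = 1L) {
  classifiers <- match.arg(classifiers, c("DT", "RF"), several.ok = TRUE)
  structure(list(step = as.integer(step), cap = as.integer(cap),
                 classifiers = classifiers, n_folds = as.integer(n_folds),
                 k_neighbors = if (is.null(k_neighbors)) NULL
                               else as.integer(k_neighbors),
                 cell_fraction = cell_fraction, magnitude = magnitude,
                 n_repeats = as.integer(n_repeats),
                 rank_method = rank_method, rank_params = rank_params,
                 balance_final = balance_final, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full workflow and write a report bundle
#'
#' Executes rank -> IFS (per classifier) -> optimal refits -> rule mining
#' (from the optimal DT) -> robustness (on the optimal RF when run, else the
#' optimal DT), writing every artifact plus a machine-readable manifest of
#' all parameters and seeds to `out_dir`. Rerunning with an identical
#' configuration reproduces the bundle bit-identically.
#'
#' @param data a labeled [expression_dataset()].
#' @param out_dir output directory (created if absent).
#' @param cfg a [pipeline_config()].
#' @param progress print per-stage progress.
#' @return invisibly, a list with the in-memory results (`ranked`, `curves`,
#'   `reports`, `rules`, `robustness`, `manifest`).
#' @export
run_pipeline <- function(data, out_dir, cfg = pipeline_config(),
                         progress = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(rank = cfg$seed + 1L, rf = cfg$seed + 2L, dt = cfg$seed + 3L,
                cv = cfg$seed + 4L, smote = cfg$seed + 5L,
                noise = cfg$seed + 6L)
  balance <- if (is.null(cfg$k_neighbors)) NULL else
    balancing_config(k_neighbors = cfg$k_neighbors, seed = seeds$smote)
  manifest <- list(
    config = cfg[setdiff(names(cfg), "rank_params")],
    rank_params = cfg$rank_params, seeds = seeds,
    n_cells = n_cells(data), n_genes = n_genes(data),
    class_names = class_names(data),
    package_version = as.character(utils::packageVersion("cellrules")),
    status = "incomplete", stage = NA_character_, files = character(0))
  class(manifest$config) <- NULL
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null")
  }
  stage <- function(name, expr) {
    manifest$stage <<- name
    if (progress) message("stage: ", name)
    tryCatch(expr, error = function(e) {
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(file) manifest$files <<- c(manifest$files, file)

  ranked <- stage("rank", {
    r <- rank_features(data, params = cfg$rank_params, seed = seeds$rank,
                       method = cfg$rank_method)
    write_ranked_list(r, file.path(out_dir, "ranked_list.tsv"))
    emit("ranked_list.tsv")
    r
  })

  curves <- list()
  reports <- list()
  optima <- list()
  for (cl in cfg$classifiers) {
    spec <- classifier_spec(cl, seed = seeds[[tolower(cl)]])
    curves[[cl]] <- stage(paste0("ifs_", tolower(cl)), {
      cv <- run_ifs(data, ranked,
                    ifs_config(step = cfg$step, cap = cfg$cap,
                               classifier = spec, balance = balance,
                               n_folds = cfg$n_folds, cv_seed = seeds$cv),
                    progress = progress)
      write_ifs_curve(cv, file.path(out_dir, sprintf("ifs_%s.tsv", tolower(cl))))
      emit(sprintf("ifs_%s.tsv", tolower(cl)))
      cv
    })
    reports[[cl]] <- stage(paste0("report_", tolower(cl)), {
      feats <- ranked$gene_id[seq_len(curves[[cl]]$optimum_k)]
      rep <- cross_validate(data, feats, spec, n_folds = cfg$n_folds,
                            balance = balance, seed = seeds$cv)
      rep$meta$held_out_folds <- NULL
      write_report(rep, file.path(out_dir, sprintf("report_%s.json", tolower(cl))),
                   file.path(out_dir, sprintf("confusion_%s.tsv", tolower(cl))))
      emit(sprintf("report_%s.json", tolower(cl)))
      emit(sprintf("confusion_%s.tsv", tolower(cl)))
      rep
    })
    optima[[cl]] <- curves[[cl]]$optimum_k
  }

  rules <- NULL
  if ("DT" %in% cfg$classifiers) {
    rules <- stage("rules", {
      opt <- fit_optimal(data, ranked, optima$DT,
                         classifier = classifier_spec("DT", seed = seeds$dt),
                         balance = if (cfg$balance_final) balance else NULL)
      rs <- extract_rules(opt)
      write_ruleset(rs, file.path(out_dir, "ruleset.json"))
      writeLines(format_rules(rs), file.path(out_dir, "rules.txt"))
      counts <- rules_per_class(rs)
      data.table::fwrite(data.frame(cell_type = names(counts),
                                    n_rules = as.integer(counts)),
                         file.path(out_dir, "rules_per_class.tsv"), sep = "\t")
      emit("ruleset.json"); emit("rules.txt"); emit("rules_per_class.tsv")
      rs
    })
  }

  rob_cl <- if ("RF" %in% cfg$classifiers) "RF" else cfg$classifiers[1]
  robustness <- stage("robustness", {
    rb <- robustness_study(
      data, ranked, optima[[rob_cl]],
      classifier = classifier_spec(rob_cl, seed = seeds[[tolower(rob_cl)]]),
      cfg = noise_config(cell_fraction = cfg$cell_fraction,
                         magnitude = cfg$magnitude,
                         n_repeats = cfg$n_repeats, seed = seeds$noise),
      balance = balance, n_folds = cfg$n_folds, cv_seed = seeds$cv)
    data.table::fwrite(data.frame(repeat_id = seq_along(rb$scores),
                                  weighted_f1 = format_num(rb$scores)),
                       file.path(out_dir, "robustness_scores.tsv"), sep = "\t")
    jsonlite::write_json(
      list(baseline = rb$baseline, summary = as.list(rb$summary),
           classifier = rob_cl, optimum_k = optima[[rob_cl]],
           cell_fraction = cfg$cell_fraction, magnitude = cfg$magnitude,
           n_repeats = cfg$n_repeats),
      file.path(out_dir, "robustness_summary.json"),
      auto_unbox = TRUE, digits = I(17))
    emit("robustness_scores.tsv"); emit("robustness_summary.json")
    rb
  })

  manifest$stage <- NA_character_
  manifest$status <- "complete"
  manifest$optima <- optima
  write_manifest()
  invisible(list(ranked = ranked, curves = curves, reports = reports,
                 rules = rules, robustness = robustness,
                 manifest = manifest))
}
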
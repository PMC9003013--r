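#' Experiment run configuration
#'
#' Bundles every tunable of the end-to-end experiment grid:
#' datasets x bands x methods x {static, dynamic}. Defaults mirror the
#' pipeline's canonical choices: 100 Hz analysis rate, the six standard
#' bands, 3 s / 1 s sliding windows, a 1% threshold grid, selection at
#' alpha = 0.05.
#'
#' @param cohort Either a [cohort_config()] (records are generated) or a
#'   list of [eeg_recording()] objects.
#' @param bands Named list of [band_spec()]s (subset of [standard_bands()]).
#' @param methods Subset of `c("PLI", "MSC", "iCOH", "CORR")`.
#' @param network_kinds Subset of `c("static", "dynamic")`.
#' @param analysis_fs Target sampling rate in Hz; records above it are
#'   down-sampled.
#' @param plan A [window_plan()].
#' @param sp [spectral_params()].
#' @param threshold_step Grid step for [select_threshold()].
#' @param alpha Univariate selection level.
#' @param selection `"fold"` (default: the univariate screen is re-fit
#'   inside every LOOCV training fold, so the held-out sample never
#'   influences which features the model sees) or `"global"` (screen once on
#'   the full table before cross-validation -- the traditional order, kept
#'   for comparability; optimistically biased).
#' @param cv_unit `"sample"` or `"subject"`.
#' @param n_random Random graphs per small-world evaluation.
#' @param split_min_len If not `NULL`, records are split into fragments of
#'   at least this many seconds (the "split" dataset); `NULL` analyzes the
#'   original records.
#' @param seed Master seed.
#' @param out_dir Output directory for persisted tables (`NULL` = nothing
#'   written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort, bands = standard_bands()["Full"],
                       methods = "PLI", network_kinds = c("static", "dynamic"),
                       analysis_fs = 100, plan = window_plan(),
                       sp = spectral_params(), threshold_step = 0.01,
                       alpha = 0.05, selection = c("fold", "global"),
                       cv_unit = "sample", n_random = 20,
                       split_min_len = NULL, seed = 1, out_dir = NULL) {
  if (!length(bands) || !length(methods)) stop("bands and methods must be nonempty")
  selection <- match.arg(selection)
  structure(list(cohort = cohort, bands = bands, methods = methods,
                 network_kinds = network_kinds, analysis_fs = analysis_fs,
                 plan = plan, sp = sp, threshold_step = threshold_step,
                 alpha = alpha, selection = selection,
                 cv_unit = cv_unit, n_random = n_random,
                 split_min_len = split_min_len, seed = seed, out_dir = out_dir),
            class = "run_config")
}

# Build the feature table for one condition from band-filtered records.
condition_features <- function(recs, kind, method, band, cfg) {
  groups <- vapply(recs, `[[`, "", "group")
  ids <- vapply(recs, function(r)
    if (!is.na(r$segment)) paste0(r$subject_id, "_f", r$segment) else r$subject_id, "")
  subjects <- vapply(recs, `[[`, "", "subject_id")
  if (kind == "static") {
    mats <- lapply(recs, connectivity_matrix, method = method, band = band,
                   sp = cfg$sp)
    avg_by_group <- lapply(split(mats, groups), average_network)
    thr <- select_threshold(avg_by_group, cfg$threshold_step)
    feats <- t(vapply(seq_along(mats), function(i) {
      g <- apply_threshold(mats[[i]], thr$proportion)
      static_features(g, n_random = cfg$n_random,
                      seed = derive_seed(cfg$seed, i), quiet = TRUE)
    }, numeric(5)))
    colnames(feats) <- static_feature_names
  } else {
    wmats <- lapply(recs, window_matrices, method = method, band = band,
                    plan = cfg$plan, sp = cfg$sp)
    avg_by_group <- lapply(split(wmats, groups), function(l)
      average_network(unlist(l, recursive = FALSE)))
    thr <- select_threshold(avg_by_group, cfg$threshold_step)
    feats <- t(vapply(seq_along(wmats), function(i) {
      ser <- topology_series(mats = wmats[[i]], proportion = thr$proportion,
                             n_random = cfg$n_random,
                             seed = derive_seed(cfg$seed, i))
      summarize_series(ser)
    }, numeric(20)))
  }
  list(tab = feature_table(feats, groups, sample_id = ids, subject_id = subjects),
       threshold = thr)
}

#' Run the full experiment grid
#'
#' For every condition (band x method x network kind): preprocess and
#' band-filter the records, build static or sliding-window networks, select
#' the connectivity-preserving threshold on the group averages, extract
#' features, run the univariate screen, and evaluate all six classifiers
#' under LOOCV. Intermediate tables are persisted under `cfg$out_dir` when
#' set, together with a run log of versions, seeds and thresholds. A failing
#' condition is logged and skipped; the others continue.
#'
#' @param cfg A [run_config()].
#' @return List with `report` (long accuracy table from
#'   [compare_conditions()]), `conditions` (per-condition results:
#'   `threshold`, `features`, `univariate`, `cv`), and `log` (character).
#' @export
run_experiment <- function(cfg) {
  recs <- if (inherits(cfg$cohort, "cohort_config"))
    generate_cohort(cfg$cohort) else cfg$cohort
  log <- c(paste("dynconn", as.character(packageVersion("dynconn"))),
           paste("R", as.character(getRversion())),
           paste("seed", cfg$seed),
           paste("records", length(recs)))
  recs <- lapply(recs, function(r)
    if (r$fs > cfg$analysis_fs) resample_recording(r, cfg$analysis_fs) else r)
  dataset <- "original"
  if (!is.null(cfg$split_min_len)) {
    recs <- unlist(lapply(recs, split_segments, min_len = cfg$split_min_len),
                   recursive = FALSE)
    dataset <- "split"
    log <- c(log, paste("split into", length(recs), "fragments of >=",
                        cfg$split_min_len, "s"))
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  persist <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    write.table(obj, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  conditions <- list()
  results <- list()
  for (bname in names(cfg$bands)) {
    band <- cfg$bands[[bname]]
    filtered <- tryCatch(lapply(recs, bandpass_recording, band = band),
                         error = function(e) {
                           log <<- c(log, paste("band", bname, ": FAILED:",
                                                conditionMessage(e)))
                           NULL
                         })
    if (is.null(filtered)) next
    for (method in cfg$methods) for (kind in cfg$network_kinds) {
      cid <- paste(kind, method, bname, dataset, sep = ".")
      res <- tryCatch({
        cf <- condition_features(filtered, kind, method, band, cfg)
        sel <- univariate_select(cf$tab, alpha = cfg$alpha)
        if (cfg$selection == "global") {
          keep <- sel$selected
          if (!length(keep)) {
            log <- c(log, paste(cid, ": no feature passed the screen;",
                                "retaining the smallest-p feature"))
            keep <- sel$results$Item[which.min(sel$results$p)]
          }
          tab_sel <- feature_table(cf$tab[, keep, drop = FALSE], cf$tab$group,
                                   cf$tab$sample_id, cf$tab$subject_id)
          cv <- evaluate_all(tab_sel, cv_unit = cfg$cv_unit, seed = cfg$seed)
        } else {
          cv <- evaluate_all(cf$tab, cv_unit = cfg$cv_unit, seed = cfg$seed,
                             select_alpha = cfg$alpha)
          keep <- sel$selected
        }
        attr(cv, "condition") <- c(network = kind, method = method,
                                   band = bname, dataset = dataset)
        persist(data.frame(group = names(cf$threshold$disconnect_point_per_group),
                           disconnect_point = unname(cf$threshold$disconnect_point_per_group),
                           selected_proportion = cf$threshold$proportion),
                paste0(cid, ".threshold"))
        persist(cf$tab, paste0(cid, ".features"))
        persist(sel$results, paste0(cid, ".univariate"))
        persist(cv, paste0(cid, ".cv"))
        log <- c(log, paste(cid, ": threshold", cf$threshold$proportion, ";",
                            length(keep), "features retained"))
        list(threshold = cf$threshold, features = cf$tab, univariate = sel,
             cv = cv)
      }, error = function(e) {
        log <<- c(log, paste(cid, ": FAILED:", conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        conditions[[cid]] <- res
        results[[cid]] <- res$cv
      }
    }
  }
  report <- if (length(results)) compare_conditions(results) else NULL
  if (!is.null(report)) persist(report, "report")
  if (!is.null(out_dir)) writeLines(log, file.path(out_dir, "run_log.txt"))
  list(report = report, conditions = conditions, log = log)
}
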
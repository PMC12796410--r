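# End-to-end pipeline: simulate (optional) -> connectivity -> metrics ->
# PCA + clustering + stability -> comparisons -> cross-band agreement.
# Every stage writes plain-text artifacts into the run directory; a run is
# a deterministic function of (config, seed).

#' Build and validate a pipeline run configuration
#'
#' All numeric fields are validated here, before any computation. Either
#' `input_dir` (a directory of `P<id>_<pre|post>.csv` recordings plus
#' `behavioral.csv`) or `simulate = TRUE` must be chosen.
#'
#' @param out_dir Output (run) directory.
#' @param input_dir Directory with recordings; `NULL` when simulating.
#' @param simulate If `TRUE`, generate a synthetic cohort first.
#' @param sim Named list of overrides passed to [generate_cohort()].
#' @param bands List of [band_spec()]s (default delta + beta).
#' @param rate_hz Sampling rate for text recordings read from `input_dir`.
#' @param epoch_length_s Epoch length in seconds.
#' @param density Binarization edge density, in (0, 1).
#' @param k Cluster count for the reported solution.
#' @param k_range Cluster counts profiled for elbow/silhouette.
#' @param n_boot Bootstrap iterations for stability.
#' @param subsample_frac Bootstrap subsample fraction, in (0, 1].
#' @param seed Integer master seed.
#' @param write_recordings Whether simulated recordings are written out.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, input_dir = NULL, simulate = is.null(input_dir),
                       sim = list(), bands = default_bands()[c("delta", "beta")],
                       rate_hz = 256, epoch_length_s = 4, density = 0.2,
                       k = 2L, k_range = 2:8, n_boot = 300L,
                       subsample_frac = 0.8, seed = 1L,
                       write_recordings = FALSE) {
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  if (!(epoch_length_s > 0)) stop("epoch_length_s must be positive")
  if (!(subsample_frac > 0 && subsample_frac <= 1))
    stop("subsample_frac must be in (0, 1]")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (k < 2) stop("k must be >= 2")
  if (!simulate && is.null(input_dir)) stop("need input_dir or simulate = TRUE")
  for (b in bands) stopifnot(inherits(b, "band_spec"))
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulate = simulate, sim = sim, bands = bands,
                 rate_hz = rate_hz, epoch_length_s = epoch_length_s,
                 density = density, k = as.integer(k), k_range = k_range,
                 n_boot = as.integer(n_boot),
                 subsample_frac = subsample_frac, seed = as.integer(seed),
                 write_recordings = isTRUE(write_recordings)),
            class = "run_config")
}

log_info <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

read_cohort_dir <- function(input_dir, rate_hz) {
  files <- list.files(input_dir, pattern = "^P.+_(pre|post)\\.(csv|edf)$")
  if (length(files) == 0L) stop("no P<id>_<pre|post> recordings in input_dir")
  ids <- unique(sub("_(pre|post)\\.(csv|edf)$", "", files))
  recs <- lapply(ids, function(id) {
    one <- function(cond) {
      f <- files[grepl(sprintf("^%s_%s\\.", id, cond), files)]
      if (length(f) != 1L)
        stop(sprintf("participant %s: missing or duplicated %s recording",
                     id, cond))
      p <- file.path(input_dir, f)
      if (grepl("\\.edf$", f))
        read_recording_edf(p, participant_id = id, condition = cond)
      else read_recording_txt(p, rate_hz, participant_id = id,
                              condition = cond)
    }
    list(pre = one("pre"), post = one("post"))
  })
  names(recs) <- ids
  beh_path <- file.path(input_dir, "behavioral.csv")
  behavioral <- if (file.exists(beh_path)) utils::read.csv(beh_path) else NULL
  list(recordings = recs, behavioral = behavioral)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (optional), band-pass + epoch + wPLI per
#' participant/condition/band, density binarization + graph metrics, z-score
#' + KMO/Bartlett + 2-component PCA + Ward clustering + bootstrap stability
#' per band, cluster-profile comparisons against the behavioral table, the
#' paired pre/post comparison, and cross-band partition agreement. All
#' artifacts are CSV/JSON files under `config$out_dir`; a `manifest.json`
#' records the config, seed and package version. Given the same config and
#' seed the run is bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`metrics`,
#'   per-band `pca`, `solution`, `stability`, `comparisons`, `agreement`)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  band_names <- vapply(config$bands, function(b) b$name, "")

  ground_truth <- NULL
  if (config$simulate) {
    log_info("simulate: generating synthetic cohort (seed %d)", config$seed)
    args <- utils::modifyList(
      list(seed = config$seed, bands = config$bands), config$sim)
    cohort <- stage("simulate", do.call(generate_cohort, args))
    recordings <- cohort$recordings
    names(recordings) <- cohort$behavioral$participant_id
    behavioral <- cohort$behavioral
    ground_truth <- cohort$labels
    if (config$write_recordings)
      write_cohort(cohort, file.path(config$out_dir, "recordings"))
    utils::write.csv(behavioral, file.path(config$out_dir, "behavioral.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(participant_id = behavioral$participant_id,
                 subgroup = ground_truth),
      file.path(config$out_dir, "ground_truth.csv"), row.names = FALSE)
  } else {
    log_info("load: reading recordings from %s", config$input_dir)
    loaded <- stage("load", read_cohort_dir(config$input_dir, config$rate_hz))
    recordings <- loaded$recordings
    behavioral <- loaded$behavioral
  }

  conn_dir <- file.path(config$out_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  metrics <- list()
  conn_files <- character()
  for (id in names(recordings)) {
    for (cond in c("pre", "post")) {
      rec <- recordings[[id]][[cond]]
      for (b in config$bands) {
        w <- stage(sprintf("connectivity (participant %s, %s, %s)",
                           id, cond, b$name),
                   connectivity(rec, b, config$epoch_length_s))
        fn <- file.path(conn_dir, sprintf("%s_%s_%s.csv", id, cond, b$name))
        write_connectivity_csv(w, fn)
        conn_files <- c(conn_files, basename(fn))
        metrics[[length(metrics) + 1L]] <-
          stage(sprintf("metrics (participant %s, %s, %s)", id, cond, b$name),
                graph_metrics(w, config$density))
      }
    }
    log_info("connectivity + metrics: participant %s done", id)
  }
  metrics <- do.call(rbind, metrics)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  per_band <- list()
  label_tabs <- list()
  for (b in config$bands) {
    bn <- b$name
    log_info("cluster: band %s", bn)
    feats <- stage(paste0("features (", bn, ")"), feature_table(metrics, bn))
    z <- stage(paste0("zscore (", bn, ")"), zscore_features(feats))
    pca <- stage(paste0("pca (", bn, ")"), pca2(z))
    sol <- stage(paste0("ward (", bn, ")"),
                 ward_cluster(pca$scores, config$k_range, config$k))
    stab <- stage(paste0("stability (", bn, ")"),
                  bootstrap_stability(pca$scores, sol,
                                      n_boot = config$n_boot,
                                      frac = config$subsample_frac,
                                      seed = config$seed))
    utils::write.csv(as.data.frame(pca$loadings),
                     file.path(config$out_dir, sprintf("pca_loadings_%s.csv", bn)))
    utils::write.csv(as.data.frame(pca$scores),
                     file.path(config$out_dir, sprintf("pca_scores_%s.csv", bn)))
    utils::write.csv(
      data.frame(component = seq_along(pca$explained_variance_ratio),
                 explained_variance_ratio = pca$explained_variance_ratio,
                 kmo = as.numeric(pca$kmo), bartlett_chi2 = pca$bartlett$chi2,
                 bartlett_df = pca$bartlett$df,
                 bartlett_p = pca$bartlett$p_value),
      file.path(config$out_dir, sprintf("pca_summary_%s.csv", bn)),
      row.names = FALSE)
    utils::write.csv(
      data.frame(k = sol$k_range, inertia = sol$inertia_by_k,
                 silhouette = sol$silhouette_by_k),
      file.path(config$out_dir, sprintf("model_selection_%s.csv", bn)),
      row.names = FALSE)
    lab <- data.frame(participant_id = rownames(feats), cluster = sol$labels)
    utils::write.csv(lab, file.path(config$out_dir,
                                    sprintf("labels_%s.csv", bn)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(stab),
                     file.path(config$out_dir, sprintf("stability_%s.csv", bn)),
                     row.names = FALSE)

    comp <- NULL
    if (!is.null(behavioral)) {
      feats_df <- cbind(as.data.frame(feats), behavioral[
        match(rownames(feats), behavioral$participant_id), , drop = FALSE])
      cont <- c(colnames(feats),
                intersect(c("errors", "wm1", "wm2", "wm3", "wm_time1",
                            "wm_time2", "wm_time3", "age_years", "parent_age",
                            "child_weekday_use", "child_weekend_use",
                            "parent_weekday_use", "parent_weekend_use"),
                          names(behavioral)))
      cat2 <- intersect(c("sex", "own_device", "played_before",
                          "parent_education"), names(behavioral))
      cat2 <- cat2[vapply(cat2, function(v)
        nlevels(factor(feats_df[[v]])) == 2L, TRUE)]
      comp <- stage(paste0("compare (", bn, ")"),
                    compare_clusters(feats_df, sol$labels, cont, cat2,
                                     seed = config$seed))
      utils::write.csv(comp, file.path(config$out_dir,
                                       sprintf("comparisons_%s.csv", bn)),
                       row.names = FALSE)
    }
    pp <- stage(paste0("prepost (", bn, ")"), prepost_comparison(metrics, bn))
    utils::write.csv(pp, file.path(config$out_dir,
                                   sprintf("prepost_%s.csv", bn)),
                     row.names = FALSE)
    label_tabs[[bn]] <- sol$labels
    per_band[[bn]] <- list(features = feats, pca = pca, solution = sol,
                           stability = stab, comparisons = comp,
                           prepost = pp)
  }

  agreement <- NULL
  if (length(label_tabs) >= 2L) {
    agreement <- stage("agreement",
                       partition_agreement(label_tabs[[1L]], label_tabs[[2L]]))
    write_agreement_csv(agreement,
                        file.path(config$out_dir, "agreement.csv"),
                        names(label_tabs)[1:2])
  }

  cfg_json <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    package = "wplinet",
    version = as.character(utils::packageVersion("wplinet")),
    seed = config$seed,
    config = config_as_list(config),
    config_md5 = unname(tools::md5sum(
      local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
    connectivity_files = conn_files,
    n_participants = length(recordings),
    bands = band_names)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_info("run complete: %s", config$out_dir)
  invisible(list(out_dir = config$out_dir, metrics = metrics,
                 per_band = per_band, agreement = agreement,
                 ground_truth = ground_truth))
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$bands <- lapply(x$bands, unclass)
  if (!is.null(x$sim$bands)) x$sim$bands <- lapply(x$sim$bands, unclass)
  if (!is.null(x$sim$specs)) x$sim$specs <- lapply(x$sim$specs, unclass)
  x
}

write_agreement_csv <- function(ag, path, band_names = c("a", "b")) {
  tb <- as.matrix(ag$contingency)
  df <- data.frame(
    cell = as.vector(outer(rownames(tb), colnames(tb),
                           function(i, j) sprintf("%s%s_%s%s",
                                                  band_names[1L], i,
                                                  band_names[2L], j))),
    count = as.vector(tb))
  df2 <- data.frame(cell = c("rand_index", "adjusted_rand_index",
                             "n_concordant", "n"),
                    count = c(ag$rand_index, ag$adjusted_rand_index,
                              ag$n_concordant, ag$n))
  utils::write.csv(rbind(df, df2), path, row.names = FALSE)
  invisible(path)
}
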
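# End-to-end orchestration: library -> descriptors -> stepwise model ->
# PDD windows -> screening verdicts -> fingerprint clusters, with every
# artifact written as a diff-able text file and the run parameters logged.

.default_config <- function() {
  list(
    library_smi = NULL,     # path to .smi; NULL -> synthesize
    labels_csv = NULL,      # path to id,label CSV (with library_smi)
    n_per_class = 100,      # synthetic library size
    seed = 42,
    bin_width = 0.25,
    expectancy_threshold = 0.5,
    p_enter = 0.05,
    p_remove = 0.05,
    max_terms = 20,
    folds = 10,
    holdout_fraction = 0.2,
    fingerprint_bits = 1024,
    linkage = "average",
    srw_log_transform = FALSE,
    out_dir = "topojak_run"
  )
}

#' Read a pipeline configuration file
#'
#' Plain `key = value` text (or JSON); unknown keys are rejected so typos
#' fail loudly. Missing keys take the documented defaults.
#'
#' @param path Path to the config file.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  defaults <- .default_config()
  if (grepl("\\.json$", path)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = "="))
      if (v %in% c("TRUE", "FALSE")) as.logical(v)
      else if (grepl("^-?[0-9.]+$", v)) as.numeric(v)
      else v
    })
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, vals)
}

#' Run the full screening pipeline
#'
#' Stages, in order: load or synthesize a labeled library; compute the
#' descriptor table; select and fit a discriminant model by stepwise
#' Wilks' lambda; cross-validate; build the PDD and derive activity
#' windows; score and screen every compound; cluster the screened-active
#' compounds by fingerprint similarity. Each stage writes its artifact
#' into `out_dir` and the run report records seeds and parameters
#' sufficient to reproduce the run.
#'
#' @param config A config list (see [read_pipeline_config()] for the
#'   keys); missing entries take defaults.
#' @return Invisibly, a list with the per-stage results and the report.
#' @export
run_pipeline <- function(config = list()) {
  unknown <- setdiff(names(config), names(.default_config()))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  # stage: library
  if (!is.null(cfg$library_smi)) {
    if (!file.exists(cfg$library_smi))
      stop("configuration error: library file not found: ",
           cfg$library_smi, call. = FALSE)
    lib <- read_smi(cfg$library_smi)
    if (!is.null(cfg$labels_csv)) {
      if (!file.exists(cfg$labels_csv))
        stop("configuration error: labels file not found: ",
             cfg$labels_csv, call. = FALSE)
      labels <- read.csv(cfg$labels_csv, stringsAsFactors = FALSE)
      lib <- dplyr::left_join(lib, labels, by = "id")
    }
  } else {
    lib <- generate_library(cfg$n_per_class, seed = cfg$seed)
  }
  write_smi(lib, out("library.smi"))
  write.csv(lib[c("id", "label")], out("labels.csv"), row.names = FALSE)

  # stage: descriptors
  desc <- calc_descriptors(lib)
  write.csv(desc, out("descriptors.csv"), row.names = FALSE)

  # stage: model
  train <- dplyr::left_join(desc, lib[c("id", "label")], by = "id")
  model <- stepwise_select(train, candidates = retraining_descriptors(),
                           p_enter = cfg$p_enter, p_remove = cfg$p_remove,
                           max_terms = cfg$max_terms, name = "DF_fit")
  write_model(model, out("model.json"))

  cv <- lsocv(train, model, folds = cfg$folds,
              holdout_fraction = cfg$holdout_fraction, seed = cfg$seed)
  write.csv(cv$folds, out("validation.csv"), row.names = FALSE)

  # stage: PDD + windows
  scored <- evaluate_df(train, model)
  h <- build_pdd(scored, bin_width = cfg$bin_width)
  windows <- derive_windows(h, cfg$expectancy_threshold, model = model$name)
  write_windows(windows, out("windows.json"))

  # stage: screening
  scored$verdict <- screen_general(scored$df, windows)
  profiles <- scored[c("id", "label", "df", "verdict")]
  write.csv(profiles, out("profiles.csv"), row.names = FALSE)

  # stage: clustering of screened actives
  hits <- lib[lib$id %in% profiles$id[profiles$verdict == "active"], ]
  clusters <- if (nrow(hits) >= 2) {
    cluster_library(hits, n_bits = cfg$fingerprint_bits,
                    linkage = cfg$linkage)
  } else {
    tibble::tibble(id = hits$id, cluster = rep(1L, nrow(hits)))
  }
  write.csv(clusters, out("clusters.csv"), row.names = FALSE)

  report <- list(
    config = cfg[setdiff(names(cfg),
                         c("library_smi", "labels_csv", "out_dir"))],
    n_compounds = nrow(lib),
    model = list(descriptors = model$descriptors,
                 stats = model$stats),
    cv = as.list(cv$summary),
    windows = list(active = windows$active, nc_bounds = windows$nc_bounds),
    n_hits = sum(profiles$verdict == "active"),
    n_clusters = max(clusters$cluster)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(list(library = lib, descriptors = desc, model = model,
                 cv = cv, pdd = h, windows = windows,
                 profiles = profiles, clusters = clusters,
                 report = report))
}
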
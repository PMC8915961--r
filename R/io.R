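#' Read a tabular (CSV) file against a schema
#'
#' Reads a CSV, optionally renames columns through a mapping (so files in a
#' deposit's column layout can be adapted to the package's native names),
#' checks that every schema column is present, and coerces types. Unknown
#' columns are preserved as passthrough. Coercion failures are reported
#' with their row numbers; in strict mode (default) they are errors,
#' otherwise the offending rows are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping required column names to
#'   types among `"character"`, `"integer"`, `"numeric"`, `"logical"`.
#' @param column_map Optional named character vector
#'   `c(native_name = "file_name")` translating the file's column names.
#' @param strict Error on malformed rows (default) or drop them?
#' @return A data frame with the schema columns typed and any extra columns
#'   appended.
#' @export
read_table <- function(path, schema, column_map = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0)
      stop("mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    names(raw)[match(unname(column_map), names(raw))] <- names(column_map)
  }
  missing_col <- setdiff(names(schema), names(raw))
  if (length(missing_col) > 0)
    stop("required column(s) missing: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  bad_rows <- integer(0)
  for (col in names(schema)) {
    x <- raw[[col]]
    coerced <- switch(schema[[col]],
                      character = x,
                      integer = suppressWarnings(as.integer(x)),
                      numeric = suppressWarnings(as.numeric(x)),
                      logical = suppressWarnings(as.logical(x)),
                      stop("unknown schema type: ", schema[[col]],
                           call. = FALSE))
    bad <- which(is.na(coerced) & !is.na(x) & x != "" & x != "NA")
    bad_rows <- union(bad_rows, bad)
    raw[[col]] <- coerced
  }
  if (length(bad_rows) > 0) {
    msg <- sprintf("type coercion failed in row(s): %s",
                   paste(sort(bad_rows), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; rows dropped", call. = FALSE)
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Write results deterministically
#'
#' Writes a data frame as CSV with a fixed column order and no row names so
#' that re-running an identical configuration and seed reproduces the file
#' byte for byte.
#'
#' @param results A data frame.
#' @param path Output path (directories are created as needed).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  results <- results[, sort(names(results)), drop = FALSE]
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the full configuration (every threshold and parameter used), the
#' seed, and the package version alongside a run's outputs, so that the
#' manifest plus the seed suffice to regenerate every artifact.
#'
#' @param dir Output directory.
#' @param config The run configuration (a list; coerced to JSON).
#' @param seed The RNG seed used.
#' @param outputs Character vector of files the run wrote.
#' @return Path to `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, config, seed, outputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "covertsig",
    version = as.character(utils::packageVersion("covertsig")),
    seed = seed,
    config = config,
    outputs = outputs
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the synthetic pipeline end to end
#'
#' Orchestrates simulate -> classify -> analyze on synthetic data and
#' writes CSV artifacts plus a manifest to `out_dir`. Stage record counts
#' are logged to standard error in a funnel style (generated -> included ->
#' classified -> selected). Stages default to all three; an empty stage
#' vector is an explicit no-op.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing all generators.
#' @param stages Subset of `c("simulate", "classify", "analyze")`.
#' @param rating_cfg,experiment_cfg,thresholds Stage configurations.
#' @return Named list of computed artifacts, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         stages = c("simulate", "classify", "analyze"),
                         rating_cfg = rating_config(),
                         experiment_cfg = experiment_config(),
                         thresholds = classification_thresholds()) {
  bad <- setdiff(stages, c("simulate", "classify", "analyze"))
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  log_stage <- function(...) message(sprintf(...))
  if (length(stages) == 0) {
    log_stage("run_pipeline: no stages requested; nothing to do")
    return(invisible(list()))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  outputs <- character(0)

  if (any(c("simulate", "classify") %in% stages)) {
    rat <- generate_rating_dataset(rating_cfg, seed = seed)
    artifacts$ratings <- rat
    log_stage("simulate: %d rating records on %d tweets",
              nrow(rat$ratings), nrow(rat$truth))
    if ("simulate" %in% stages) {
      write_results(rat$ratings, file.path(out_dir, "ratings.csv"))
      write_results(rat$truth, file.path(out_dir, "ratings_truth.csv"))
      outputs <- c(outputs, "ratings.csv", "ratings_truth.csv")
    }
  }
  if ("simulate" %in% stages) {
    exp_data <- generate_experiment_dataset(experiment_cfg, seed = seed + 1L)
    artifacts$experiment <- exp_data
    log_stage("simulate: %d participants, %d rounds",
              nrow(exp_data$participants), nrow(exp_data$rounds))
    write_results(exp_data$participants,
                  file.path(out_dir, "participants.csv"))
    write_results(exp_data$rounds, file.path(out_dir, "rounds.csv"))
    outputs <- c(outputs, "participants.csv", "rounds.csv")
  }
  if ("classify" %in% stages) {
    labels <- classify_tweets(artifacts$ratings$ratings, thresholds)
    incl <- inclusion_filter(artifacts$ratings$ratings)
    artifacts$labels <- labels
    artifacts$candidates <- select_candidates(labels, thresholds)
    log_stage("classify: %d included -> %d labeled -> %d preselected",
              length(incl$included), sum(labels$category != "none"),
              sum(vapply(artifacts$candidates, nrow, integer(1))))
    write_results(labels, file.path(out_dir, "labels.csv"))
    outputs <- c(outputs, "labels.csv")
  }
  if ("analyze" %in% stages) {
    if (is.null(artifacts$experiment))
      artifacts$experiment <- generate_experiment_dataset(experiment_cfg,
                                                          seed = seed + 1L)
    ed <- artifacts$experiment
    fit <- fit_poisson_glmm(ed$rounds, ed$participants,
                            response = "covert", arm = "cross_partisan",
                            re = "participant", nAGQ = 1L)
    ame <- average_marginal_effect(fit,
                                   cell_a = list(outgroup_size = 1),
                                   cell_b = list(outgroup_size = 9))
    artifacts$fit <- fit
    artifacts$ame <- ame
    log_stage("analyze: covert AME (outgroup 1 -> 9) = %.3f [%.3f, %.3f]",
              ame$ame, ame$conf_int[1], ame$conf_int[2])
    write_results(data.frame(quantity = "ame_covert_outgroup_1_9",
                             estimate = ame$ame, se = ame$se,
                             lower = ame$conf_int[1],
                             upper = ame$conf_int[2]),
                  file.path(out_dir, "analysis.csv"))
    outputs <- c(outputs, "analysis.csv")
  }
  write_manifest(out_dir,
                 config = list(stages = stages,
                               rating_cfg = unclass(rating_cfg),
                               experiment_cfg = unclass(experiment_cfg),
                               thresholds = unclass(thresholds)),
                 seed = seed, outputs = outputs)
  invisible(artifacts)
}
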
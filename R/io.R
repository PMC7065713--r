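# Configuration files, CSV writers and run manifests.
#
# Config schema (YAML or JSON, detected by extension): keys n_states,
# feature_dim, means (list of N+1 mean vectors, absent state first),
# covariance (list of M rows), prior_presence,
# prior_content_given_presence, optional state_labels, optional flat_prior
# (enables the flat comparator), optional precisions (default sweep grid
# for this parameter set).

#' Load a model specification from a YAML or JSON config file
#'
#' Parses and fully validates a model config; every structural invariant is
#' checked at load time and violations raise an error naming the offending
#' field. Three configs covering the simulation parameter sets ship with
#' the package under `inst/extdata`: `nearthreshold_2d.yaml` (content means
#' one unit from the absent mean; posterior/confidence maps),
#' `discrimination_2d.yaml` (widely separated means; flat-SDT contrast) and
#' `masking_sweep.yaml` (the wide-separation set plus a default precision
#' grid).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @param type `"hoss"` (default) builds a [hoss_model()]; `"flat"` builds
#'   a [flat_model()] using the config's `flat_prior` (uniform if absent).
#' @return A [hoss_model()] or [flat_model()]. Any `flat_prior` or
#'   `precisions` entries are attached as attributes of the same name.
#' @examples
#' cfg <- system.file("extdata", "nearthreshold_2d.yaml", package = "hoss")
#' read_model_spec(cfg)
#' @export
read_model_spec <- function(path, type = c("hoss", "flat")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config file must be .yaml, .yml or .json: ", path)

  required <- c("n_states", "feature_dim", "means", "covariance",
                "prior_presence", "prior_content_given_presence")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config missing required key(s): ", paste(missing, collapse = ", "))

  N <- as.integer(cfg$n_states)
  M <- as.integer(cfg$feature_dim)
  if (is.na(N) || N < 1L) stop("n_states: must be an integer >= 1")
  if (is.na(M) || M < 1L) stop("feature_dim: must be an integer >= 1")

  means_list <- cfg$means
  if (is.matrix(means_list)) means_list <- asplit(means_list, 1L)
  if (length(means_list) != N + 1L)
    stop("means: expected ", N + 1L, " mean vectors (absent state first), got ",
         length(means_list))
  if (any(lengths(means_list) != M))
    stop("means: each mean vector must have feature_dim = ", M, " entries")
  means <- do.call(cbind, lapply(means_list, as.numeric))

  cov_rows <- cfg$covariance
  if (is.matrix(cov_rows)) cov_rows <- asplit(cov_rows, 1L)
  if (length(cov_rows) != M || any(lengths(cov_rows) != M))
    stop("covariance: expected ", M, " rows of ", M, " entries")
  covariance <- do.call(rbind, lapply(cov_rows, as.numeric))

  labels <- if (!is.null(cfg$state_labels)) as.character(cfg$state_labels)

  model <- if (type == "hoss") {
    hoss_model(means, covariance,
               prior_presence = as.numeric(cfg$prior_presence),
               prior_content = as.numeric(cfg$prior_content_given_presence),
               state_labels = labels)
  } else {
    flat_model(means, covariance,
               prior = if (!is.null(cfg$flat_prior)) as.numeric(cfg$flat_prior),
               state_labels = labels)
  }
  if (!is.null(cfg$flat_prior))
    attr(model, "flat_prior") <- as.numeric(cfg$flat_prior)
  if (!is.null(cfg$precisions))
    attr(model, "precisions") <- as.numeric(cfg$precisions)
  model
}

#' Write a model specification to a YAML or JSON config file
#'
#' Inverse of [read_model_spec()]; the written file round-trips to an
#' identical model.
#'
#' @param model a [hoss_model()].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "hoss_model"))
  cfg <- list(
    n_states = model$n_states,
    feature_dim = model$feature_dim,
    means = lapply(seq_len(ncol(model$means)),
                   function(k) as.numeric(model$means[, k])),
    covariance = lapply(seq_len(nrow(model$covariance)),
                        function(i) as.numeric(model$covariance[i, ])),
    prior_presence = model$prior_presence,
    prior_content_given_presence = model$prior_content,
    state_labels = model$state_labels
  )
  if (!is.null(attr(model, "flat_prior")))
    cfg$flat_prior <- attr(model, "flat_prior")
  if (!is.null(attr(model, "precisions")))
    cfg$precisions <- attr(model, "precisions")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path, precision = 17L)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("config file must be .yaml, .yml or .json: ", path)
  invisible(path)
}

#' Write a result table as a deterministic CSV
#'
#' UTF-8, header row, `.` decimal separator, `\n` line endings, rows in the
#' order given. Two runs producing identical data frames produce
#' byte-identical files.
#'
#' @param x a data frame (grid map, trial table or sweep summary).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, eol = "\n",
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Write a JSON run manifest for a set of output files
#'
#' Records everything needed to reproduce the outputs: the resolved
#' configuration snapshot, the seed, the package version, a UTC timestamp,
#' and an md5 content hash per output file. The manifest round-trips
#' losslessly through [read_manifest()].
#'
#' @param outputs character vector of output file paths (must exist).
#' @param path manifest path (`.json`).
#' @param config a list snapshot of the resolved configuration (for model
#'   runs, typically the config list written by [write_model_spec()] plus
#'   run parameters).
#' @param seed the integer seed of the run, or `NULL` for deterministic
#'   runs.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(outputs, path, config = NULL, seed = NULL) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest: output file(s) not found: ", paste(missing, collapse = ", "))
  manifest <- list(
    package = "hoss",
    version = as.character(utils::packageVersion("hoss")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    config = config,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest path written by [write_manifest()].
#' @return the manifest as a list.
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Verify that manifest hashes match the files on disk
#'
#' @param path manifest path; output files are resolved relative to the
#'   manifest's directory.
#' @return `TRUE` if every hash matches; otherwise an error naming the
#'   first mismatching file.
#' @export
verify_manifest <- function(path) {
  man <- read_manifest(path)
  dir <- dirname(path)
  for (o in man$outputs) {
    f <- file.path(dir, o$file)
    if (!file.exists(f)) stop("manifest: missing output file ", o$file)
    if (unname(tools::md5sum(f)) != o$md5)
      stop("manifest: content hash mismatch for ", o$file)
  }
  TRUE
}
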
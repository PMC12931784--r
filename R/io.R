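#' Read expert judgments from CSV
#'
#' Schema: `alternative,expert,criterion,rating_term,reliability_term`.
#' All rows are validated (terms resolve on the given scales, no duplicate
#' keys); problems are reported together with their row numbers.
#'
#' @param path CSV file path.
#' @param scales named list with `rating` and `reliability` scales.
#' @return data frame of judgments.
#' @export
read_judgments <- function(path, scales = builtin_scales()) {
  df <- .read_table(path, c("alternative", "expert", "criterion",
                            "rating_term", "reliability_term"))
  errs <- character()
  bad <- !df$rating_term %in% scales$rating$terms$term
  if (any(bad))
    errs <- c(errs, sprintf("row %d: unknown rating term '%s'",
                            which(bad), df$rating_term[bad]))
  bad <- !df$reliability_term %in% scales$reliability$terms$term
  if (any(bad))
    errs <- c(errs, sprintf("row %d: unknown reliability term '%s'",
                            which(bad), df$reliability_term[bad]))
  key <- paste(df$alternative, df$expert, df$criterion)
  dup <- duplicated(key)
  if (any(dup))
    errs <- c(errs, sprintf("row %d: duplicate judgment for (%s)",
                            which(dup), key[dup]))
  if (length(errs))
    stop("invalid judgment file '", path, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  df
}

#' Read panel votes from CSV
#'
#' Schema: `alternative,expert,Y,N,theta,n` (an optional `criterion`
#' column scopes votes per cell instead of per expert-row).
#'
#' @param path CSV file path.
#' @return data frame of votes.
#' @export
read_votes <- function(path) {
  df <- .read_table(path, c("alternative", "expert", "Y", "N", "theta", "n"))
  bad <- df$Y + df$N + df$theta != df$n
  if (any(bad))
    stop(sprintf("invalid vote file '%s': row %d does not satisfy Y+N+theta=n",
                 path, which(bad)[1]), call. = FALSE)
  df
}

#' Read BWM comparison vectors from CSV
#'
#' Schema: `expert,best,worst,criterion,bo_term,ow_term`, one row per
#' (expert, criterion).
#'
#' @param path CSV file path.
#' @param importance_scale scale the terms must resolve on.
#' @return named list of [comparison_vector()]s, one per expert.
#' @export
read_comparisons <- function(path,
                             importance_scale = builtin_scales()$importance) {
  df <- .read_table(path, c("expert", "best", "worst", "criterion",
                            "bo_term", "ow_term"))
  lapply(split(df, df$expert), function(d)
    comparison_vector(d$criterion, best = d$best[1], worst = d$worst[1],
                      best_to_others = stats::setNames(d$bo_term, d$criterion),
                      others_to_worst = stats::setNames(d$ow_term,
                                                        d$criterion),
                      expert = d$expert[1],
                      importance_scale = importance_scale))
}

#' Read a fuzzy decision matrix from CSV
#'
#' Long format with columns `alternative,criterion,l,m,u`.
#'
#' @param path CSV file path.
#' @param stage stage marker for the resulting matrix.
#' @return a `"fuzzy_matrix"`.
#' @export
read_fuzzy_matrix <- function(path, stage = "initial") {
  df <- .read_table(path, c("alternative", "criterion", "l", "m", "u"))
  fuzzy_matrix_from_df(df, stage = stage)
}

.read_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Write a ranking result
#'
#' Serializes a `"ranking_result"` at full precision as CSV or JSON; the
#' JSON form round-trips losslessly via [read_ranking()].
#'
#' @param result a `"ranking_result"`.
#' @param path output file.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path, format = NULL) {
  df <- as.data.frame(result)[c("alternative", "S_l", "S_m", "S_u",
                                "score", "rank")]
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a ranking result written by [write_ranking()]
#'
#' @param path CSV or JSON file.
#' @return a `"ranking_result"`.
#' @export
read_ranking <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("alternative", "S_l", "S_m", "S_u", "score", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ranking file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$rank <- as.integer(df$rank)
  class(df) <- c("ranking_result", "data.frame")
  df
}

#' Run configuration
#'
#' Bundles the knobs of a pipeline run.  All enumerations are validated
#' against their closed sets; the configuration is embedded in every output
#' manifest so a run can be reproduced exactly.
#'
#' @param variant `"ze"` (consensus-aware) or `"z"`.
#' @param defuzzifier `"centroid"` or `"gmir"`.
#' @param normalization `"minmax"` or `"max"`.
#' @param n_starts,seed,tolerance BWM solver budget.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(variant = c("ze", "z"),
                       defuzzifier = c("centroid", "gmir"),
                       normalization = c("minmax", "max"),
                       n_starts = 32, seed = 1, tolerance = 1e-8) {
  structure(list(variant = match.arg(variant),
                 defuzzifier = match.arg(defuzzifier),
                 normalization = match.arg(normalization),
                 n_starts = n_starts, seed = seed, tolerance = tolerance),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the defaults of
#' [run_config()].
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(run_config, x)
}

# manifest written next to every CLI output for byte-identical reruns
.write_manifest <- function(dir, config, inputs = character()) {
  checks <- vapply(inputs, function(f)
    as.character(tools::md5sum(f)), "")
  man <- list(package = "zefmea",
              version = as.character(utils::packageVersion("zefmea")),
              config = unclass(config),
              inputs = as.list(checks))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
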
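#' Linguistic scales
#'
#' A linguistic scale binds an ordered set of term labels (e.g. "VL" ...
#' "VH") to triangular fuzzy numbers, optionally carrying a per-term
#' consistency index (CI) as used by the Best--Worst Method.
#'
#' @param name scale identifier.
#' @param terms a data frame with columns `term`, `l`, `m`, `u` and
#'   optionally `ci` and `label`.
#' @return an object of class `"linguistic_scale"`.
#' @seealso [builtin_scales()], [term_tfn()], [read_scale()]
#' @export
linguistic_scale <- function(name, terms) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(terms))
  need <- c("term", "l", "m", "u")
  if (!all(need %in% names(terms)))
    stop("scale terms need columns term, l, m, u", call. = FALSE)
  if (anyDuplicated(terms$term))
    stop("duplicate term labels in scale '", name, "'", call. = FALSE)
  tfn(terms$l, terms$m, terms$u)  # validates every entry
  terms$term <- as.character(terms$term)
  structure(list(name = name, terms = terms), class = "linguistic_scale")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat(sprintf("Linguistic scale '%s' (%d terms)\n", x$name, nrow(x$terms)))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Look up the fuzzy value of linguistic terms
#'
#' @param scale a [linguistic_scale()].
#' @param term character vector of term labels.
#' @return a `tfn` of the same length as `term`.
#' @examples
#' term_tfn(builtin_scales()$reliability, "L")   # (0.1, 0.3, 0.5)
#' @export
term_tfn <- function(scale, term) {
  stopifnot(inherits(scale, "linguistic_scale"))
  i <- match(term, scale$terms$term)
  if (anyNA(i))
    stop(sprintf("unknown term '%s' on scale '%s'", term[which(is.na(i))[1]],
                 scale$name), call. = FALSE)
  tfn(scale$terms$l[i], scale$terms$m[i], scale$terms$u[i])
}

#' Consistency index of an importance term
#'
#' @param scale a [linguistic_scale()] whose terms carry a `ci` column.
#' @param term term label.
#' @return numeric consistency index.
#' @export
term_ci <- function(scale, term) {
  stopifnot(inherits(scale, "linguistic_scale"))
  if (is.null(scale$terms$ci))
    stop("scale '", scale$name, "' carries no consistency index", call. = FALSE)
  i <- match(term, scale$terms$term)
  if (anyNA(i))
    stop(sprintf("unknown term '%s' on scale '%s'", term[which(is.na(i))[1]],
                 scale$name), call. = FALSE)
  scale$terms$ci[i]
}

#' Built-in linguistic scales
#'
#' Returns the three scales the risk-assessment framework runs on:
#' \describe{
#'   \item{`importance`}{six terms EI/WI/FI/I/VI/AI for pairwise criteria
#'     comparison, each with a consistency index (EI: (1,1,1), CI 3.00, up
#'     to AI: (4.5,5,5.5), CI 9.35).}
#'   \item{`reliability`}{five terms VL/L/M/H/VH on `[0,1]` expressing the
#'     confidence attached to a rating (VL: (0,0,0.3) ... VH: (0.7,1,1)).}
#'   \item{`rating`}{seven terms VL/L/ML/M/MH/H/VH on the 0--10 severity/
#'     occurrence/detection axis (VL: (0,1,2) ... VH: (8,9,10)).}
#' }
#'
#' @return named list of three [linguistic_scale()] objects.
#' @export
builtin_scales <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "zefmea", mustWork = TRUE))
  list(importance  = linguistic_scale("importance",
                                      rd("scale_importance.csv")),
       reliability = linguistic_scale("reliability",
                                      rd("scale_reliability.csv")),
       rating      = linguistic_scale("rating", rd("scale_rating.csv")))
}

#' Read a linguistic scale from a YAML or JSON file
#'
#' Expected layout: `{name: ..., terms: [{label, l, m, u, ci?}, ...]}` where
#' `label` is the term label (`term` is accepted as a synonym).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a [linguistic_scale()].
#' @export
read_scale <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else stop("unsupported scale file format: ", path, call. = FALSE)
  if (is.null(x$name) || is.null(x$terms))
    stop("scale file needs 'name' and 'terms' entries", call. = FALSE)
  rows <- lapply(x$terms, function(t) {
    lab <- if (!is.null(t$label)) t$label else t$term
    if (is.null(lab) || is.null(t$l) || is.null(t$m) || is.null(t$u))
      stop("each scale term needs label, l, m, u", call. = FALSE)
    data.frame(term = lab, l = as.numeric(t$l), m = as.numeric(t$m),
               u = as.numeric(t$u),
               ci = if (is.null(t$ci)) NA_real_ else as.numeric(t$ci))
  })
  terms <- do.call(rbind, rows)
  if (all(is.na(terms$ci))) terms$ci <- NULL
  linguistic_scale(x$name, terms)
}
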
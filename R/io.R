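# Model-specification files (YAML/JSON), report documents, and rendering.

#' Read a model specification file
#'
#' The file (YAML or JSON, detected from the extension, falling back to
#' content sniffing) carries keys \code{name}, \code{states},
#' \code{inputs}, \code{outputs}, the matrices \code{A}, \code{B},
#' \code{C}, \code{D} as lists of rows of expression strings, and the
#' optional \code{true_values} (map) and \code{conditions} (list of
#' \code{x0}/\code{u0} entry lists, each entry a number, a symbol name, or
#' 0).
#'
#' @param path file path.
#' @return list with \code{model}, \code{conditions}, \code{true_values}.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model spec file not found: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  is_json <- grepl("\\.json$", path, ignore.case = TRUE) ||
    grepl("^\\s*\\{", txt)
  spec <- if (is_json) jsonlite::fromJSON(txt, simplifyVector = FALSE)
          else yaml::yaml.load(txt)
  for (key in c("A", "C"))
    if (is.null(spec[[key]]))
      stop(sprintf("model spec is missing matrix '%s'", key), call. = FALSE)
  getmat <- function(key) {
    m <- spec[[key]]
    if (is.null(m)) return(NULL)
    coerce_exprmat(m, key)
  }
  model <- linear_model(A = getmat("A"), B = getmat("B"),
                        C = getmat("C"), D = getmat("D"),
                        states = nullchr(spec$states),
                        inputs = nullchr(spec$inputs),
                        outputs = nullchr(spec$outputs),
                        parameters = nullchr(spec$parameters),
                        name = spec$name %||% "model")
  true_values <- numeric(0)
  if (!is.null(spec$true_values)) {
    true_values <- vapply(spec$true_values, as.numeric, numeric(1))
    missing <- setdiff(names(true_values), model$parameters)
    if (length(missing))
      stop(sprintf("true_values name unknown parameters: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  conditions <- list()
  if (!is.null(spec$conditions)) {
    conditions <- lapply(spec$conditions, function(cd) {
      cond <- experiment(x0 = lapply(cd$x0, spec_entry),
                         u0 = if (is.null(cd$u0)) NULL else lapply(cd$u0, spec_entry))
      validate_condition(model, cond)
    })
    if (!is.null(names(spec$conditions))) names(conditions) <- names(spec$conditions)
  }
  list(model = model, conditions = conditions, true_values = true_values)
}

nullchr <- function(x) if (is.null(x)) NULL else unname(vapply(x, as.character, character(1)))

spec_entry <- function(e) {
  if (is.numeric(e)) return(e)
  norm_entry(as.character(e))
}

#' Write a model specification file
#'
#' Inverse of \code{\link{read_model_spec}}: serializes the model (matrix
#' entries as canonical expression strings), plus optional true values and
#' conditions, as YAML or JSON chosen from the file extension.
#'
#' @param model a \code{linear_model}.
#' @param path output path (\code{.yaml}, \code{.yml} or \code{.json}).
#' @param true_values optional named numeric vector.
#' @param conditions optional named list of \code{experiment} objects.
#' @export
write_model_spec <- function(model, path, true_values = NULL,
                             conditions = NULL) {
  matlist <- function(sm) {
    d <- dim(sm)
    lapply(seq_len(d[1]), function(i)
      lapply(seq_len(d[2]), function(j) rf_to_string(sm_get(sm, i, j))))
  }
  spec <- list(name = model$name,
               states = as.list(model$states),
               inputs = as.list(model$inputs),
               outputs = as.list(model$outputs),
               parameters = as.list(model$parameters),
               A = matlist(model$A), B = matlist(model$B),
               C = matlist(model$C), D = matlist(model$D))
  if (length(true_values)) spec$true_values <- as.list(true_values)
  if (length(conditions)) {
    spec$conditions <- lapply(conditions, function(cd) {
      cd <- validate_condition(model, cd)
      list(x0 = cd$x0, u0 = cd$u0)
    })
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

# ------------------------------------------------------------------------

#' Assemble a serializable report document
#'
#' Flattens an \code{identifiability} object into a named list of plain
#' values (strings and numbers) with a stable field order, suitable for
#' JSON serialization or text rendering.
#'
#' @param report an \code{identifiability} object.
#' @param verification optional free-form list appended under
#'   \code{verification} (e.g. refit-scan summaries).
#' @return named list of class \code{"report_document"}.
#' @export
as_report_document <- function(report, verification = NULL) {
  stopifnot(inherits(report, "identifiability"))
  fmt_cond <- function(cond) {
    ent <- function(e) if (is.numeric(e)) as.character(e) else e
    paste0("x0=(", paste(vapply(cond$x0, ent, character(1)), collapse = ", "),
           "); u0=(", paste(vapply(cond$u0, ent, character(1)), collapse = ", "), ")")
  }
  doc <- list(
    model = report$model_name,
    condition = fmt_cond(report$condition),
    input_mode = report$input_mode,
    parameters = report$parameters,
    status = as.list(report$status),
    groups = lapply(report$groups, identity),
    group_class = as.list(report$group_class),
    basis = lapply(report$basis, function(v) as.list(v$strings)),
    combinations = vapply(report$combinations, `[[`, character(1), "expression"),
    n_max = report$n_max,
    equations_per_dataset = report$equations_per_dataset,
    independent_rows = report$independent_rows,
    n_d = report$n_d,
    datasets_for_unique_fit = datasets_for_unique_fit(report))
  if (!is.null(verification)) doc$verification <- verification
  structure(doc, class = c("report_document", "list"))
}

# "how many datasets for a unique fit": 1 when nothing is correlated, the
# remedy count n_d when the correlation is practical, NA (no finite number)
# when a structural correlation persists
datasets_for_unique_fit <- function(report) {
  if (!length(report$groups)) return(1L)
  if (any(report$group_class == "practical")) return(max(1L, report$n_d))
  NA_integer_
}

#' Write an identifiability report to disk
#'
#' @param report an \code{identifiability} object or a
#'   \code{report_document}.
#' @param path output file.
#' @param format \code{"json"} (stable field order) or \code{"text"}.
#' @param verification see \code{\link{as_report_document}}.
#' @export
write_report <- function(report, path, format = c("json", "text"),
                         verification = NULL) {
  format <- match.arg(format)
  doc <- if (inherits(report, "report_document")) report
         else as_report_document(report, verification)
  if (format == "json") {
    jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    writeLines(render_report_text(doc), path)
  }
  invisible(path)
}

render_report_text <- function(doc) {
  out <- c(sprintf("Identifiability report for '%s'", doc$model),
           sprintf("condition: %s", doc$condition),
           sprintf("input mode: %s", doc$input_mode),
           "",
           "parameter status:")
  for (p in names(doc$status))
    out <- c(out, sprintf("  %-10s %s", p, doc$status[[p]]))
  if (length(doc$groups)) {
    out <- c(out, "", "correlated groups:")
    for (g in seq_along(doc$groups))
      out <- c(out, sprintf("  {%s}  [%s]",
                            paste(doc$groups[[g]], collapse = ", "),
                            doc$group_class[[g]]))
    out <- c(out, "", "nullspace basis (entries in parameter order):")
    for (v in doc$basis)
      out <- c(out, paste0("  (", paste(unlist(v), collapse = ", "), ")"))
  }
  if (length(doc$combinations)) {
    out <- c(out, "", "identifiable combinations:")
    for (cmb in doc$combinations) out <- c(out, paste0("  ", cmb))
  }
  c(out, "",
    sprintf("n_max = %d, equations per dataset = %d (observed independent rows: %d)",
            doc$n_max, doc$equations_per_dataset, doc$independent_rows),
    sprintf("n_d (datasets to remedy practical non-identifiability) = %d", doc$n_d),
    sprintf("datasets for a unique fit: %s",
            ifelse(is.na(doc$datasets_for_unique_fit), "none (structural)",
                   doc$datasets_for_unique_fit)))
}

#' @export
print.report_document <- function(x, ...) {
  cat(paste(render_report_text(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.identifiability <- function(x, ...) {
  print(as_report_document(x))
  invisible(x)
}

#' @export
summary.identifiability <- function(object, ...) {
  n_ident <- sum(object$status == "identifiable")
  cat(sprintf("Model '%s': %d of %d parameters identifiable under the analyzed condition\n",
              object$model_name, n_ident, length(object$parameters)))
  if (length(object$groups)) {
    for (g in seq_along(object$groups))
      cat(sprintf("  group %d (%s): {%s}\n", g, object$group_class[g],
                  paste(object$groups[[g]], collapse = ", ")))
    cat(sprintf("  n_max = %d, equations/dataset = %d, n_d = %d\n",
                object$n_max, object$equations_per_dataset, object$n_d))
    if (length(object$combinations))
      cat("  identifiable combinations:",
          paste(vapply(object$combinations, `[[`, character(1), "expression"),
                collapse = ";  "), "\n")
  } else {
    cat("  no parameter correlations: one dataset suffices for unique estimation\n")
  }
  invisible(object)
}
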
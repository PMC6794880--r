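#' Parse a decimal number in point or comma notation
#'
#' Elicitation tables in European clinical reports frequently use decimal
#' commas ("0,266", "1,4"); readers in this package accept both dialects and
#' normalize to decimal points. Grouping (thousands) separators are rejected
#' as ambiguous.
#'
#' @param text Character vector of numbers.
#' @return Numeric vector.
#' @examples
#' parse_number(c("1,4", "2.5", "3"))
#' @export
parse_number <- function(text) {
  text <- trimws(as.character(text))
  ok <- grepl("^[+-]?[0-9]+([.,][0-9]+)?$", text)
  if (any(!ok))
    stop("cannot parse number(s): ", paste(text[!ok], collapse = ", "),
         " (grouping separators are unsupported)", call. = FALSE)
  as.numeric(gsub(",", ".", text, fixed = TRUE))
}

#' Read an expert panel from CSV, YAML or JSON
#'
#' CSV: columns \code{expert_id}, \code{order} (leaf ids joined by
#' semicolons) and \code{ratios} (decimals joined by semicolons, comma or
#' point decimals). YAML/JSON: a list of records with the same fields as
#' lists.
#'
#' @param path File path; format chosen by extension (\code{.csv},
#'   \code{.yaml}/\code{.yml}, \code{.json}).
#' @return List of \code{expert_judgement}s.
#' @export
read_panel <- function(path) {
  recs <- switch(file_ext(path),
    csv = {
      d <- utils::read.csv(path, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(d)), function(i)
        list(expert_id = d$expert_id[i],
             order = strsplit(as.character(d$order[i]), ";", fixed = TRUE)[[1L]],
             ratios = strsplit(as.character(d$ratios[i]), ";", fixed = TRUE)[[1L]]))
    },
    yaml = yaml::read_yaml(path),
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported panel format: ", path, call. = FALSE))
  lapply(recs, function(r)
    expert_judgement(r$expert_id, trimws(unlist(r$order)),
                     parse_number(unlist(r$ratios))))
}

#' Write an expert panel
#'
#' Inverse of [read_panel()]; round trips are lossless.
#'
#' @param panel List of \code{expert_judgement}s.
#' @param path Output path (\code{.csv}, \code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  recs <- lapply(panel, function(j)
    list(expert_id = j$expert_id, order = as.list(j$order),
         ratios = as.list(j$ratios)))
  switch(file_ext(path),
    csv = utils::write.csv(data.frame(
      expert_id = vapply(panel, `[[`, "", "expert_id"),
      order = vapply(panel, function(j) paste(j$order, collapse = ";"), ""),
      ratios = vapply(panel, function(j)
        paste(format(j$ratios, trim = TRUE, digits = 15), collapse = ";"), ""),
      stringsAsFactors = FALSE), path, row.names = FALSE),
    yaml = yaml::write_yaml(recs, path),
    yml = yaml::write_yaml(recs, path),
    json = jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported panel format: ", path, call. = FALSE))
  invisible(path)
}

#' Read a decision matrix from CSV
#'
#' First column: alternative labels; header row: criterion (leaf) ids.
#' Decimal commas are accepted in cells.
#'
#' @param path CSV path.
#' @return A \code{decision_matrix}.
#' @export
read_decision_matrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character")
  vals <- vapply(d[-1L], parse_number, numeric(nrow(d)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(d))
  decision_matrix(vals, alternatives = d[[1L]], criteria = names(d)[-1L])
}

#' Write a decision matrix to CSV
#'
#' @param D A \code{decision_matrix}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_decision_matrix <- function(D, path) {
  d <- data.frame(alternative = rownames(D), unclass(D),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a TOPSIS audit bundle as JSON
#'
#' Full-precision dump of every intermediate quantity (normalized and
#' weighted matrices, ideals, separations, closeness, ranks) plus the
#' convention header, so any reported number can be reproduced from the
#' bundle alone.
#'
#' @param res A \code{topsis_result}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_audit_bundle <- function(res, path) {
  stopifnot(inherits(res, "topsis_result"))
  jsonlite::write_json(list(
    convention = res$convention,
    weights = as.list(res$weights),
    decision = matrix_records(res$decision),
    normalized = matrix_records(res$normalized),
    weighted = matrix_records(res$weighted),
    ideal_positive = as.list(res$ideals$positive),
    ideal_negative = as.list(res$ideals$negative),
    scores = res$scores), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

matrix_records <- function(m) {
  m <- as.matrix(m)
  stats::setNames(lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])),
                  rownames(m))
}

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

# structured config (hierarchy, run config): YAML or JSON by extension
read_structured <- function(path) {
  switch(file_ext(path),
    yaml = yaml::read_yaml(path),
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported structured format: ", path, call. = FALSE))
}
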
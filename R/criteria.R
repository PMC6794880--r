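#' Build a two-level criteria hierarchy
#'
#' A criteria hierarchy has exactly two levels: main criteria (e.g. convenience,
#' pain, risk) and leaf sub-criteria (e.g. general medical condition, stage of
#' cancer). All weighting and ranking operates on the leaves; the leaf order
#' given here is the canonical column order for every downstream weight vector
#' and decision matrix.
#'
#' @param spec A list with components \code{main} and \code{leaves}, or a path
#'   to a YAML or JSON file with the same structure. \code{main} is a list of
#'   records with \code{id} and optional \code{label}; \code{leaves} is a list
#'   of records with \code{id}, \code{parent}, and optional \code{label},
#'   \code{direction} (\code{"benefit"} or \code{"cost"}; default
#'   \code{"benefit"}) and \code{scale} (named label-to-level map).
#' @return An object of class \code{criteria_hierarchy}: a list with
#'   data frames \code{main} (\code{id}, \code{label}) and \code{leaves}
#'   (\code{id}, \code{label}, \code{parent}, \code{direction}) plus a named
#'   list \code{scales} of per-leaf scale encodings.
#' @details Score levels used on leaf scales are restricted to
#'   \{1, 1.5, 2, 2.5, 3\}; half levels arise when integer expert scores are
#'   averaged. Scales default to benefit orientation: the hierarchy is usually
#'   encoded so that level 3 is the favourable pole of every leaf, but the
#'   direction can be set per leaf for experiments.
#' @examples
#' h <- build_hierarchy(list(
#'   main = list(list(id = "C1", label = "Convenience")),
#'   leaves = list(
#'     list(id = "C11", parent = "C1", label = "General medical condition"),
#'     list(id = "C12", parent = "C1", label = "Stage of cancer")
#'   )
#' ))
#' leaf_criteria(h)$id
#' @seealso [leaf_criteria()], [pain_case_study()] for the built-in
#'   eleven-leaf hierarchy.
#' @export
build_hierarchy <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) spec <- read_structured(spec)
  if (!is.list(spec) || is.null(spec$main) || is.null(spec$leaves))
    stop("hierarchy spec must be a list with components 'main' and 'leaves'",
         call. = FALSE)

  main <- do.call(rbind, lapply(spec$main, function(m) {
    data.frame(id = as.character(m$id),
               label = as.character(m$label %||% m$id),
               stringsAsFactors = FALSE)
  }))
  leaves <- do.call(rbind, lapply(spec$leaves, function(l) {
    data.frame(id = as.character(l$id),
               label = as.character(l$label %||% l$id),
               parent = as.character(l$parent %||% ""),
               direction = match.arg(as.character(l$direction %||% "benefit"),
                                     c("benefit", "cost")),
               stringsAsFactors = FALSE)
  }))
  scales <- lapply(spec$leaves, function(l) {
    if (is.null(l$scale)) return(NULL)
    s <- unlist(l$scale)
    storage.mode(s) <- "double"
    s
  })
  names(scales) <- leaves$id
  scales <- scales[!vapply(scales, is.null, logical(1))]

  if (nrow(main) < 1L) stop("at least one main criterion required", call. = FALSE)
  if (nrow(leaves) < 2L)
    stop("at least two leaf criteria required (ranking is degenerate with one)",
         call. = FALSE)
  ids <- c(main$id, leaves$id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate criterion id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  orphan <- setdiff(leaves$parent, main$id)
  if (length(orphan) || any(leaves$parent == ""))
    stop("leaf criteria with missing/unknown parent: ",
         paste(leaves$id[leaves$parent %in% c(orphan, "")], collapse = ", "),
         call. = FALSE)
  bad_scale <- names(scales)[vapply(
    scales, function(s) !all(s %in% c(1, 1.5, 2, 2.5, 3)), logical(1))]
  if (length(bad_scale))
    stop("scale levels outside {1, 1.5, 2, 2.5, 3} for: ",
         paste(bad_scale, collapse = ", "), call. = FALSE)

  structure(list(main = main, leaves = leaves, scales = scales),
            class = "criteria_hierarchy")
}

#' Leaf sub-criteria in canonical order
#'
#' @param h A \code{criteria_hierarchy}.
#' @return The \code{leaves} data frame (\code{id}, \code{label},
#'   \code{parent}, \code{direction}) in canonical column order.
#' @export
leaf_criteria <- function(h) {
  stopifnot(inherits(h, "criteria_hierarchy"))
  h$leaves
}

#' @export
print.criteria_hierarchy <- function(x, ...) {
  cat("Criteria hierarchy:", nrow(x$main), "main criteria,",
      nrow(x$leaves), "sub-criteria\n")
  for (m in x$main$id) {
    lab <- x$main$label[x$main$id == m]
    cat(sprintf("  %s %s\n", m, if (lab != m) lab else ""))
    kids <- x$leaves[x$leaves$parent == m, ]
    for (i in seq_len(nrow(kids)))
      cat(sprintf("    %s %s [%s]\n", kids$id[i],
                  if (kids$label[i] != kids$id[i]) kids$label[i] else "",
                  kids$direction[i]))
  }
  invisible(x)
}

# directions named by leaf id, recycled from a scalar if needed
leaf_directions <- function(h) {
  stats::setNames(h$leaves$direction, h$leaves$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
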
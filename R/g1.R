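#' The admissible importance-ratio grid
#'
#' Verbal elicitation scale for the adjacent importance ratio r_j between a
#' criterion and the one ranked immediately above it: 1.0 means the two are
#' equally important, 1.2 slightly more, 1.4 more, 1.6 strongly more, and 1.8
#' extremely more important, with the odd tenths as intermediate grades.
#'
#' @return Named numeric vector of the nine admissible ratio values.
#' @export
importance_scale <- function() {
  stats::setNames(seq(1.0, 1.8, by = 0.1),
                  c("equal", "equal/slight", "slight", "slight/more", "more",
                    "more/strong", "strong", "strong/extreme", "extreme"))
}

#' Construct an expert judgement
#'
#' One expert's input to the G1 order-relation method: a strict importance
#' ordering of all leaf criteria (most important first) and the n-1 adjacent
#' ratios r_2..r_n, where r_j is the weight of the criterion in position j-1
#' divided by the weight of the criterion in position j.
#'
#' @param expert_id Label for the expert (e.g. \code{"PP#1"}).
#' @param order Character vector of leaf ids, most to least important.
#' @param ratios Numeric vector of length \code{length(order) - 1}, each >= 1.
#' @return An object of class \code{expert_judgement}.
#' @export
expert_judgement <- function(expert_id, order, ratios) {
  j <- structure(list(expert_id = as.character(expert_id),
                      order = as.character(order),
                      ratios = as.numeric(ratios)),
                 class = "expert_judgement")
  if (length(j$order) < 2L)
    stop("an expert judgement needs at least two criteria", call. = FALSE)
  if (length(j$ratios) != length(j$order) - 1L)
    stop("need exactly ", length(j$order) - 1L, " ratios for ",
         length(j$order), " criteria, got ", length(j$ratios), call. = FALSE)
  j
}

#' @export
print.expert_judgement <- function(x, ...) {
  cat(sprintf("Expert %s: %s\n", x$expert_id,
              paste(x$order, collapse = " > ")))
  cat("  ratios:", paste(format(x$ratios), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an expert judgement against a hierarchy
#'
#' Checks that the stated ordering is a permutation of the hierarchy's leaf
#' ids, that every ratio is >= 1, and (optionally) that every ratio lies on
#' the nine-point elicitation grid.
#'
#' @param j An \code{expert_judgement}.
#' @param h A \code{criteria_hierarchy}, or a character vector of leaf ids.
#' @param strict_grid If \code{TRUE}, off-grid ratios are violations rather
#'   than merely unusual.
#' @return A data frame with columns \code{check} and \code{message}; zero
#'   rows iff the judgement is valid.
#' @export
validate_judgement <- function(j, h, strict_grid = FALSE) {
  stopifnot(inherits(j, "expert_judgement"))
  ids <- if (inherits(h, "criteria_hierarchy")) h$leaves$id else as.character(h)
  v <- list()
  add <- function(check, msg) v[[length(v) + 1L]] <<-
    data.frame(check = check, message = msg, stringsAsFactors = FALSE)

  if (length(j$order) != length(ids) || !setequal(j$order, ids) ||
      anyDuplicated(j$order)) {
    missing <- setdiff(ids, j$order)
    extra <- setdiff(j$order, ids)
    dup <- unique(j$order[duplicated(j$order)])
    add("permutation", paste0(
      "order is not a permutation of the leaf ids",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ",")),
      if (length(dup)) paste0("; duplicated: ", paste(dup, collapse = ","))))
  }
  if (length(j$ratios) != length(j$order) - 1L)
    add("ratio_count", sprintf("expected %d ratios, got %d",
                               length(j$order) - 1L, length(j$ratios)))
  bad <- which(!is.finite(j$ratios) | j$ratios < 1)
  if (length(bad))
    add("ratio_bound", paste0("ratio < 1 (or non-finite) at position(s) ",
                              paste(bad + 1L, collapse = ",")))
  off <- which(is.finite(j$ratios) &
                 !vapply(j$ratios, function(r)
                   any(abs(r - importance_scale()) < 1e-9), logical(1)))
  if (length(off) && strict_grid)
    add("ratio_grid", paste0("ratio off the {1.0..1.8 by 0.1} grid at position(s) ",
                             paste(off + 1L, collapse = ",")))
  if (length(v)) do.call(rbind, v)
  else data.frame(check = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' G1 order-relation weights for one expert
#'
#' Converts a strict importance ordering plus adjacent importance ratios into
#' a normalized weight vector. With criteria ranked w_(1) >= ... >= w_(n) and
#' r_j = w_(j-1)/w_(j), the last-ranked weight is
#' \deqn{w_{(n)} = \left[1 + \sum_{i=2}^{n} \prod_{k=i}^{n} r_k\right]^{-1}}
#' and each earlier position follows the recursion w_(j-1) = r_j w_(j). This
#' is the tail-product form; it is equivalent to assigning the last-ranked
#' criterion an unnormalized weight of 1, back-multiplying by the ratios, and
#' normalizing to sum 1.
#'
#' @param j An \code{expert_judgement}.
#' @param h Optional \code{criteria_hierarchy} or character vector of leaf ids
#'   giving the canonical output order (and enabling full validation). When
#'   omitted, the expert's own ordering is used as canonical order.
#' @param strict_grid Passed to [validate_judgement()]; if \code{TRUE},
#'   off-grid ratios are an error, otherwise they only trigger a warning.
#' @param warn_off_grid Set \code{FALSE} to silence the off-grid warning, e.g.
#'   for judgements carrying exact (unquantized) ratios from a latent weight
#'   vector.
#' @return Named numeric weight vector in canonical leaf order; positive,
#'   summing to 1.
#' @examples
#' j <- expert_judgement("E1", c("A", "B"), 1.8)
#' g1_weight_vector(j)  # (1.8, 1) / 2.8
#' @export
g1_weight_vector <- function(j, h = NULL, strict_grid = FALSE,
                             warn_off_grid = TRUE) {
  stopifnot(inherits(j, "expert_judgement"))
  ids <- if (is.null(h)) j$order
         else if (inherits(h, "criteria_hierarchy")) h$leaves$id
         else as.character(h)
  rep_ <- validate_judgement(j, ids, strict_grid = strict_grid)
  if (nrow(rep_))
    stop("invalid judgement for expert ", j$expert_id, ":\n  ",
         paste(rep_$message, collapse = "\n  "), call. = FALSE)
  off <- !vapply(j$ratios, function(r)
    any(abs(r - importance_scale()) < 1e-9), logical(1))
  if (any(off) && !strict_grid && warn_off_grid)
    warning("ratio(s) off the elicitation grid for expert ", j$expert_id, ": ",
            paste(j$ratios[off], collapse = ", "), call. = FALSE)

  n <- length(j$order)
  # unnormalized weights by position: tail = 1, back-multiplied by the ratios
  u <- rev(cumprod(c(1, rev(j$ratios))))
  w <- stats::setNames(u / sum(u), j$order)
  w[ids]
}

#' Aggregate a panel of weight vectors
#'
#' Component-wise arithmetic mean of per-expert weight vectors over a common
#' leaf set. The mean of vectors that each sum to 1 again sums to 1.
#'
#' @param panel Non-empty list of named weight vectors indexed by the same
#'   leaf ids.
#' @param method Aggregation rule; only \code{"arithmetic_mean"} is available.
#' @return Named numeric weight vector in the leaf order of the first panel
#'   member.
#' @export
aggregate_weight_vectors <- function(panel, method = "arithmetic_mean") {
  method <- match.arg(method, "arithmetic_mean")
  if (!is.list(panel) || length(panel) == 0L)
    stop("panel must be a non-empty list of weight vectors", call. = FALSE)
  ids <- names(panel[[1L]])
  for (k in seq_along(panel)) {
    w <- panel[[k]]
    if (is.null(names(w)) || !setequal(names(w), ids)) {
      diff <- union(setdiff(ids, names(w)), setdiff(names(w), ids))
      stop("weight vector ", k, " indexes a different leaf set; ",
           "symmetric difference: ", paste(diff, collapse = ", "),
           call. = FALSE)
    }
  }
  rowMeans(vapply(panel, function(w) w[ids], numeric(length(ids))))
}
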
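#' Construct a decision matrix
#'
#' Performance scores of m alternatives (rows) against n criteria (columns).
#' All scores must be finite and non-negative; in the clinical scoring scheme
#' used by the case study they lie on the levels \{1, 1.5, 2, 2.5, 3\}.
#'
#' @param values Numeric matrix (or object coercible to one), m x n.
#' @param alternatives Optional row labels; default \code{Alt1..Altm}.
#' @param criteria Optional column labels (canonical leaf ids).
#' @return A numeric matrix of class \code{decision_matrix} with dimnames set.
#' @export
decision_matrix <- function(values, alternatives = NULL, criteria = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least two alternatives", call. = FALSE)
  if (ncol(m) < 1L) stop("need at least one criterion", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop("decision matrix has missing or non-finite cells", call. = FALSE)
  if (any(m < 0)) stop("decision matrix scores must be >= 0", call. = FALSE)
  rownames(m) <- alternatives %||% rownames(values) %||%
    paste0("Alt", seq_len(nrow(m)))
  colnames(m) <- criteria %||% colnames(values) %||%
    paste0("F", seq_len(ncol(m)))
  class(m) <- c("decision_matrix", class(m))
  m
}

#' Normalize a decision matrix
#'
#' Vector (Euclidean) normalization. The standard form, \code{vector_column},
#' divides each column by its Euclidean norm over the alternatives, so every
#' non-zero column of the result has unit norm. \code{vector_row} divides each
#' row by its norm over the criteria instead; it is provided only for
#' reproduction experiments with nonstandard conventions and is not the
#' default anywhere in the package.
#'
#' @param D A \code{decision_matrix} (or plain numeric matrix).
#' @param method \code{"vector_column"} (default) or \code{"vector_row"}.
#' @return Normalized matrix with attribute \code{normalization} set.
#' @export
normalize_matrix <- function(D, method = c("vector_column", "vector_row")) {
  method <- match.arg(method)
  D <- unclass(as.matrix(D))
  if (method == "vector_column") {
    nrm <- sqrt(colSums(D^2))
    zero <- which(nrm == 0)
    if (length(zero))
      stop("zero-norm column(s): ",
           paste(colnames(D)[zero] %||% zero, collapse = ", "), call. = FALSE)
    R <- sweep(D, 2L, nrm, "/")
  } else {
    nrm <- sqrt(rowSums(D^2))
    zero <- which(nrm == 0)
    if (length(zero))
      stop("zero-norm row(s): ",
           paste(rownames(D)[zero] %||% zero, collapse = ", "), call. = FALSE)
    R <- sweep(D, 1L, nrm, "/")
  }
  attr(R, "normalization") <- method
  R
}

#' Weight a normalized matrix
#'
#' @param N Normalized matrix from [normalize_matrix()].
#' @param w Named weight vector covering every column of \code{N} (extra names
#'   are an error), or an unnamed vector of matching length.
#' @return Weighted normalized matrix v_ij = w_j r_ij.
#' @export
apply_weights <- function(N, w) {
  N <- as.matrix(N)
  if (!is.null(names(w))) {
    missing <- setdiff(colnames(N), names(w))
    if (length(missing))
      stop("no weight for column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    w <- w[colnames(N)]
  } else if (length(w) != ncol(N)) {
    stop("unnamed weight vector must have length ncol(N)", call. = FALSE)
  }
  sweep(N, 2L, as.numeric(w), "*")
}

#' Positive and negative ideal solutions
#'
#' For benefit criteria the positive ideal takes the column maximum and the
#' negative ideal the minimum; cost criteria are mirrored.
#'
#' @param W Weighted normalized matrix.
#' @param directions Per-column \code{"benefit"}/\code{"cost"} flags: a single
#'   value recycled to all columns, or a (named) vector covering every column.
#' @return List with numeric vectors \code{positive}, \code{negative} and the
#'   expanded \code{directions}.
#' @export
ideal_solutions <- function(W, directions = "benefit") {
  W <- as.matrix(W)
  dirs <- expand_directions(directions, W)
  hi <- apply(W, 2L, max)
  lo <- apply(W, 2L, min)
  pos <- ifelse(dirs == "benefit", hi, lo)
  neg <- ifelse(dirs == "benefit", lo, hi)
  list(positive = stats::setNames(pos, colnames(W)),
       negative = stats::setNames(neg, colnames(W)),
       directions = dirs)
}

expand_directions <- function(directions, W) {
  n <- ncol(W)
  if (length(directions) == 1L && is.null(names(directions)))
    directions <- rep(directions, n)
  if (!is.null(names(directions))) {
    missing <- setdiff(colnames(W), names(directions))
    if (length(missing))
      stop("no direction for column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    directions <- directions[colnames(W)]
  } else if (length(directions) != n) {
    stop("directions must be length 1 or ncol(W)", call. = FALSE)
  }
  dirs <- vapply(directions, match.arg, "", choices = c("benefit", "cost"))
  stats::setNames(dirs, colnames(W))
}

#' Euclidean separation from the ideal solutions
#'
#' @param W Weighted normalized matrix.
#' @param ideals Result of [ideal_solutions()].
#' @return Data frame with per-alternative distances \code{d_pos} (to the
#'   positive ideal) and \code{d_neg} (to the negative ideal).
#' @export
separations <- function(W, ideals) {
  W <- as.matrix(W)
  stopifnot(length(ideals$positive) == ncol(W))
  data.frame(
    alternative = rownames(W) %||% paste0("Alt", seq_len(nrow(W))),
    d_pos = sqrt(rowSums(sweep(W, 2L, ideals$positive)^2)),
    d_neg = sqrt(rowSums(sweep(W, 2L, ideals$negative)^2)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Closeness coefficients and ranks
#'
#' The relative closeness is C_i = d_neg / (d_pos + d_neg), in [0, 1], larger
#' is better. Rank 1 goes to the largest closeness; exact ties (within 1e-12
#' absolute) share the better rank (competition ranking, "1224"), stably in
#' input order. The degenerate case d_pos + d_neg = 0 (all alternatives
#' identical on every criterion) is defined as closeness 0.5.
#'
#' @param S Separations data frame from [separations()].
#' @return Data frame \code{alternative}, \code{d_pos}, \code{d_neg},
#'   \code{closeness}, \code{rank}.
#' @export
closeness_and_rank <- function(S) {
  tot <- S$d_pos + S$d_neg
  cc <- ifelse(tot == 0, 0.5, S$d_neg / ifelse(tot == 0, 1, tot))
  S$closeness <- cc
  S$rank <- competition_rank(cc, tol = 1e-12)
  S
}

# rank 1 = largest; values within tol are tied and share the better rank
competition_rank <- function(x, tol = 1e-12) {
  vapply(seq_along(x), function(i) 1L + sum(x > x[i] + tol), integer(1))
}

#' Run the full TOPSIS pipeline
#'
#' Composition of [normalize_matrix()], [apply_weights()],
#' [ideal_solutions()], [separations()] and [closeness_and_rank()]. The
#' result keeps every intermediate matrix for audit.
#'
#' @param D A \code{decision_matrix}.
#' @param w Weight vector (named by columns, or unnamed of matching length);
#'   default uniform. Closeness is invariant to scaling \code{w} by any
#'   positive constant.
#' @param directions Per-column benefit/cost flags (see [ideal_solutions()]).
#' @param normalization Passed to [normalize_matrix()].
#' @return Object of class \code{topsis_result}: list with \code{decision},
#'   \code{normalized}, \code{weighted}, \code{weights}, \code{ideals},
#'   \code{scores} (the closeness/rank table) and \code{convention}.
#' @examples
#' D <- decision_matrix(rbind(c(3, 1), c(1, 3), c(2, 2)))
#' run_topsis(D)$scores
#' @export
run_topsis <- function(D, w = NULL,
                       directions = "benefit",
                       normalization = c("vector_column", "vector_row")) {
  normalization <- match.arg(normalization)
  D <- if (inherits(D, "decision_matrix")) D else decision_matrix(D)
  if (is.null(w)) w <- stats::setNames(rep(1 / ncol(D), ncol(D)), colnames(D))
  N <- normalize_matrix(D, normalization)
  V <- apply_weights(N, w)
  ideals <- ideal_solutions(V, directions)
  S <- separations(V, ideals)
  structure(list(
    decision = D, normalized = N, weighted = V,
    weights = if (is.null(names(w))) stats::setNames(as.numeric(w), colnames(D)) else w[colnames(D)],
    ideals = ideals,
    scores = closeness_and_rank(S),
    convention = list(normalization = normalization,
                      directions = ideals$directions)),
    class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, digits = 3, ...) {
  cat(sprintf("TOPSIS ranking (%s normalization; %d benefit / %d cost columns)\n",
              x$convention$normalization,
              sum(x$convention$directions == "benefit"),
              sum(x$convention$directions == "cost")))
  s <- x$scores
  s$d_pos <- round(s$d_pos, digits)
  s$d_neg <- round(s$d_neg, digits)
  s$closeness <- round(s$closeness, digits)
  print(s[order(s$rank), ], row.names = FALSE)
  invisible(x)
}
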
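#' Sample a latent weight vector compatible with the elicitation grid
#'
#' Rejection-samples a positive, normalized weight vector whose adjacent
#' ratios in descending order are all at most \code{max_ratio}, so that an
#' expert ranking the criteria by these weights could express every adjacent
#' comparison on the bounded importance scale. Used as ground truth in
#' parameter-recovery tests.
#'
#' @param n Number of criteria (>= 2).
#' @param max_ratio Upper bound on each sorted adjacent ratio (>= 1); the
#'   elicitation grid tops out at 1.8.
#' @param seed Integer seed; the draw is a pure function of
#'   (\code{n}, \code{max_ratio}, \code{seed}).
#' @param ids Criterion ids for the output; default \code{F01..Fnn}.
#' @param max_tries Rejection budget before giving up.
#' @return List of class \code{latent_weights}: \code{weights} (named, sums
#'   to 1, in \code{ids} order) and \code{sorted_ratios} (the n-1 adjacent
#'   ratios of the descending-sorted weights).
#' @export
gen_latent_weights <- function(n, max_ratio = 1.8, seed = 1L, ids = NULL,
                               max_tries = 10000L) {
  stopifnot(n >= 2)
  if (max_ratio < 1) stop("max_ratio must be >= 1", call. = FALSE)
  ids <- ids %||% sprintf("F%02d", seq_len(n))
  stopifnot(length(ids) == n)
  w <- withr::with_seed(as.integer(seed), {
    # build the sorted vector directly from admissible adjacent ratios, then
    # shuffle positions; every draw is admissible, so "rejection" only guards
    # degenerate numerical cases
    for (try_ in seq_len(max_tries)) {
      r <- stats::runif(n - 1L, 1, max_ratio)
      u <- rev(cumprod(c(1, rev(r))))
      cand <- u / sum(u)
      if (all(cand > 0) && all(ratio_of_sorted(cand) <= max_ratio + 1e-12)) {
        cand <- sample(cand)  # random assignment of weights to criteria
        break
      }
      cand <- NULL
    }
    cand
  })
  if (is.null(w))
    stop("rejection budget exceeded; try a larger max_ratio", call. = FALSE)
  structure(list(weights = stats::setNames(w, ids),
                 sorted_ratios = ratio_of_sorted(w)),
            class = "latent_weights")
}

ratio_of_sorted <- function(w) {
  s <- sort(w, decreasing = TRUE)
  s[-length(s)] / s[-1L]
}

#' Expert judgement implied by a latent weight vector
#'
#' Inverts the G1 construction: the ordering is the criteria sorted by
#' descending latent weight (stable in input order on ties) and the ratios
#' are the exact adjacent ratios of the sorted weights, optionally snapped to
#' the nearest point of the elicitation grid.
#'
#' @param lw A \code{latent_weights} object (or a named positive weight
#'   vector).
#' @param quantize If \code{TRUE}, each ratio is replaced by the nearest grid
#'   value in \{1.0, 1.1, ..., 1.8\}; ratios above 1.8 clamp to 1.8.
#' @param expert_id Label for the generated judgement.
#' @return An \code{expert_judgement}. Without quantization,
#'   \code{g1_weight_vector()} applied to the result recovers \code{lw}
#'   exactly (to numerical precision).
#' @export
judgement_from_weights <- function(lw, quantize = FALSE,
                                   expert_id = "synthetic") {
  w <- if (inherits(lw, "latent_weights")) lw$weights else lw
  stopifnot(!is.null(names(w)), all(w > 0))
  ord <- order(-w)
  r <- ratio_of_sorted(w)
  if (quantize) {
    grid <- seq(1.0, 1.8, by = 0.1)
    r <- vapply(r, function(x) grid[which.min(abs(grid - x))], numeric(1))
  }
  expert_judgement(expert_id, names(w)[ord], r)
}

#' Generate a synthetic expert panel
#'
#' Emulates the elicitation format of a multi-expert study: each expert
#' supplies a strict importance ordering and adjacent ratios. A shared base
#' ordering models panel consensus; with probability \code{concordance} an
#' expert takes the base ordering perturbed by at most \code{max_swaps}
#' adjacent transpositions (experts typically agree on the top criteria and
#' diverge lower down), otherwise an independent uniform permutation.
#'
#' @param n_criteria Number of criteria (>= 2).
#' @param n_experts Number of experts (>= 1).
#' @param ratio_mode \code{"grid"}: ratios drawn uniformly from the
#'   elicitation grid; \code{"exact"}: each expert's ratios derived exactly
#'   from an expert-specific latent weight vector (off-grid reals).
#' @param concordance Probability in [0, 1] that an expert follows the base
#'   ordering (with swaps) rather than an independent permutation.
#' @param max_swaps Maximum adjacent swaps applied to the base ordering.
#' @param seed Integer seed; the panel is a pure function of the spec.
#' @param ids Criterion ids; default \code{F01..}.
#' @return List of \code{expert_judgement}s labelled \code{E1..}.
#' @export
gen_panel <- function(n_criteria, n_experts, ratio_mode = c("grid", "exact"),
                      concordance = 1, max_swaps = 2L, seed = 1L, ids = NULL) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(n_criteria >= 2, n_experts >= 1,
            concordance >= 0, concordance <= 1)
  ids <- ids %||% sprintf("F%02d", seq_len(n_criteria))
  grid <- seq(1.0, 1.8, by = 0.1)
  withr::with_seed(as.integer(seed), {
    base <- sample(ids)
    lapply(seq_len(n_experts), function(e) {
      if (stats::runif(1) <= concordance) {
        ord <- base
        for (s in seq_len(stats::rbinom(1, max_swaps, 0.5))) {
          k <- sample.int(n_criteria - 1L, 1L)
          ord[c(k, k + 1L)] <- ord[c(k + 1L, k)]
        }
      } else {
        ord <- sample(ids)
      }
      if (ratio_mode == "grid") {
        r <- sample(grid, n_criteria - 1L, replace = TRUE)
        expert_judgement(paste0("E", e), ord, r)
      } else {
        r <- stats::runif(n_criteria - 1L, 1, 1.8)
        expert_judgement(paste0("E", e), ord, r)
      }
    })
  })
}

#' Generate a synthetic score matrix
#'
#' Independent uniform draws over a discrete level set, emulating averaged
#' expert scores for alternatives against criteria.
#'
#' @param m Number of alternatives (>= 2).
#' @param n Number of criteria.
#' @param levels Non-empty subset of \{1, 1.5, 2, 2.5, 3\}.
#' @param seed Integer seed.
#' @param alternatives,criteria Optional dimnames.
#' @return A \code{decision_matrix}.
#' @export
gen_score_matrix <- function(m, n, levels = c(1, 1.5, 2, 2.5, 3), seed = 1L,
                             alternatives = NULL, criteria = NULL) {
  stopifnot(m >= 2, n >= 1)
  if (!length(levels) || !all(levels %in% c(1, 1.5, 2, 2.5, 3)))
    stop("levels must be a non-empty subset of {1, 1.5, 2, 2.5, 3}",
         call. = FALSE)
  vals <- withr::with_seed(as.integer(seed),
                           levels[sample.int(length(levels), m * n,
                                             replace = TRUE)])
  decision_matrix(matrix(vals, m, n), alternatives = alternatives,
                  criteria = criteria)
}
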
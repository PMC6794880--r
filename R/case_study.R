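#' Built-in chronic cancer pain case study
#'
#' The complete worked example shipped with the package: selection of an
#' interventional therapy for chronic pain in upper abdominal malignancy.
#' Four treatment alternatives — lumbar epidural catheter, spinal port,
#' celiac plexus block, and splanchnic nerve radiofrequency thermocoagulation
#' — are scored against eleven sub-criteria grouped under convenience, pain,
#' risk, duration and cost, by a panel of five experts (three pain
#' physicians, one oncologic surgeon, one oncologist).
#'
#' @return A list of class \code{case_study_fixture} with components:
#'   \describe{
#'     \item{hierarchy}{\code{criteria_hierarchy}, 5 main criteria, 11 leaves.}
#'     \item{panel}{list of five \code{expert_judgement}s (PP#1, PP#2, PP#3,
#'       OS, OC): importance orderings and adjacent ratios.}
#'     \item{scores}{4 x 11 \code{decision_matrix} of averaged expert scores
#'       on the levels \{1, 1.5, 2, 2.5, 3\}, higher = more favourable.}
#'     \item{published_weights}{the reference weight vector as printed in the
#'       original study report, for comparison only.}
#'     \item{published_ranking}{the reference unweighted/weighted closeness
#'       values and ranks as printed, for comparison only — the package never
#'       treats these as expected output (see the methods vignette).}
#'   }
#' @examples
#' cs <- pain_case_study()
#' length(cs$panel)
#' dim(cs$scores)
#' @export
pain_case_study <- function() {
  hierarchy <- build_hierarchy(list(
    main = list(
      list(id = "C1", label = "Convenience"),
      list(id = "C2", label = "Pain"),
      list(id = "C3", label = "Risk"),
      list(id = "C4", label = "Duration"),
      list(id = "C5", label = "Cost")),
    leaves = list(
      list(id = "C11", parent = "C1", label = "General medical condition"),
      list(id = "C12", parent = "C1", label = "Stage of cancer"),
      list(id = "C13", parent = "C1", label = "Level of evidence"),
      list(id = "C21", parent = "C2", label = "Localization of pain"),
      list(id = "C22", parent = "C2", label = "Character of pain"),
      list(id = "C31", parent = "C3", label = "Risk of complication"),
      list(id = "C32", parent = "C3", label = "Radiation exposure"),
      list(id = "C41", parent = "C4", label = "Duration of procedure"),
      list(id = "C42", parent = "C4", label = "Persistency"),
      list(id = "C51", parent = "C5", label = "Material cost"),
      list(id = "C52", parent = "C5", label = "Cost of hospitalization"))))

  panel <- list(
    expert_judgement("PP#1",
      c("C11","C21","C12","C13","C22","C31","C42","C41","C32","C52","C51"),
      c(1.0, 1.2, 1.4, 1.4, 1.2, 1.6, 1.4, 1.6, 1.8, 1.1)),
    expert_judgement("PP#2",
      c("C11","C13","C31","C12","C21","C42","C22","C32","C41","C51","C52"),
      c(1.2, 1.4, 1.4, 1.1, 1.4, 1.2, 1.6, 1.6, 1.8, 1.2)),
    expert_judgement("PP#3",
      c("C11","C12","C21","C13","C31","C22","C41","C42","C32","C51","C52"),
      c(1.4, 1.4, 1.5, 1.6, 1.6, 1.8, 1.2, 1.6, 1.8, 1.2)),
    expert_judgement("OS",
      c("C12","C11","C13","C21","C31","C32","C42","C41","C22","C52","C51"),
      c(1.6, 1.7, 1.5, 1.4, 1.6, 1.4, 1.4, 1.6, 1.4, 1.2)),
    expert_judgement("OC",
      c("C11","C12","C21","C13","C42","C31","C22","C32","C41","C52","C51"),
      c(1.4, 1.4, 1.7, 1.6, 1.4, 1.6, 1.5, 1.7, 1.2, 1.1)))

  alternatives <- c("Lumbar epidural catheter", "Spinal port",
                    "Celiac plexus block", "Splanchnic RF thermocoagulation")
  scores <- decision_matrix(rbind(
    c(3,   1, 1, 1, 2, 3,   3, 3,   1,   3,   1),
    c(2,   3, 2, 3, 3, 2,   3, 1,   3,   1,   1),
    c(1,   2, 3, 2, 2, 1,   1, 2,   2.5, 2.5, 2),
    c(1.5, 2, 2, 2, 2, 1.5, 2, 1.5, 2.5, 2,   2)),
    alternatives = alternatives,
    criteria = hierarchy$leaves$id)

  published_weights <- stats::setNames(
    c(0.266, 0.221, 0.134, 0.145, 0.046, 0.079, 0.025, 0.021, 0.045,
      0.009, 0.009),
    hierarchy$leaves$id)

  published_ranking <- data.frame(
    alternative = alternatives,
    unweighted_closeness = c(0.443, 0.591, 0.550, 0.606),
    unweighted_rank = c(4L, 2L, 3L, 1L),
    weighted_closeness = c(0.205, 0.800, 0.498, 0.746),
    weighted_rank = c(4L, 1L, 3L, 2L),
    stringsAsFactors = FALSE)

  structure(list(hierarchy = hierarchy, panel = panel, scores = scores,
                 published_weights = published_weights,
                 published_ranking = published_ranking),
            class = "case_study_fixture")
}

#' Reproduce the case-study criterion weights
#'
#' Computes each expert's G1 weight vector from the panel judgements,
#' averages them arithmetically, and tabulates the result against the
#' published reference weights.
#'
#' @param f A \code{case_study_fixture} (default: the built-in study).
#' @return List with \code{weights} (the computed panel-mean weight vector),
#'   \code{per_expert} (matrix, experts x leaves) and \code{comparison}
#'   (data frame: leaf, label, computed, computed at 3 dp, published,
#'   absolute difference at 3 dp, and a mismatch flag).
#' @details Computed and published weights agree to 3 decimals on ten of the
#'   eleven leaves; the procedure-duration leaf (C41) computes to 0.022
#'   against a published 0.021. The comparison surfaces this 0.001 difference
#'   rather than forcing agreement.
#' @export
reproduce_weights <- function(f = pain_case_study()) {
  stopifnot(inherits(f, "case_study_fixture"))
  per <- t(vapply(f$panel, g1_weight_vector, numeric(nrow(f$hierarchy$leaves)),
                  h = f$hierarchy))
  rownames(per) <- vapply(f$panel, `[[`, "", "expert_id")
  w <- aggregate_weight_vectors(asplit(per, 1L))
  comp <- data.frame(
    leaf = names(w),
    label = f$hierarchy$leaves$label,
    computed = as.numeric(w),
    computed_3dp = round(as.numeric(w), 3),
    published = as.numeric(f$published_weights[names(w)]),
    stringsAsFactors = FALSE)
  comp$abs_diff_3dp <- abs(comp$computed_3dp - comp$published)
  comp$mismatch <- comp$abs_diff_3dp > 1e-9
  list(weights = w, per_expert = per, comparison = comp)
}

#' Recompute the case-study ranking and compare with the published one
#'
#' Runs TOPSIS on the case-study score matrix, either with uniform weights
#' (\code{variant = "unweighted"}: every sub-criterion equally important) or
#' with the panel-mean G1 weights (\code{variant = "weighted"}), and places
#' the computed closeness and ranks next to the published reference values.
#' Divergence is reported, never reconciled: the published closeness values
#' could not be re-derived under any standard convention, so the comparison
#' is tagged with the exact convention used for the recomputation.
#'
#' @param f A \code{case_study_fixture}.
#' @param variant \code{"weighted"} (default) or \code{"unweighted"}.
#' @param normalization,directions Convention options passed to
#'   [run_topsis()]; defaults are column vector normalization with every
#'   column a benefit criterion (the score scales are pre-oriented so that 3
#'   is the favourable level).
#' @return List with \code{result} (the \code{topsis_result}),
#'   \code{comparison} (computed vs published closeness and rank per
#'   alternative, with mismatch flags) and \code{convention}.
#' @export
reproduce_ranking <- function(f = pain_case_study(),
                              variant = c("weighted", "unweighted"),
                              normalization = "vector_column",
                              directions = "benefit") {
  stopifnot(inherits(f, "case_study_fixture"))
  variant <- match.arg(variant)
  w <- if (variant == "weighted") reproduce_weights(f)$weights
       else stats::setNames(rep(1 / ncol(f$scores), ncol(f$scores)),
                            colnames(f$scores))
  res <- run_topsis(f$scores, w, directions = directions,
                    normalization = normalization)
  pub <- f$published_ranking
  pc <- pub[[paste0(variant, "_closeness")]]
  pr <- pub[[paste0(variant, "_rank")]]
  comp <- data.frame(
    alternative = res$scores$alternative,
    computed_closeness = res$scores$closeness,
    published_closeness = pc,
    computed_rank = res$scores$rank,
    published_rank = pr,
    stringsAsFactors = FALSE)
  comp$closeness_diff <- comp$computed_closeness - comp$published_closeness
  comp$rank_agrees <- comp$computed_rank == comp$published_rank
  list(result = res, comparison = comp,
       convention = c(res$convention, list(variant = variant)))
}

#' Leave-one-expert-out rank stability
#'
#' Recomputes the panel-mean weights and the weighted ranking with each
#' expert removed in turn, summarizing how much the final ranking depends on
#' any single panel member.
#'
#' @param f A \code{case_study_fixture}.
#' @param normalization,directions Convention options, as in
#'   [reproduce_ranking()].
#' @return List with \code{weights} (matrix: one reduced-panel mean weight
#'   vector per held-out expert), \code{ranks} (matrix: rank per alternative
#'   per held-out expert), \code{rank1} (character: rank-1 alternative per
#'   row) and \code{stability} (named vector: fraction of reduced panels in
#'   which each alternative keeps its full-panel rank).
#' @export
leave_one_expert_out <- function(f = pain_case_study(),
                                 normalization = "vector_column",
                                 directions = "benefit") {
  stopifnot(inherits(f, "case_study_fixture"))
  if (length(f$panel) < 2L) stop("need at least two experts", call. = FALSE)
  ids <- vapply(f$panel, `[[`, "", "expert_id")
  per <- lapply(f$panel, g1_weight_vector, h = f$hierarchy)
  full <- run_topsis(f$scores, aggregate_weight_vectors(per),
                     directions = directions, normalization = normalization)
  out_w <- list(); out_r <- list(); rank1 <- character()
  for (k in seq_along(f$panel)) {
    w <- aggregate_weight_vectors(per[-k])
    res <- run_topsis(f$scores, w, directions = directions,
                      normalization = normalization)
    out_w[[ids[k]]] <- w
    out_r[[ids[k]]] <- stats::setNames(res$scores$rank, res$scores$alternative)
    rank1[ids[k]] <- res$scores$alternative[res$scores$rank == 1L][1L]
  }
  ranks <- do.call(rbind, out_r)
  baseline <- stats::setNames(full$scores$rank, full$scores$alternative)
  stability <- colMeans(ranks == matrix(baseline, nrow(ranks),
                                        ncol(ranks), byrow = TRUE))
  list(weights = do.call(rbind, out_w), ranks = ranks, rank1 = rank1,
       baseline_ranks = baseline, stability = stability)
}

#' Ratio-perturbation rank stability
#'
#' Monte Carlo robustness check on the elicited importance ratios: in each
#' replicate every expert ratio is independently moved up or down by at most
#' \code{delta} grid steps (0.1 each) on the nine-point elicitation grid,
#' clamped to [1.0, 1.8]; the panel-mean weights and the weighted TOPSIS
#' ranking are recomputed, and the frequency of each (alternative, rank)
#' pair across replicates is returned.
#'
#' @param f A \code{case_study_fixture}.
#' @param delta Maximum number of grid steps (non-negative integer).
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed; the result is a pure function of
#'   (\code{f}, \code{delta}, \code{reps}, \code{seed}).
#' @param normalization,directions Convention options.
#' @return List with \code{frequencies} (matrix alternatives x ranks; each
#'   row sums to 1) and \code{baseline_ranks}.
#' @export
perturb_ratios <- function(f = pain_case_study(), delta = 1L, reps = 100L,
                           seed = 1L,
                           normalization = "vector_column",
                           directions = "benefit") {
  stopifnot(inherits(f, "case_study_fixture"))
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 ||
      delta != round(delta))
    stop("delta must be a non-negative integer number of grid steps",
         call. = FALSE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("reps must be >= 1", call. = FALSE)
  m <- nrow(f$scores)
  alt <- rownames(f$scores)
  counts <- matrix(0L, m, m, dimnames = list(alt, paste0("rank", seq_len(m))))
  withr::with_seed(as.integer(seed), {
    for (rep_ in seq_len(reps)) {
      panel <- lapply(f$panel, function(j) {
        steps <- sample.int(2L * delta + 1L, length(j$ratios),
                            replace = TRUE) - (delta + 1L)
        r <- pmin(1.8, pmax(1.0, j$ratios + 0.1 * steps))
        expert_judgement(j$expert_id, j$order, round(r, 1))
      })
      w <- aggregate_weight_vectors(
        lapply(panel, g1_weight_vector, h = f$hierarchy))
      res <- run_topsis(f$scores, w, directions = directions,
                        normalization = normalization)
      for (i in seq_len(m))
        counts[i, res$scores$rank[i]] <- counts[i, res$scores$rank[i]] + 1L
    }
  })
  base <- run_topsis(f$scores, reproduce_weights(f)$weights,
                     directions = directions, normalization = normalization)
  list(frequencies = counts / reps,
       baseline_ranks = stats::setNames(base$scores$rank,
                                        base$scores$alternative))
}
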
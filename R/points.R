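#' Points awarded for a criterion rank
#'
#' A criterion ranked r among N carries N + 1 - r points: the top-ranked
#' criterion of a 48-item list is worth 48 points, the second 47, and the
#' worst-ranked 1.
#'
#' @param rank integer rank(s), 1 = best.
#' @param n_criteria total number of ranked criteria N.
#' @return Integer points, N + 1 - rank.
#' @examples
#' points_from_rank(2, 48)  # 47
#' points_from_rank(5, 48)  # 44
#' @export
points_from_rank <- function(rank, n_criteria) {
  rank <- as.integer(rank)
  n_criteria <- as.integer(n_criteria)
  if (any(is.na(rank)) || any(rank < 1L) || any(rank > n_criteria))
    stop("RankError: rank must lie in 1..", n_criteria, call. = FALSE)
  n_criteria + 1L - rank
}

#' Total points available over all ranked criteria
#'
#' N(N+1)/2, the sum of the rank-to-points values over all ranks; 1176 for
#' the 48-criterion catalog.
#'
#' @param n_criteria number of ranked criteria N (>= 1).
#' @return Integer total.
#' @export
total_points <- function(n_criteria) {
  n_criteria <- as.integer(n_criteria)
  if (is.na(n_criteria) || n_criteria < 1L)
    stop("n_criteria must be a positive integer", call. = FALSE)
  (n_criteria * (n_criteria + 1L)) %/% 2L
}

#' Score a candidate drug against the ranked criteria
#'
#' Sums the points of every criterion the drug satisfies and compares the
#' sum with a threshold expressed as a fraction of the total available
#' points (default one half: 588 of 1176 for 48 criteria). A drug reaching
#' the threshold is forwarded with a positive recommendation; a score
#' exactly at the threshold counts as attainment.
#'
#' @param satisfied character vector of criterion ids the drug meets (may
#'   be empty).
#' @param ranks named integer vector of ranks covering the whole catalog,
#'   e.g. the \code{ranks} element of a \code{\link{run_topsis}} result.
#' @param drug_name label carried into the result.
#' @param threshold_fraction fraction of the total points required
#'   (default 0.5).
#' @return A list of class \code{"recommendation"}: \code{drug_name},
#'   \code{score}, \code{threshold}, \code{total}, \code{decision}
#'   (\code{"forward_positive"} or \code{"not_forwarded"}) and a
#'   per-criterion \code{breakdown} data frame.
#' @examples
#' ranks <- stats::setNames(1:4, c("A1", "A2", "A3", "A4"))
#' score_drug(c("A1", "A3"), ranks)
#' @export
score_drug <- function(satisfied, ranks, drug_name = "candidate drug",
                       threshold_fraction = 0.5) {
  satisfied <- unique(as.character(satisfied))
  if (is.null(names(ranks)))
    stop("ranks must be named by criterion id", call. = FALSE)
  if (threshold_fraction < 0 || threshold_fraction > 1)
    stop("threshold_fraction must lie in [0, 1]", call. = FALSE)
  n <- length(ranks)
  if (!setequal(sort(as.integer(ranks)), seq_len(n)))
    stop("ranks must be a permutation of 1..N", call. = FALSE)
  unknown <- setdiff(satisfied, names(ranks))
  if (length(unknown))
    stop("UnknownCriterionError: id(s) absent from ranks: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  points <- points_from_rank(as.integer(ranks), n)
  names(points) <- names(ranks)
  score <- sum(points[satisfied])
  total <- total_points(n)
  threshold <- threshold_fraction * total
  breakdown <- data.frame(id = names(ranks),
                          rank = as.integer(ranks),
                          points = as.integer(points),
                          satisfied = names(ranks) %in% satisfied,
                          stringsAsFactors = FALSE, row.names = NULL)
  breakdown <- breakdown[order(breakdown$rank), ]
  rownames(breakdown) <- NULL
  structure(list(drug_name = drug_name,
                 score = as.integer(score),
                 threshold = threshold,
                 total = total,
                 decision = if (score >= threshold) "forward_positive"
                            else "not_forwarded",
                 breakdown = breakdown),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat("Drug:", x$drug_name, "\n")
  cat(sprintf("Score: %d / %d points (threshold %g)\n",
              x$score, x$total, x$threshold))
  cat("Decision:",
      if (x$decision == "forward_positive")
        "forward with positive consideration" else "not forwarded", "\n")
  cat("Satisfied criteria:", sum(x$breakdown$satisfied), "of",
      nrow(x$breakdown), "\n")
  invisible(x)
}
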
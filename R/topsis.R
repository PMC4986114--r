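#' The four fixed sub-criteria of the stage-2 instrument
#'
#' Each surviving criterion (alternative) is scored by every respondent on
#' four fixed sub-criteria: how easily its cost can be calculated, how easily
#' its value is interpreted, how precisely it is defined, and how readily it
#' can be kept up to date.
#'
#' @format Character vector of length 4.
#' @export
SUBCRITERIA <- c("cost_calculation_simplicity", "interpretability",
                 "precision", "updating_capability")

#' Construct a stage-2 Likert panel
#'
#' A three-way array of ordinal responses on the 1--5 Likert scale
#' (1 = very little ... 5 = very much): respondent x alternative x
#' sub-criterion. \code{NA} cells are non-responses.
#'
#' @param responses numeric array with dimensions (respondent, alternative,
#'   sub-criterion); present values must be integers in 1..5.
#' @param respondent_ids,alternative_ids,subcriterion_ids optional dimension
#'   names; defaults from \code{dimnames(responses)} or generated.
#' @return An array of class \code{"likert_panel"}.
#' @export
likert_panel <- function(responses, respondent_ids = NULL,
                         alternative_ids = NULL, subcriterion_ids = NULL) {
  responses <- as.array(responses)
  if (length(dim(responses)) != 3L)
    stop("responses must be a 3-way array", call. = FALSE)
  storage.mode(responses) <- "double"
  dn <- dimnames(responses) %||% vector("list", 3L)
  respondent_ids <- respondent_ids %||% dn[[1L]] %||%
    paste0("R", seq_len(dim(responses)[1L]))
  alternative_ids <- alternative_ids %||% dn[[2L]] %||%
    paste0("A", seq_len(dim(responses)[2L]))
  subcriterion_ids <- subcriterion_ids %||% dn[[3L]] %||%
    SUBCRITERIA[seq_len(dim(responses)[3L])]
  if (length(respondent_ids) != dim(responses)[1L] ||
      length(alternative_ids) != dim(responses)[2L] ||
      length(subcriterion_ids) != dim(responses)[3L])
    stop("DimensionError: id lists must match array dimensions",
         call. = FALSE)
  v <- responses[!is.na(responses)]
  if (length(v) && (min(v) < 1 || max(v) > 5 || any(v != round(v))))
    stop("Likert responses must be integers in 1..5", call. = FALSE)
  dimnames(responses) <- list(respondent_ids, alternative_ids,
                              subcriterion_ids)
  class(responses) <- c("likert_panel", "array")
  responses
}

#' Impute non-responses with the scale minimum
#'
#' Missing Likert cells are replaced by 1, the scale minimum, mirroring the
#' published handling of sporadic non-response: the ranking stage requires a
#' complete matrix, and an unanswered item is scored as conveying the least
#' possible endorsement.
#'
#' @param panel a \code{\link{likert_panel}}.
#' @return A complete panel; the number of imputed cells is available as
#'   attribute \code{n_imputed} and is reported via \code{message()} when
#'   positive.
#' @export
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "likert_panel"))
  n_missing <- sum(is.na(panel))
  if (n_missing > 0L) {
    panel[is.na(panel)] <- 1
    message("impute_missing: ", n_missing,
            " missing cell(s) set to scale minimum 1")
  }
  attr(panel, "n_imputed") <- n_missing
  panel
}

#' Aggregate a complete Likert panel into a decision matrix
#'
#' Collapses the respondent dimension: cell (i, j) of the decision matrix is
#' the aggregate over respondents of the responses for alternative i on
#' sub-criterion j.
#'
#' @param panel a complete \code{\link{likert_panel}} (impute first).
#' @param method \code{"mean"} (default), \code{"median"} or
#'   \code{"geometric_mean"}.
#' @param weights per-sub-criterion weights for the returned decision
#'   matrix; default equal.
#' @param directions per-sub-criterion orientation, \code{"benefit"}
#'   (larger is better) or \code{"cost"}; default all-benefit.
#' @return A \code{\link{decision_matrix}} with entries in \[1, 5\].
#' @export
aggregate_panel <- function(panel, method = c("mean", "median",
                                              "geometric_mean"),
                            weights = NULL, directions = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "likert_panel"))
  if (dim(panel)[1L] == 0L)
    stop("EmptyPanelError: panel has zero respondents", call. = FALSE)
  if (anyNA(panel))
    stop("panel has missing cells; run impute_missing() first",
         call. = FALSE)
  f <- switch(method,
              mean = function(z) mean(z),
              median = function(z) stats::median(z),
              geometric_mean = function(z) exp(mean(log(z))))
  x <- apply(unclass(panel), c(2L, 3L), f)
  decision_matrix(x, weights = weights, directions = directions)
}

#' Construct a TOPSIS decision matrix
#'
#' @param x numeric matrix of aggregated scores, rows = alternatives,
#'   columns = (sub-)criteria; all entries must be finite and positive.
#' @param weights per-column non-negative weights summing to 1; default
#'   equal weights.
#' @param directions per-column \code{"benefit"} or \code{"cost"}; default
#'   all \code{"benefit"}.
#' @return A list of class \code{"decision_matrix"} with elements \code{x},
#'   \code{weights}, \code{directions}.
#' @export
decision_matrix <- function(x, weights = NULL, directions = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("A", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- SUBCRITERIA[seq_len(ncol(x))]
  if (any(!is.finite(x)) || any(x <= 0))
    stop("decision matrix entries must be finite and > 0", call. = FALSE)
  m <- ncol(x)
  weights <- weights %||% rep(1 / m, m)
  directions <- directions %||% rep("benefit", m)
  if (length(directions) == 1L) directions <- rep(directions, m)
  if (length(weights) != m || length(directions) != m)
    stop("DimensionError: weights/directions must have one entry per column",
         call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'", call. = FALSE)
  structure(list(x = x, weights = as.numeric(weights),
                 directions = directions),
            class = "decision_matrix")
}

#' Vector (Euclidean) column normalization
#'
#' r_ij = x_ij / sqrt(sum_i x_ij^2): after normalization every column has
#' unit Euclidean norm, making columns with different measurement scales
#' commensurable.
#'
#' @param x numeric matrix (or a \code{\link{decision_matrix}}, whose
#'   \code{x} is used).
#' @return The normalized matrix r, same shape as \code{x}.
#' @examples
#' vector_normalize(matrix(c(3, 4), 2, 1))  # 0.6, 0.8
#' @export
vector_normalize <- function(x) {
  if (inherits(x, "decision_matrix")) x <- x$x
  x <- as.matrix(x)
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0))
    stop("NormalizationError: all-zero column(s): ",
         paste(colnames(x)[norms == 0], collapse = ", "), call. = FALSE)
  sweep(x, 2L, norms, "/")
}

#' Apply weights to a normalized matrix
#'
#' v_ij = w_j * r_ij.
#'
#' @param r normalized matrix.
#' @param weights per-column weights.
#' @return The weighted normalized matrix v.
#' @export
apply_weights <- function(r, weights) {
  r <- as.matrix(r)
  if (length(weights) != ncol(r))
    stop("DimensionError: one weight per column required", call. = FALSE)
  sweep(r, 2L, as.numeric(weights), "*")
}

#' Positive-ideal and negative-ideal solutions
#'
#' For a benefit column the ideal value is the column maximum and the
#' anti-ideal the minimum; for a cost column the roles are reversed.
#'
#' @param v weighted normalized matrix.
#' @param directions per-column \code{"benefit"} or \code{"cost"}.
#' @return List with numeric vectors \code{ideal} and \code{anti_ideal}.
#' @export
ideal_solutions <- function(v, directions = rep("benefit", ncol(v))) {
  v <- as.matrix(v)
  if (nrow(v) == 0L) stop("empty matrix", call. = FALSE)
  if (length(directions) != ncol(v))
    stop("DimensionError: one direction per column required", call. = FALSE)
  hi <- apply(v, 2L, max)
  lo <- apply(v, 2L, min)
  cost <- directions == "cost"
  ideal <- ifelse(cost, lo, hi)
  anti <- ifelse(cost, hi, lo)
  list(ideal = as.numeric(ideal), anti_ideal = as.numeric(anti))
}

#' Euclidean separation from the ideal and anti-ideal points
#'
#' d_i+ = sqrt(sum_j (v_ij - ideal_j)^2), and analogously d_i- with the
#' anti-ideal.
#'
#' @param v weighted normalized matrix.
#' @param ideal,anti_ideal per-column reference vectors.
#' @return List with numeric vectors \code{d_plus}, \code{d_minus}.
#' @export
separation_measures <- function(v, ideal, anti_ideal) {
  v <- as.matrix(v)
  if (length(ideal) != ncol(v) || length(anti_ideal) != ncol(v))
    stop("DimensionError: reference vectors must match column count",
         call. = FALSE)
  d_plus <- sqrt(rowSums(sweep(v, 2L, ideal, "-")^2))
  d_minus <- sqrt(rowSums(sweep(v, 2L, anti_ideal, "-")^2))
  list(d_plus = as.numeric(d_plus), d_minus = as.numeric(d_minus))
}

#' Relative closeness to the ideal solution
#'
#' C_i = d_i- / (d_i+ + d_i-), in \[0, 1\]: 1 means the alternative
#' coincides with the ideal point, 0 with the anti-ideal. When an
#' alternative has d+ = d- = 0 (all alternatives identical in every
#' column), C is set to 0.5 by convention and flagged via the
#' \code{degenerate} attribute.
#'
#' @param d_plus,d_minus non-negative separation vectors.
#' @return Numeric vector of closeness values with logical attribute
#'   \code{degenerate}.
#' @export
relative_closeness <- function(d_plus, d_minus) {
  if (any(d_plus < 0) || any(d_minus < 0))
    stop("ContractViolation: separations must be non-negative",
         call. = FALSE)
  tot <- d_plus + d_minus
  degen <- tot == 0
  ct <- ifelse(degen, 0.5, d_minus / ifelse(degen, 1, tot))
  attr(ct, "degenerate") <- degen
  ct
}

#' Rank alternatives by descending closeness
#'
#' Rank 1 is the alternative closest to the ideal. Exact ties are broken
#' deterministically by the ascending numeric suffix of the alternative id
#' (position order if ids carry no numeric suffix), so runs are
#' bit-reproducible.
#'
#' @param closeness numeric vector of relative closeness values.
#' @param ids alternative ids, used for tie-breaking; defaults to names of
#'   \code{closeness} or positions.
#' @return Integer ranks, a permutation of 1..N.
#' @export
rank_alternatives <- function(closeness, ids = NULL) {
  if (any(!is.finite(closeness)))
    stop("closeness must be finite", call. = FALSE)
  n <- length(closeness)
  ids <- ids %||% names(closeness) %||% as.character(seq_len(n))
  suffix <- suppressWarnings(id_suffix(ids))
  if (anyNA(suffix)) suffix <- seq_len(n)
  ord <- order(-closeness, suffix)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- ids
  ranks
}

#' Run the full TOPSIS procedure
#'
#' Composes the classical steps on a decision matrix: vector-normalize the
#' columns, apply the weights, locate the positive- and negative-ideal
#' points, measure each alternative's Euclidean separation from both, form
#' the relative closeness C = d-/(d+ + d-), and rank by descending C. All
#' intermediate matrices are retained in the result for reporting.
#'
#' @param x a \code{\link{decision_matrix}}, a \code{\link{likert_panel}}
#'   (imputed and aggregated first, see below), or a plain numeric matrix.
#' @param weights,directions used when \code{x} is not already a
#'   \code{decision_matrix}; defaults equal weights, all-benefit.
#' @param aggregation respondent-aggregation method when \code{x} is a
#'   \code{likert_panel}.
#' @return An object of class \code{"topsis_result"}: a list with the input
#'   matrix \code{x}, \code{weights}, \code{directions}, normalized
#'   \code{r}, weighted \code{v}, \code{ideal}, \code{anti_ideal},
#'   \code{d_plus}, \code{d_minus}, \code{closeness}, \code{ranks},
#'   logical vector \code{degenerate} and \code{n_imputed}.
#' @examples
#' x <- matrix(c(5, 1, 4, 2, 3, 3, 2, 4), nrow = 2,
#'             dimnames = list(c("A1", "A2"), NULL))
#' run_topsis(x)
#' @export
run_topsis <- function(x, weights = NULL, directions = NULL,
                       aggregation = c("mean", "median", "geometric_mean")) {
  aggregation <- match.arg(aggregation)
  n_imputed <- 0L
  if (inherits(x, "likert_panel")) {
    x <- impute_missing(x)
    n_imputed <- attr(x, "n_imputed")
    x <- aggregate_panel(x, method = aggregation, weights = weights,
                         directions = directions)
  }
  if (!inherits(x, "decision_matrix"))
    x <- decision_matrix(x, weights = weights, directions = directions)
  r <- vector_normalize(x$x)
  v <- apply_weights(r, x$weights)
  ref <- ideal_solutions(v, x$directions)
  sep <- separation_measures(v, ref$ideal, ref$anti_ideal)
  cl <- relative_closeness(sep$d_plus, sep$d_minus)
  names(cl) <- rownames(x$x)
  ranks <- rank_alternatives(as.numeric(cl), ids = rownames(x$x))
  structure(list(x = x$x, weights = x$weights, directions = x$directions,
                 r = r, v = v,
                 ideal = ref$ideal, anti_ideal = ref$anti_ideal,
                 d_plus = stats::setNames(sep$d_plus, rownames(x$x)),
                 d_minus = stats::setNames(sep$d_minus, rownames(x$x)),
                 closeness = stats::setNames(as.numeric(cl), rownames(x$x)),
                 ranks = ranks,
                 degenerate = stats::setNames(attr(cl, "degenerate"),
                                              rownames(x$x)),
                 n_imputed = n_imputed),
            class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, n = 10L, ...) {
  cat("TOPSIS ranking of", length(x$closeness), "alternatives over",
      ncol(x$x), "criteria\n")
  cat("weights:", paste(round(x$weights, 4), collapse = " "),
      " directions:", paste(x$directions, collapse = " "), "\n")
  if (x$n_imputed > 0L)
    cat("imputed cells:", x$n_imputed, "\n")
  if (any(x$degenerate))
    cat("NOTE: degenerate closeness (0/0 -> 0.5) for",
        sum(x$degenerate), "alternative(s)\n")
  df <- as.data.frame(x)
  print(utils::head(df[order(df$rank), ], n), row.names = FALSE)
  if (length(x$closeness) > n) cat("...", length(x$closeness) - n,
                                   "more alternatives\n")
  invisible(x)
}

#' @export
as.data.frame.topsis_result <- function(x, ...) {
  data.frame(id = names(x$closeness),
             d_plus = as.numeric(x$d_plus),
             d_minus = as.numeric(x$d_minus),
             closeness = as.numeric(x$closeness),
             rank = as.integer(x$ranks),
             stringsAsFactors = FALSE, row.names = NULL)
}
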
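#' Construct a stage-1 importance panel
#'
#' Stage one of the consensus process asks each expert respondent to mark the
#' importance of every candidate criterion on a 1--100 scale (1 = least,
#' 100 = most important). The panel is a respondents-by-criteria matrix;
#' \code{NA} cells are item non-responses.
#'
#' @param scores numeric matrix, rows = respondents, columns = criteria.
#'   Present values must lie in \[1, 100\].
#' @param respondent_ids,criterion_ids optional character vectors naming the
#'   rows and columns; defaults are taken from \code{dimnames(scores)} or
#'   generated (\code{R1...}, \code{A1...}).
#' @return A matrix of class \code{"importance_panel"}.
#' @export
importance_panel <- function(scores, respondent_ids = NULL,
                             criterion_ids = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(respondent_ids))
    respondent_ids <- rownames(scores) %||% paste0("R", seq_len(nrow(scores)))
  if (is.null(criterion_ids))
    criterion_ids <- colnames(scores) %||% paste0("A", seq_len(ncol(scores)))
  if (length(respondent_ids) != nrow(scores) ||
      length(criterion_ids) != ncol(scores))
    stop("DimensionError: id lists must match matrix dimensions",
         call. = FALSE)
  v <- scores[!is.na(scores)]
  if (length(v) && (min(v) < 1 || max(v) > 100))
    stop("importance scores must lie in [1, 100]", call. = FALSE)
  dimnames(scores) <- list(respondent_ids, criterion_ids)
  class(scores) <- c("importance_panel", "matrix", "array")
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-criterion importance summary
#'
#' Computes, for each criterion, the number of non-missing responses, the
#' arithmetic mean and the sample (n-1) standard deviation over those
#' responses. Criteria with no responses are reported with \code{NA} mean and
#' sd, never dropped; sd is \code{NA} when fewer than two responses exist.
#'
#' @param panel an \code{\link{importance_panel}}.
#' @return A data frame of class \code{"screening_summary"} with columns
#'   \code{criterion_id}, \code{n_responses}, \code{mean}, \code{sd}.
#' @examples
#' p <- importance_panel(matrix(c(60, 80), 2, 1))
#' summarize_importance(p)  # mean 70, sd ~14.14
#' @export
summarize_importance <- function(panel) {
  stopifnot(inherits(panel, "importance_panel"))
  if (nrow(panel) == 0L || ncol(panel) == 0L)
    stop("EmptyPanelError: panel has no respondents or no criteria",
         call. = FALSE)
  n <- colSums(!is.na(panel))
  m <- ifelse(n >= 1L, colMeans(panel, na.rm = TRUE), NA_real_)
  s <- apply(unclass(panel), 2L, stats::sd, na.rm = TRUE)
  s[n < 2L] <- NA_real_
  out <- data.frame(criterion_id = colnames(panel),
                    n_responses = as.integer(n),
                    mean = as.numeric(m), sd = as.numeric(s),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("screening_summary", "data.frame")
  out
}

#' Cronbach's alpha internal-consistency reliability
#'
#' alpha = (k/(k-1)) * (1 - sum of item variances / variance of respondent
#' totals), with sample (n-1) variances and k the number of items (criteria).
#' Values near 1 indicate high internal consistency; alpha can be negative
#' for incoherent instruments.
#'
#' @param panel an \code{\link{importance_panel}} or a complete numeric
#'   matrix (respondents x items). Missing cells are not allowed: impute or
#'   drop before calling.
#' @return The reliability coefficient, a number in \code{(-Inf, 1]}.
#' @export
cronbach_alpha <- function(panel) {
  x <- unclass(as.matrix(panel))
  storage.mode(x) <- "double"
  if (anyNA(x))
    stop("cronbach_alpha requires a complete panel (no missing cells)",
         call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("cronbach_alpha needs >= 2 respondents and >= 2 items",
         call. = FALSE)
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0)
    stop("DegenerateScaleError: zero variance of respondent total scores",
         call. = FALSE)
  item_var <- apply(x, 2L, stats::var)
  (k / (k - 1)) * (1 - sum(item_var) / total_var)
}

#' Apply the mean/SD exclusion screen to an importance summary
#'
#' The consensus screen removes criteria that the panel rates unimportant or
#' rates without agreement: with the default thresholds, a criterion fails
#' when its mean importance is below 60 or its standard deviation exceeds 25.
#' \code{mode = "any"} excludes on either condition (the default);
#' \code{mode = "both"} excludes only when both hold.
#'
#' @param summary a \code{\link{summarize_importance}} result.
#' @param mean_threshold minimum acceptable mean, importance units
#'   (default 60, must be in (0, 100\]).
#' @param sd_threshold maximum acceptable standard deviation (default 25).
#' @param mode \code{"any"} or \code{"both"}; how the two exclusion
#'   conditions combine.
#' @return The summary with an added logical column \code{retained}, carrying
#'   attributes \code{n_retained} and \code{n_excluded}.
#' @examples
#' p <- importance_panel(matrix(c(80, 79, 30, 35), 2, 2))
#' screen_criteria(summarize_importance(p))
#' @export
screen_criteria <- function(summary, mean_threshold = 60, sd_threshold = 25,
                            mode = c("any", "both")) {
  mode <- match.arg(mode)
  stopifnot(inherits(summary, "screening_summary"))
  if (mean_threshold <= 0 || mean_threshold > 100 || sd_threshold <= 0)
    stop("thresholds must be positive and mean_threshold <= 100",
         call. = FALSE)
  if (anyNA(summary$mean) || anyNA(summary$sd)) {
    bad <- summary$criterion_id[is.na(summary$mean) | is.na(summary$sd)]
    stop("ScreeningError: undefined mean/sd (n_responses < 2) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  low_mean <- summary$mean < mean_threshold
  high_sd <- summary$sd > sd_threshold
  excluded <- if (mode == "any") low_mean | high_sd else low_mean & high_sd
  summary$retained <- !excluded
  attr(summary, "n_retained") <- sum(summary$retained)
  attr(summary, "n_excluded") <- sum(!summary$retained)
  attr(summary, "config") <- list(mean_threshold = mean_threshold,
                                  sd_threshold = sd_threshold, mode = mode)
  summary
}

#' Subset a catalog to the criteria retained by a screen
#'
#' @param catalog a \code{\link{criteria_catalog}} covering the screened ids.
#' @param screened a \code{\link{screen_criteria}} result.
#' @return The catalog rows whose ids were retained, in catalog order.
#' @export
retained_catalog <- function(catalog, screened) {
  stopifnot(inherits(catalog, "criteria_catalog"),
            inherits(screened, "screening_summary"),
            !is.null(screened$retained))
  keep <- screened$criterion_id[screened$retained]
  out <- catalog[catalog$id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("criteria_catalog", "data.frame")
  out
}
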
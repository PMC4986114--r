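#' Read a stage-1 importance panel from delimited text
#'
#' Expected layout: header row of criterion ids preceded by a respondent-id
#' column, one row per respondent, blank cells for missing responses.
#'
#' @param file path or connection.
#' @param sep field delimiter (default comma).
#' @return An \code{\link{importance_panel}}.
#' @export
read_importance_panel <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L)
    stop("SchemaError: need a respondent column plus >= 1 criterion column",
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  importance_panel(m, respondent_ids = as.character(df[[1L]]),
                   criterion_ids = colnames(df)[-1L])
}

#' Write a stage-1 importance panel
#'
#' @param panel an \code{\link{importance_panel}}.
#' @param file destination.
#' @param sep field delimiter.
#' @return \code{file}, invisibly.
#' @export
write_importance_panel <- function(panel, file, sep = ",") {
  stopifnot(inherits(panel, "importance_panel"))
  df <- data.frame(respondent = rownames(panel),
                   unclass(panel), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a stage-2 Likert panel from long-format text
#'
#' Columns \code{respondent,alternative,subcriterion,score}; a blank score
#' marks a missing response. Dimension orders follow first appearance in
#' the file.
#'
#' @param file path or connection.
#' @param sep field delimiter.
#' @return A \code{\link{likert_panel}}.
#' @export
read_likert_panel <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("respondent", "alternative", "subcriterion", "score")
  if (!all(need %in% names(df)))
    stop("SchemaError: long panel requires columns ",
         paste(need, collapse = ", "), call. = FALSE)
  rid <- unique(df$respondent)
  aid <- unique(df$alternative)
  sid <- unique(df$subcriterion)
  arr <- array(NA_real_, dim = c(length(rid), length(aid), length(sid)))
  i <- match(df$respondent, rid)
  j <- match(df$alternative, aid)
  k <- match(df$subcriterion, sid)
  arr[cbind(i, j, k)] <- df$score
  likert_panel(arr, respondent_ids = as.character(rid),
               alternative_ids = as.character(aid),
               subcriterion_ids = as.character(sid))
}

#' Write a stage-2 Likert panel in long format
#'
#' @param panel a \code{\link{likert_panel}}.
#' @param file destination.
#' @param sep field delimiter.
#' @return \code{file}, invisibly.
#' @export
write_likert_panel <- function(panel, file, sep = ",") {
  stopifnot(inherits(panel, "likert_panel"))
  dn <- dimnames(panel)
  grid <- expand.grid(respondent = dn[[1L]], alternative = dn[[2L]],
                      subcriterion = dn[[3L]], stringsAsFactors = FALSE)
  grid$score <- as.vector(unclass(panel))
  utils::write.table(grid, file, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(file)
}

#' Read sub-criterion weights and directions from JSON
#'
#' Expected shape: \code{{"weights": [...], "directions": [...]}}; either
#' key may be absent, yielding \code{NULL} (engine defaults).
#'
#' @param file path to a JSON file.
#' @return List with elements \code{weights} and \code{directions}.
#' @export
read_weights <- function(file) {
  cfg <- jsonlite::fromJSON(file)
  list(weights = if (!is.null(cfg$weights)) as.numeric(cfg$weights),
       directions = if (!is.null(cfg$directions))
         as.character(cfg$directions))
}

# expected md5 of the normalized packaged fixture; guards transcription
# integrity of the published tables
.PUBLISHED_FIXTURE_MD5 <- "85b6da1f6329216bb25a4bd0c166d826"

#' Load the packaged published ranking tables
#'
#' Returns the published stage-2 results for the 48 criteria: relative
#' closeness, final rank, and the separations from the ideal (d+) and
#' anti-ideal (d-) points, exactly as printed (3 decimals). The file's
#' checksum is verified on every load.
#'
#' @param check_integrity verify the fixture md5 (default TRUE).
#' @return A data frame of class \code{"published_results"} with columns
#'   \code{id}, \code{closeness_published}, \code{rank_published},
#'   \code{d_plus_published}, \code{d_minus_published}, ordered by
#'   published rank.
#' @examples
#' pub <- load_published_fixture()
#' pub$id[which.max(pub$closeness_published)]  # "A7"
#' @export
load_published_fixture <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "published_results.csv",
                      package = "topsisHTA", mustWork = TRUE)
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .PUBLISHED_FIXTURE_MD5))
      stop("FixtureCorruptionError: published_results.csv checksum ",
           "mismatch (", md5, ")", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rank_published <- as.integer(df$rank_published)
  class(df) <- c("published_results", "data.frame")
  df
}

#' Validate the internal consistency of the published tables
#'
#' Recomputes relative closeness from the published separations,
#' C = d-/(d+ + d-), and compares it with the published closeness; counts
#' adjacent published ranks whose published closeness values are out of
#' descending order; and computes Kendall's tau between the published ranks
#' and ranks re-derived by sorting the published closeness.
#'
#' @param results a \code{\link{load_published_fixture}} data frame (or any
#'   \code{published_results}-shaped frame).
#' @param tolerance closeness units; a row whose recomputed closeness
#'   deviates more than this is flagged (default 0.01, the slack expected
#'   from 3-decimal rounding of the separations).
#' @return A list of class \code{"validation_report"}:
#'   \code{max_abs_closeness_discrepancy}, \code{flagged_ids} (rows beyond
#'   tolerance), \code{degenerate_ids} (rows with d+ + d- = 0),
#'   \code{n_rank_inversions}, \code{inversions} (data frame of offending
#'   adjacent pairs), \code{kendall_tau}, \code{tolerance} and logical
#'   \code{pass} (TRUE iff the maximum discrepancy is within tolerance).
#' @export
validate_published_tables <- function(results, tolerance = 0.01) {
  stopifnot(is.data.frame(results))
  need <- c("id", "closeness_published", "rank_published",
            "d_plus_published", "d_minus_published")
  if (!all(need %in% names(results)))
    stop("SchemaError: results must carry columns ",
         paste(need, collapse = ", "), call. = FALSE)
  res <- results[order(results$rank_published), ]
  tot <- res$d_plus_published + res$d_minus_published
  degenerate <- tot == 0
  recomputed <- ifelse(degenerate, NA_real_,
                       res$d_minus_published / ifelse(degenerate, 1, tot))
  disc <- abs(res$closeness_published - recomputed)
  max_disc <- max(disc, na.rm = TRUE)
  flagged <- res$id[!is.na(disc) & disc > tolerance]
  # adjacent published ranks whose closeness is out of descending order
  inv <- which(diff(res$closeness_published) > 0)
  inversions <- data.frame(rank_above = res$rank_published[inv],
                           id_above = res$id[inv],
                           closeness_above = res$closeness_published[inv],
                           rank_below = res$rank_published[inv + 1L],
                           id_below = res$id[inv + 1L],
                           closeness_below =
                             res$closeness_published[inv + 1L],
                           stringsAsFactors = FALSE, row.names = NULL)
  tau <- stats::cor(res$rank_published,
                    rank(-res$closeness_published, ties.method = "average"),
                    method = "kendall")
  structure(list(max_abs_closeness_discrepancy = max_disc,
                 flagged_ids = flagged,
                 degenerate_ids = res$id[degenerate],
                 n_rank_inversions = nrow(inversions),
                 inversions = inversions,
                 kendall_tau = tau,
                 tolerance = tolerance,
                 pass = max_disc <= tolerance),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Published-table consistency report\n")
  cat(sprintf("  max |C_published - d-/(d+ + d-)| = %.4f (tolerance %.3g)\n",
              x$max_abs_closeness_discrepancy, x$tolerance))
  if (length(x$flagged_ids))
    cat("  rows beyond tolerance:", paste(x$flagged_ids, collapse = ", "),
        "\n")
  if (length(x$degenerate_ids))
    cat("  degenerate rows (d+ + d- = 0):",
        paste(x$degenerate_ids, collapse = ", "), "\n")
  cat("  adjacent rank inversions:", x$n_rank_inversions, "\n")
  if (x$n_rank_inversions > 0)
    for (i in seq_len(nrow(x$inversions)))
      cat(sprintf("    rank %d %s (%.3f) above rank %d %s (%.3f)\n",
                  x$inversions$rank_above[i], x$inversions$id_above[i],
                  x$inversions$closeness_above[i],
                  x$inversions$rank_below[i], x$inversions$id_below[i],
                  x$inversions$closeness_below[i]))
  cat(sprintf("  Kendall tau (published vs re-derived ranks): %.4f\n",
              x$kendall_tau))
  cat("  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
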
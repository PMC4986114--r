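#' Criterion categories
#'
#' The four appraisal categories under which every candidate reimbursement
#' criterion is classified: quality evaluation of the supporting evidence,
#' clinical evaluation, economic evaluation, and managerial appraisal.
#'
#' @format Character vector of length 4.
#' @export
CRITERION_CATEGORIES <- c("evidence_quality", "clinical", "economic",
                          "managerial")

#' Construct a criteria catalog
#'
#' A criteria catalog is an ordered collection of candidate reimbursement
#' criteria, each with a short id (a letter followed by a positive integer,
#' e.g. \code{"A7"}), a free-text label, and one of the four appraisal
#' categories. Iteration order is stable and equals input order.
#'
#' @param id character vector of criterion ids.
#' @param label character vector of criterion descriptions.
#' @param category character vector; each element one of
#'   \code{\link{CRITERION_CATEGORIES}}.
#' @return A data frame of class \code{"criteria_catalog"} with columns
#'   \code{id}, \code{label}, \code{category}.
#' @examples
#' criteria_catalog(c("A1", "A2"), c("first", "second"),
#'                  c("economic", "clinical"))
#' @export
criteria_catalog <- function(id, label, category) {
  id <- as.character(id)
  label <- as.character(label)
  category <- as.character(category)
  n <- length(id)
  if (length(label) != n || length(category) != n)
    stop("id, label and category must have equal length", call. = FALSE)
  if (anyDuplicated(id))
    stop("DuplicateCriterionError: duplicate criterion id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  bad_id <- !grepl("^[A-Za-z]+[1-9][0-9]*$", id)
  if (any(bad_id))
    stop("SchemaError: malformed criterion id(s): ",
         paste(id[bad_id], collapse = ", "), call. = FALSE)
  bad_cat <- !(category %in% CRITERION_CATEGORIES)
  if (any(bad_cat))
    stop("SchemaError: unknown category value(s): ",
         paste(unique(category[bad_cat]), collapse = ", "), call. = FALSE)
  out <- data.frame(id = id, label = label, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("criteria_catalog", "data.frame")
  out
}

#' Read a criteria catalog from delimited text or JSON
#'
#' @param file path or connection; a UTF-8 delimited file with header
#'   \code{id,label,category}, or a JSON array of objects with the same
#'   fields when \code{format = "json"}.
#' @param format \code{"csv"} (default) or \code{"json"}.
#' @param sep field delimiter for the tabular format.
#' @return A \code{\link{criteria_catalog}}, rows in file order.
#' @export
read_catalog <- function(file, format = c("csv", "json"), sep = ",") {
  format <- match.arg(format)
  if (format == "json") {
    df <- jsonlite::fromJSON(file)
    if (length(df) == 0L) df <- data.frame(id = character(),
                                           label = character(),
                                           category = character())
  } else {
    df <- utils::read.table(file, header = TRUE, sep = sep,
                            colClasses = "character", quote = "\"",
                            encoding = "UTF-8",
                            stringsAsFactors = FALSE, comment.char = "")
  }
  need <- c("id", "label", "category")
  if (!all(need %in% names(df)))
    stop("SchemaError: catalog requires columns id, label, category",
         call. = FALSE)
  criteria_catalog(df$id, df$label, df$category)
}

#' Write a criteria catalog
#'
#' @param catalog a \code{\link{criteria_catalog}}.
#' @param file destination path or connection.
#' @param format \code{"csv"} or \code{"json"}.
#' @param sep field delimiter for the tabular format.
#' @return \code{file}, invisibly.
#' @export
write_catalog <- function(catalog, file, format = c("csv", "json"),
                          sep = ",") {
  format <- match.arg(format)
  stopifnot(inherits(catalog, "criteria_catalog"))
  if (format == "json") {
    jsonlite::write_json(as.data.frame(unclass(catalog),
                                       stringsAsFactors = FALSE),
                         file, auto_unbox = TRUE)
  } else {
    utils::write.table(catalog, file, sep = sep, row.names = FALSE,
                       qmethod = "double", fileEncoding = "UTF-8")
  }
  invisible(file)
}

#' Number of criteria in a catalog
#'
#' @param catalog a \code{\link{criteria_catalog}}.
#' @return Integer count.
#' @export
catalog_size <- function(catalog) {
  stopifnot(inherits(catalog, "criteria_catalog"))
  nrow(catalog)
}

#' The packaged 48-criterion reimbursement catalog
#'
#' Loads the catalog of the 48 criteria that survived stage-1 screening and
#' formed the stage-2 instrument, ids \code{A1}--\code{A48}. Category
#' assignments follow the published per-criterion discussion where one is
#' given and a documented best-effort mapping elsewhere; supply your own file
#' to \code{\link{read_catalog}} to override.
#'
#' @return A \code{\link{criteria_catalog}} with 48 rows.
#' @examples
#' catalog_size(default_catalog())  # 48
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "criteria_table4.csv",
                           package = "topsisHTA", mustWork = TRUE))
}

#' @export
print.criteria_catalog <- function(x, ...) {
  cat("Criteria catalog:", nrow(x), "criteria\n")
  tab <- table(factor(x$category, levels = CRITERION_CATEGORIES))
  cat("  by category:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  NextMethod()
}

# numeric suffix of an id like "A7" -> 7; used only for deterministic
# tie-breaking downstream, ids are otherwise opaque keys
id_suffix <- function(id) {
  as.integer(sub("^[A-Za-z]+", "", id))
}
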
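#' Construct a validated multi-reader multi-case rating panel
#'
#' A rating panel holds the complete set of ordinal image-quality ratings of
#' an MRMC visual grading study: one rating per combination of observer,
#' case (patient), acquisition protocol and quality criterion.  The
#' constructor enforces the two structural invariants such studies rely on:
#' the design is *complete* (every observer rated every case under every
#' protocol for every criterion) and free of duplicate keys, and every
#' rating is an integer on the declared `1..n_categories` ordinal scale.
#'
#' The number of categories is declared rather than inferred from the data,
#' so a panel in which an extreme category ("Very bad", say) was never used
#' is still valid and its VGC operating points are still computed over the
#' full scale.
#'
#' @param records data frame with columns `observer`, `case`, `protocol`,
#'   `criterion` (character or factor, non-empty labels) and `rating`
#'   (integer).
#' @param n_categories number of ordinal categories `K`; ratings must lie in
#'   `1..K`.  Default 5 ("Very bad" ... "Very good").
#' @return An object of class `rating_panel`: a list with the sorted
#'   `records` data frame, `n_categories`, and the distinct label sets
#'   `observers`, `cases`, `protocols`, `criteria`.
#' @seealso [read_ratings()], [write_ratings()], [generate_panel()]
#' @examples
#' recs <- expand.grid(observer = c("o1", "o2"), case = c("c1", "c2"),
#'                     protocol = c("ref", "test"), criterion = "Q1",
#'                     stringsAsFactors = FALSE)
#' recs$rating <- c(3L, 4L, 2L, 5L, 3L, 4L, 2L, 5L)
#' rating_panel(recs, n_categories = 5)
#' @export
rating_panel <- function(records, n_categories = 5) {
  if (!is.data.frame(records))
    stopf("`records` must be a data frame")
  needed <- c("observer", "case", "protocol", "criterion", "rating")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stopf("`records` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L)
    stopf("a rating panel must contain at least one record")
  if (!is.numeric(n_categories) || length(n_categories) != 1L ||
      n_categories < 2 || n_categories != as.integer(n_categories))
    stopf("`n_categories` must be a single integer >= 2")
  n_categories <- as.integer(n_categories)

  rec <- data.frame(
    observer  = as.character(records$observer),
    case      = as.character(records$case),
    protocol  = as.character(records$protocol),
    criterion = as.character(records$criterion),
    rating    = records$rating,
    stringsAsFactors = FALSE
  )
  for (col in needed[1:4]) {
    if (anyNA(rec[[col]]) || any(!nzchar(rec[[col]])))
      stopf("column `%s` contains empty or missing labels", col)
  }
  r <- rec$rating
  if (anyNA(r) || !is.numeric(r) || any(r != as.integer(r)))
    stopf("ratings must be integers")
  bad <- which(r < 1 | r > n_categories)
  if (length(bad))
    stopf(paste0("rating out of range: value %s at (%s, %s, %s, %s); ",
                 "ratings must lie in [1, %d]"),
          r[bad[1]], rec$observer[bad[1]], rec$case[bad[1]],
          rec$protocol[bad[1]], rec$criterion[bad[1]], n_categories,
          class = "vgc_range_error")
  rec$rating <- as.integer(r)

  key <- paste(rec$observer, rec$case, rec$protocol, rec$criterion, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup)
    stopf("duplicate rating for key (%s, %s, %s, %s)",
          rec$observer[dup], rec$case[dup], rec$protocol[dup],
          rec$criterion[dup], class = "vgc_duplicate_error")

  observers <- sort(unique(rec$observer))
  cases     <- sort(unique(rec$case))
  protocols <- sort(unique(rec$protocol))
  criteria  <- sort(unique(rec$criterion))
  n_expect <- length(observers) * length(cases) * length(protocols) *
    length(criteria)
  if (nrow(rec) != n_expect) {
    miss <- first_missing_key(key, observers, cases, protocols, criteria)
    stopf(paste0("incomplete design: missing rating for (observer=%s, ",
                 "case=%s, protocol=%s, criterion=%s)"),
          miss[1], miss[2], miss[3], miss[4], class = "vgc_completeness_error")
  }

  ord <- order(rec$observer, rec$case, rec$protocol, rec$criterion,
               method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL

  structure(
    list(records = rec, n_categories = n_categories, observers = observers,
         cases = cases, protocols = protocols, criteria = criteria),
    class = "rating_panel"
  )
}

# first missing (observer, case, protocol, criterion) key in lexicographic
# order of the sorted label sets
#' @noRd
first_missing_key <- function(key, observers, cases, protocols, criteria) {
  full <- expand.grid(criterion = criteria, protocol = protocols,
                      case = cases, observer = observers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full_key <- paste(full$observer, full$case, full$protocol, full$criterion,
                    sep = "\r")
  i <- which(!(full_key %in% key))[1]
  c(full$observer[i], full$case[i], full$protocol[i], full$criterion[i])
}

#' Read a rating panel from a long-format CSV file
#'
#' The canonical interchange format is a tidy CSV with header
#' `observer,case,protocol,criterion,rating` and one rating per row, the
#' natural merge of per-observer study log files.  The file is validated on
#' read: completeness, duplicate keys and the rating range are all checked.
#'
#' @param path path to a CSV file (UTF-8).
#' @param n_categories declared number of ordinal categories, default 5.
#' @return A [rating_panel] object.
#' @export
read_ratings <- function(path, n_categories = 5) {
  if (!file.exists(path))
    stopf("ratings file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rating = "integer"))
  needed <- c("observer", "case", "protocol", "criterion", "rating")
  if (!all(needed %in% names(df)))
    stopf("ratings file must declare header `%s`; got `%s`",
          paste(needed, collapse = ","), paste(names(df), collapse = ","))
  rating_panel(df[needed], n_categories = n_categories)
}

#' Write a rating panel to CSV
#'
#' Records are written in the panel's canonical sort order (observer, case,
#' protocol, criterion), so two writes of the same panel are byte-identical
#' and `read_ratings(write_ratings(p))` reproduces `p` record for record.
#'
#' @param panel a [rating_panel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(panel, path) {
  stopifnot(inherits(panel, "rating_panel"))
  utils::write.csv(panel$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.rating_panel <- function(x, ...) x$records

#' @export
print.rating_panel <- function(x, ...) {
  cat(sprintf(
    "MRMC rating panel: %d observers x %d cases x %d protocols x %d criteria\n",
    length(x$observers), length(x$cases), length(x$protocols),
    length(x$criteria)))
  cat(sprintf("  %d ratings on a %d-category ordinal scale (complete design)\n",
              nrow(x$records), x$n_categories))
  cat("  protocols:", paste(x$protocols, collapse = ", "), "\n")
  invisible(x)
}

#' Read a criterion-to-class map
#'
#' Visual grading criteria are grouped into classes (e.g. vessel
#' demarcation, vessel disturbance, bone structure, tumor homogeneity) whose
#' pooled ratings are analysed together.  The map is a two-column CSV with
#' header `criterion,class`.  The map bundled with the package
#' (`system.file("extdata", "criterion_classes.csv", package = "vgctools")`)
#' groups Q1-Q5 as demarcation, Q6-Q10 as disturbance, Q11-Q12 as bone and
#' Q13-Q14 as tumor.
#'
#' @param x path to a CSV file, or a data frame with columns `criterion` and
#'   `class`.
#' @return Data frame with character columns `criterion` and `class`.
#' @export
read_class_map <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("class map file not found: %s", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !all(c("criterion", "class") %in% names(x)))
    stopf("class map needs columns `criterion` and `class`")
  map <- data.frame(criterion = as.character(x$criterion),
                    class = as.character(x$class),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$criterion))
    stopf("class map assigns criterion `%s` more than once",
          map$criterion[anyDuplicated(map$criterion)])
  map
}
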
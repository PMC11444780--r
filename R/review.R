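#' Read mini-review publication records
#'
#' Reads a CSV of literature-audit records with columns `journal`,
#' `categorized` (`yes`/`no`, or logical) and optionally `rationale` (one of
#' `statistical`, `biological`, `precedent`, `arbitrary`, `none`).
#'
#' The package ships a synthetic fixture
#' (`system.file("extdata", "review_records_synthetic.csv", package =
#' "splitcost")`) with the marginal totals of the published audit -- 72
#' records across six journals, 22 flagged as categorizing a continuous
#' predictor. The per-journal split in the fixture is illustrative, not a
#' transcription of the original audit.
#'
#' @param path Path to the CSV file.
#' @return Data frame of records with a logical `categorized` column.
#' @export
read_review_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("journal", "categorized") %in% names(rec)))
    stop("review CSV must have 'journal' and 'categorized' columns",
         call. = FALSE)
  if (!is.logical(rec$categorized)) {
    val <- tolower(trimws(as.character(rec$categorized)))
    if (!all(val %in% c("yes", "no", "true", "false")))
      stop("'categorized' must be yes/no for every record", call. = FALSE)
    rec$categorized <- val %in% c("yes", "true")
  }
  rec
}

#' Tally a set of mini-review records
#'
#' Counts how many records flagged a categorized continuous predictor,
#' overall and per journal. The headline percentage is rounded to the
#' nearest integer (100 * count / total).
#'
#' @param records Data frame from [read_review_records()] (or of the same
#'   shape); must contain at least one record.
#' @return An object of class `"review_tally"`: list with `total`,
#'   `n_categorized`, `percentage`, `by_journal` (data frame of per-journal
#'   totals and flagged counts), and `by_rationale` when a rationale column
#'   is present.
#' @export
tally_review <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame", call. = FALSE)
  if (!all(c("journal", "categorized") %in% names(records)))
    stop("records need 'journal' and 'categorized' columns", call. = FALSE)
  if (anyNA(records$categorized))
    stop("the 'categorized' flag must be present for every record",
         call. = FALSE)
  flag <- as.logical(records$categorized)
  by_j <- do.call(rbind, lapply(split(flag, records$journal), function(f)
    data.frame(n = length(f), n_categorized = sum(f))))
  by_j <- data.frame(journal = rownames(by_j), by_j, row.names = NULL)
  out <- list(total = length(flag),
              n_categorized = sum(flag),
              percentage = round(100 * sum(flag) / length(flag)),
              by_journal = by_j)
  if ("rationale" %in% names(records)) {
    r <- records$rationale[flag]
    r[is.na(r) | r == ""] <- "none"
    out$by_rationale <- sort(table(r), decreasing = TRUE)
  }
  structure(out, class = "review_tally")
}

#' @export
print.review_tally <- function(x, ...) {
  cat(sprintf("Mini-review tally: %d of %d records (%d%%) categorized a\n",
              x$n_categorized, x$total, x$percentage))
  cat("continuous predictor that could have stayed continuous.\n\n")
  print(x$by_journal, row.names = FALSE)
  if (!is.null(x$by_rationale)) {
    cat("\nstated rationale among categorizing records:\n")
    print(x$by_rationale)
  }
  invisible(x)
}
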
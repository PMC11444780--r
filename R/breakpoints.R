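#' Describe a categorization breakpoint scheme
#'
#' The breakpoint rules catalogued from the ecological literature for turning
#' a continuous predictor into categories:
#' \describe{
#'   \item{`median`}{two categories split at the 50th percentile ("early"
#'     vs "late").}
#'   \item{`uneven`}{three categories at the 25th and 75th percentiles
#'     ("early", "mid", "late").}
#'   \item{`quartiles`}{four categories at the 25th/50th/75th percentiles.}
#'   \item{`interval`}{fixed-width bins aligned to multiples of
#'     `interval_width`, labelled by their day ranges (e.g. "60–65").}
#'   \item{`bimodal`}{two categories split at the midpoint of the widest
#'     internal gap of at least `bimodal_min_gap` in the data.}
#'   \item{`custom`}{user-supplied interior edges.}
#' }
#' Quantiles use linear interpolation of order statistics (type 7).
#'
#' @param kind One of `"median"`, `"uneven"`, `"quartiles"`, `"interval"`,
#'   `"bimodal"`, `"custom"`.
#' @param interval_width Bin width in predictor units (interval kind; > 0).
#' @param custom_edges Strictly increasing interior edges (custom kind).
#' @param bimodal_min_gap Minimum empty-gap width accepted as a "natural
#'   break" (bimodal kind; > 0).
#' @return An object of class `"break_scheme"`.
#' @seealso [categorize()]
#' @export
break_scheme <- function(kind = c("median", "uneven", "quartiles", "interval",
                                  "bimodal", "custom"),
                         interval_width = 5,
                         custom_edges = NULL,
                         bimodal_min_gap = 1) {
  kind <- match.arg(kind)
  if (kind == "interval" && (!is.numeric(interval_width) || interval_width <= 0))
    stop("'interval_width' must be positive", call. = FALSE)
  if (kind == "custom") {
    if (is.null(custom_edges) || any(diff(custom_edges) <= 0))
      stop("'custom_edges' must be a strictly increasing numeric vector",
           call. = FALSE)
  }
  if (kind == "bimodal" && (!is.numeric(bimodal_min_gap) || bimodal_min_gap <= 0))
    stop("'bimodal_min_gap' must be positive", call. = FALSE)
  structure(list(kind = kind, interval_width = interval_width,
                 custom_edges = custom_edges,
                 bimodal_min_gap = bimodal_min_gap),
            class = "break_scheme")
}

#' @export
print.break_scheme <- function(x, ...) {
  cat("Breakpoint scheme:", x$kind)
  if (x$kind == "interval") cat(sprintf(" (width %g)", x$interval_width))
  if (x$kind == "bimodal") cat(sprintf(" (min gap %g)", x$bimodal_min_gap))
  if (x$kind == "custom") cat(" (edges ", paste(x$custom_edges, collapse = ", "),
                              ")", sep = "")
  cat("\n")
  invisible(x)
}

range_label <- function(lo, hi) paste0(format(lo), "–", format(hi))

#' Apply a breakpoint scheme to a continuous predictor
#'
#' Computes the interior breakpoint edges for `scheme` on `values` and assigns
#' every value to a category. Intervals are half-open `[low, high)` -- a value
#' equal to an interior edge goes to the higher category -- with the final
#' interval closed at the maximum; values beyond the realized edges fall into
#' the open-ended outer bins.
#'
#' @param values Numeric vector (at least 2 distinct, finite values).
#' @param scheme A [break_scheme()].
#' @return An object of class `"categorized_predictor"`: a list with `edges`
#'   (interior breakpoints, strictly increasing), `labels` (one more than the
#'   edges), `assignment` (factor of length `length(values)`), the `scheme`,
#'   and the observed `range`.
#' @examples
#' categorize(c(1, 2, 3, 4), break_scheme("median"))$edges  # 2.5
#' @export
categorize <- function(values, scheme) {
  stopifnot(inherits(scheme, "break_scheme"))
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite and non-missing", call. = FALSE)
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct values to categorize", call. = FALSE)
  rng <- range(values)
  q <- function(p) unname(stats::quantile(values, p, type = 7))
  edges <- switch(scheme$kind,
    median = q(0.5),
    uneven = q(c(0.25, 0.75)),
    quartiles = q(c(0.25, 0.5, 0.75)),
    interval = {
      w <- scheme$interval_width
      lo_i <- floor(rng[1] / w) + 1
      hi_i <- ceiling(rng[2] / w) - 1
      if (lo_i > hi_i)
        stop("interval width spans the whole data range: no interior edges",
             call. = FALSE)
      e <- w * seq(lo_i, hi_i)
      e[e > rng[1] & e <= rng[2]]
    },
    bimodal = {
      s <- sort(unique(values))
      gaps <- diff(s)
      ok <- which(gaps >= scheme$bimodal_min_gap)
      if (length(ok) == 0L)
        stop(sprintf("no internal gap of width >= %g found: no natural break",
                     scheme$bimodal_min_gap), call. = FALSE)
      i <- ok[which.max(gaps[ok])]
      (s[i] + s[i + 1]) / 2
    },
    custom = scheme$custom_edges)
  if (length(edges) == 0L)
    stop("scheme produced no interior edges on these values", call. = FALSE)
  if (any(diff(edges) <= 0)) {
    coll <- edges[c(diff(edges) <= 0, FALSE) | c(FALSE, diff(edges) <= 0)]
    stop(sprintf("degenerate breakpoints: edges collide at {%s}",
                 paste(format(unique(coll)), collapse = ", ")), call. = FALSE)
  }
  labels <- switch(scheme$kind,
    median = c("early", "late"),
    uneven = c("early", "mid", "late"),
    quartiles = paste0("Q", seq_len(length(edges) + 1)),
    bimodal = c("lower", "upper"),
    interval = {
      w <- scheme$interval_width
      lo <- c(w * floor(rng[1] / w), edges)
      hi <- c(edges, w * ceiling(rng[2] / w))
      mapply(range_label, lo, hi)
    },
    custom = mapply(range_label, c(rng[1], edges), c(edges, rng[2])))
  out <- structure(list(edges = edges, labels = labels,
                        assignment = NULL, scheme = scheme, range = rng),
                   class = "categorized_predictor")
  out$assignment <- assign_bins(values, out)
  out
}

#' Assign values to the categories of a realized breakpoint rule
#'
#' Half-open assignment: value in `[edge_k, edge_{k+1})` gets category
#' `k + 1`; a value exactly equal to an interior edge goes to the higher
#' category; values outside the realized edges land in the outer bins.
#'
#' @param values Numeric vector (finite, non-missing).
#' @param categorized A `"categorized_predictor"` from [categorize()].
#' @return Factor of labels with levels in category order.
#' @export
assign_bins <- function(values, categorized) {
  stopifnot(inherits(categorized, "categorized_predictor"))
  if (anyNA(values) || any(!is.finite(values)))
    stop("cannot assign missing or non-finite values", call. = FALSE)
  idx <- findInterval(values, categorized$edges) + 1L
  factor(categorized$labels[idx], levels = categorized$labels)
}

#' @export
print.categorized_predictor <- function(x, ...) {
  cat(sprintf("Categorized predictor (%s scheme)\n", x$scheme$kind))
  cat("  edges:", paste(format(x$edges), collapse = ", "), "\n")
  tab <- table(x$assignment)
  cat("  categories:\n")
  for (i in seq_along(tab))
    cat(sprintf("    %-10s n = %d\n", names(tab)[i], tab[i]))
  invisible(x)
}
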
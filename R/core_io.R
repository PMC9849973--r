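#' Construct a biometric sample
#'
#' A biometric sample is the basic data container of the package: one row per
#' fish with total length (TL, cm), body weight (BW, g) and, optionally,
#' standard length (SL, cm). All downstream analyses (length-weight
#' regression, condition indices, catch curve, ...) operate on this object.
#'
#' @param total_length numeric vector of total lengths in cm, all > 0.
#' @param body_weight numeric vector of body weights in g, all > 0.
#' @param standard_length optional numeric vector of standard lengths in cm;
#'   where present each value must satisfy 0 < SL <= TL. `NA` entries are
#'   allowed (fish whose SL was not measured).
#' @param label free-text label carried through reports.
#' @return A `data.frame` of class `biometric_sample` with columns
#'   `total_length`, `standard_length`, `body_weight` and attribute `label`.
#' @export
biometric_sample <- function(total_length, body_weight,
                             standard_length = NULL, label = "sample") {
  n <- length(total_length)
  if (n == 0L) stop("empty sample: at least one record is required")
  if (length(body_weight) != n)
    stop("total_length and body_weight must have the same length")
  if (is.null(standard_length)) standard_length <- rep(NA_real_, n)
  if (length(standard_length) != n)
    stop("standard_length must match the number of records")
  df <- data.frame(total_length = as.numeric(total_length),
                   standard_length = as.numeric(standard_length),
                   body_weight = as.numeric(body_weight))
  validate_biometrics(df)
  structure(df, label = label,
            class = c("biometric_sample", "data.frame"))
}

validate_biometrics <- function(df) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("invalid %s on row %s", what,
                   paste(utils::head(i, 5L), collapse = ", ")), call. = FALSE)
  }
  bad(!is.finite(df$total_length) | df$total_length <= 0,
      "total length (must be a positive number)")
  bad(!is.finite(df$body_weight) | df$body_weight <= 0,
      "body weight (must be a positive number)")
  sl <- df$standard_length
  has <- !is.na(sl)
  bad(has & (!is.finite(sl) | sl <= 0 | sl > df$total_length),
      "standard length (must satisfy 0 < SL <= TL)")
  invisible(df)
}

#' @export
print.biometric_sample <- function(x, ...) {
  cat(sprintf("Biometric sample '%s': n = %d fish\n",
              attr(x, "label"), nrow(x)))
  cat(sprintf("  TL %.2f-%.2f cm, BW %.2f-%.2f g, SL measured for %d fish\n",
              min(x$total_length), max(x$total_length),
              min(x$body_weight), max(x$body_weight),
              sum(!is.na(x$standard_length))))
  invisible(x)
}

#' Read a biometric table from CSV
#'
#' Reads per-fish records from a delimited text file. Column names are
#' configurable through `column_map`; drop the `standard_length` entry from
#' the map to read files without an SL column.
#'
#' @param path path to a CSV file (UTF-8, `.` decimal point).
#' @param column_map named character vector mapping the internal field names
#'   `total_length`, `body_weight` and optionally `standard_length` to the
#'   column names used in the file.
#' @param label sample label; defaults to the file name.
#' @return A [biometric_sample()] with one record per data row, in file order.
#' @export
read_biometric_table <- function(path,
                                 column_map = c(total_length = "tl_cm",
                                                standard_length = "sl_cm",
                                                body_weight = "bw_g"),
                                 label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("total_length", "body_weight")
  if (!all(need %in% names(column_map)))
    stop("column_map must map at least 'total_length' and 'body_weight'")
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols))
    stop("format error: column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  get_num <- function(field) {
    v <- raw[[column_map[[field]]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("validation error: non-numeric %s on row %d", field, bad[1L]))
    num
  }
  sl <- if ("standard_length" %in% names(column_map))
    get_num("standard_length") else NULL
  biometric_sample(total_length = get_num("total_length"),
                   body_weight = get_num("body_weight"),
                   standard_length = sl, label = label)
}

#' Write a biometric table to CSV
#'
#' Inverse of [read_biometric_table()]: the round trip preserves every record
#' to full stored precision.
#'
#' @param sample a [biometric_sample()].
#' @param path output file path.
#' @param column_map names to use for the CSV header (same convention as
#'   [read_biometric_table()]).
#' @return `path`, invisibly.
#' @export
write_biometric_table <- function(sample, path,
                                  column_map = c(total_length = "tl_cm",
                                                 standard_length = "sl_cm",
                                                 body_weight = "bw_g")) {
  stopifnot(inherits(sample, "biometric_sample"))
  out <- data.frame(sample$total_length, sample$standard_length,
                    sample$body_weight)
  names(out) <- unname(column_map[c("total_length", "standard_length",
                                    "body_weight")])
  if (!"standard_length" %in% names(column_map)) out[[2]] <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics with a 95% confidence interval for the mean
#'
#' Computes n, range, mean, sample standard deviation (n - 1 denominator) and
#' a Student-t 95% confidence interval for the mean, the summary reported per
#' measurement in length-based assessment tables.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @param conf confidence level for the interval on the mean (default 0.95).
#' @return A one-row `data.frame` with columns `n`, `minimum`, `maximum`,
#'   `mean`, `sd`, `ci95_low`, `ci95_high`. With a single observation the sd
#'   and interval are `NA`.
#' @export
descriptive_stats <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("empty sample: no values to summarize")
  m <- mean(values)
  if (n >= 2L) {
    s <- stats::sd(values)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  } else {
    s <- NA_real_
    half <- NA_real_
  }
  data.frame(n = n, minimum = min(values), maximum = max(values),
             mean = m, sd = s, ci95_low = m - half, ci95_high = m + half)
}

#' Bin lengths into a length-frequency distribution
#'
#' Bins are left-closed, right-open intervals `[edge, edge + width)` of
#' constant width anchored at `anchor`, so a fish of exactly 6.0 cm falls in
#' the 6.0-6.5 class. The modal bin is the first bin attaining the maximum
#' count.
#'
#' @param x a [biometric_sample()] (total lengths are binned) or a numeric
#'   vector of lengths in cm.
#' @param width class width in cm (default 0.5).
#' @param anchor left edge of the binning grid (default 0); all lengths must
#'   be >= anchor.
#' @return An object of class `length_frequency`: a `data.frame` with columns
#'   `lower`, `upper`, `midpoint`, `count`, and attributes `width`, `anchor`,
#'   `modal_bin` (row index) and `n`.
#' @export
bin_lengths <- function(x, width = 0.5, anchor = 0) {
  lengths <- if (inherits(x, "biometric_sample")) x$total_length else
    as.numeric(x)
  if (width <= 0) stop("width must be > 0")
  if (any(lengths < anchor)) stop("all lengths must be >= anchor")
  idx <- floor((lengths - anchor) / width)
  # guard against values sitting a hair under an exact bin edge
  up <- (lengths - anchor) / width - idx > 1 - 1e-9
  idx[up] <- idx[up] + 1L
  rng <- range(idx)
  bins <- rng[1]:rng[2]
  count <- tabulate(idx - rng[1] + 1L, nbins = length(bins))
  lfd <- data.frame(lower = anchor + bins * width,
                    upper = anchor + (bins + 1) * width,
                    midpoint = anchor + (bins + 0.5) * width,
                    count = count)
  structure(lfd, width = width, anchor = anchor,
            modal_bin = which.max(count), n = length(lengths),
            class = c("length_frequency", "data.frame"))
}

#' @export
print.length_frequency <- function(x, ...) {
  mb <- attr(x, "modal_bin")
  cat(sprintf(
    "Length-frequency distribution: %d fish in %d classes of %.2g cm\n",
    attr(x, "n"), nrow(x), attr(x, "width")))
  cat(sprintf("  modal class [%.2f, %.2f) cm with %d fish (%.1f%%)\n",
              x$lower[mb], x$upper[mb], x$count[mb],
              100 * x$count[mb] / attr(x, "n")))
  invisible(x)
}

#' Plot a length-frequency distribution
#'
#' @param x a `length_frequency` object.
#' @param refpoints optional [reference_points()] object; when supplied,
#'   vertical lines mark Lm, Lopt and the mega-spawner threshold.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.length_frequency <- function(x, refpoints = NULL, ...) {
  bp <- graphics::barplot(x$count, names.arg = sprintf("%.1f", x$midpoint),
                          xlab = "Total length class midpoint (cm)",
                          ylab = "Frequency", ...)
  if (!is.null(refpoints)) {
    to_x <- function(l) stats::approx(x$midpoint, bp[, 1], xout = l,
                                      rule = 2)$y
    graphics::abline(v = to_x(c(refpoints$lm, refpoints$lopt,
                                refpoints$mega_threshold)),
                     lty = c(2, 1, 3), col = c("blue", "darkgreen", "red"))
  }
  invisible(bp)
}

#' Shapiro-Wilk normality test for raw measurements
#'
#' Thin wrapper around [stats::shapiro.test()] with the guard rails needed in
#' a pipeline: informative errors for too-small or constant samples. The test
#' is applied to raw lengths or weights, not to binned counts.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return An `htest` object with the W statistic and two-sided p-value.
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L) stop("insufficient data: Shapiro-Wilk requires n >= 3")
  if (n > 5000L) stop("Shapiro-Wilk supports at most n = 5000")
  if (max(values) - min(values) == 0)
    stop("insufficient variation: all values are identical, W is undefined")
  stats::shapiro.test(values)
}
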
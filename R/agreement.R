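# Manual-versus-automatic method agreement: paired differences, mean
# absolute distance, percentage discrepancy, paired t test and fixed-bin
# difference histograms.

#' Paired manual-automatic differences for one measurement
#'
#' Joins the two tables on `subject_id` and returns signed differences
#' manual minus automatic; subjects present in only one table are skipped
#' and their count attached as the `skipped` attribute.
#'
#' @param manual,automatic measurement tables (data frames with
#'   `subject_id` and the measurement column).
#' @param measure measurement name (`"M"`, `"MW"`, `"B"`, `"CSW1"`,
#'   `"CSW2"`).
#' @return numeric vector of signed differences (cm), named by subject.
#' @export
paired_differences <- function(manual, automatic, measure) {
  stopifnot(measure %in% names(manual), measure %in% names(automatic))
  m <- manual[!is.na(manual[[measure]]), c("subject_id", measure)]
  a <- automatic[!is.na(automatic[[measure]]), c("subject_id", measure)]
  ids <- intersect(m$subject_id, a$subject_id)
  skipped <- length(union(m$subject_id, a$subject_id)) - length(ids)
  if (length(ids) == 0)
    stop("no matched subject pairs between the two tables for ", measure)
  d <- m[[measure]][match(ids, m$subject_id)] -
    a[[measure]][match(ids, a$subject_id)]
  names(d) <- ids
  attr(d, "skipped") <- skipped
  d
}

#' Fixed-bin histogram of paired differences
#'
#' Equal-width bins spanning the range of the differences, with a fixed
#' bin count so that bin widths vary across measurements.  The last bin
#' is right-inclusive; a degenerate (zero-width) range is widened by a
#' machine-epsilon-scaled margin so all values land in one populated bin.
#'
#' @param differences numeric vector of signed differences.
#' @param n_bins number of bins (default 11).
#' @return list with `breaks` (length `n_bins + 1`), `counts` (length
#'   `n_bins`, summing to the number of differences) and `mids`.
#' @export
difference_histogram <- function(differences, n_bins = 11) {
  stopifnot(length(differences) >= 1, n_bins >= 1)
  lo <- min(differences); hi <- max(differences)
  if (hi - lo < .Machine$double.eps) {
    eps <- max(abs(lo), 1) * .Machine$double.eps * 4 + 1e-12
    lo <- lo - eps; hi <- hi + eps
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  idx <- findInterval(differences, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
}

#' Agreement summary between manual and automatic measurements
#'
#' For each requested measurement: mean and SD of both methods, mean
#' distance (mean absolute difference, cm), percentage discrepancy
#' (100 x mean distance / mean of the denominator method, by default the
#' automatic one), a two-tailed paired t test, and an 11-bin difference
#' histogram.  A zero-variance difference vector leaves the t statistic
#' missing rather than infinite.
#'
#' @inheritParams paired_differences
#' @param measures measurement names to summarize (default: all present
#'   in both tables).
#' @param denominator `"automatic"` (default) or `"manual"`: method mean
#'   used in the discrepancy denominator.
#' @param n_bins histogram bin count.
#' @return object of class `agreement_report`: a data frame `summary`
#'   (one row per measurement: `measure`, `n`, `manual_mean`,
#'   `manual_sd`, `automatic_mean`, `automatic_sd`, `mean_distance`,
#'   `discrepancy_pct`, `t`, `p`) plus a named list `histograms`.
#' @export
agreement_summary <- function(manual, automatic, measures = NULL,
                              denominator = c("automatic", "manual"),
                              n_bins = 11) {
  denominator <- match.arg(denominator)
  if (is.null(measures))
    measures <- intersect(MEASURES,
                          intersect(names(manual), names(automatic)))
  stopifnot(length(measures) > 0)
  rows <- list(); hists <- list()
  for (msr in measures) {
    d <- paired_differences(manual, automatic, msr)
    ids <- names(d)
    mv <- manual[[msr]][match(ids, manual$subject_id)]
    av <- automatic[[msr]][match(ids, automatic$subject_id)]
    n <- length(d)
    md <- mean(abs(d))
    den <- if (denominator == "automatic") mean(av) else mean(mv)
    tstat <- pval <- NA_real_
    if (n >= 2 && stats::sd(d) > 0) {
      tt <- stats::t.test(mv, av, paired = TRUE)
      tstat <- unname(tt$statistic); pval <- tt$p.value
    } else if (n >= 2 && all(d == 0)) {
      tstat <- 0; pval <- 1
    }
    rows[[msr]] <- data.frame(
      measure = msr, n = n,
      manual_mean = mean(mv), manual_sd = stats::sd(mv),
      automatic_mean = mean(av), automatic_sd = stats::sd(av),
      mean_distance = md, discrepancy_pct = 100 * md / den,
      t = tstat, p = pval)
    hists[[msr]] <- difference_histogram(d, n_bins)
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 histograms = hists, denominator = denominator),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("<agreement_report> (discrepancy denominator:", x$denominator,
      "mean)\n")
  print(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}
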
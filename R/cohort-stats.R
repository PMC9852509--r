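# Cohort reporting: paired pre/post comparison, intra-/inter-rater
# ICC with the conventional agreement categories, classification
# summary, and a deterministic demonstration cohort.

#' Paired t-test on matched pre/post series
#'
#' Two-tailed paired t on `post - pre`: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `n - 1` degrees of freedom.
#'
#' @param pre,post Numeric vectors of equal length `>= 2`, matched by
#'   position (or by `ids`).
#' @param ids Optional identifiers; checked for pairwise matching when
#'   given as a two-column structure is not needed — values must
#'   simply be unique.
#' @return A list with `t`, `p` (two-tailed), `df`, `mean_diff`,
#'   `sd_diff`, `n`.
#' @export
#' @examples
#' paired_t(pre = c(0, 0, 0), post = c(1, 2, 3))
paired_t <- function(pre, post, ids = NULL) {
  stopifnot(is.numeric(pre), is.numeric(post))
  if (length(pre) != length(post) || length(pre) < 2L)
    stop("pre and post must be matched series of equal length >= 2", call. = FALSE)
  if (!is.null(ids) && anyDuplicated(ids))
    stop("ids must uniquely identify the matched pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0)
    stop("t statistic undefined: zero variance of the paired differences",
         call. = FALSE)
  fit <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter),
       mean_diff = mean(d), sd_diff = stats::sd(d), n = length(d))
}

#' Intraclass correlation coefficient with agreement category
#'
#' Single-measure ICC from the two-way ANOVA decomposition of a
#' subjects-by-raters table.  `form = "inter"` gives the two-way
#' random-effects absolute-agreement coefficient ICC(2,1), the
#' conventional choice for agreement between different observers;
#' `form = "intra"` gives the two-way mixed-effects consistency
#' coefficient ICC(3,1), conventional for repeated sessions of the
#' same observer.  The coefficient is categorized with the customary
#' cut-points: below 0.40 poor, 0.40--0.75 fair to good, above 0.75
#' excellent (boundaries belong to "fair to good").
#'
#' @param table Numeric matrix, rows = subjects, columns = raters or
#'   sessions; at least 2 of each, no missing cells.
#' @param form `"inter"` or `"intra"`.
#' @return A list with `icc`, `category`, and the mean squares
#'   `msr` (rows), `msc` (columns), `mse` (residual).
#' @export
#' @examples
#' icc(cbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 3, 4)), form = "inter")
icc <- function(table, form = c("inter", "intra")) {
  form <- match.arg(form)
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("rating table needs at least 2 subjects and 2 raters", call. = FALSE)
  if (anyNA(m))
    stop("rating table must have no missing cells", call. = FALSE)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || ssr <= 1e-12 * max(sst, 1))
    stop("ICC undefined: no between-subject variance", call. = FALSE)
  val <- switch(form,
    inter = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    intra = (msr - mse) / (msr + (k - 1) * mse))
  category <- if (val < 0.40) "poor"
              else if (val <= 0.75) "fair to good"
              else "excellent"
  list(icc = val, category = category, msr = msr, msc = msc, mse = mse)
}

#' Summarize a pre/post cohort table
#'
#' From a long cohort table (one row per knee and timepoint) computes,
#' for each alignment measure, the pre- and postoperative mean and
#' standard deviation and the paired t-test, plus the correction
#' classification of the postoperative WBL ratios (counts and
#' percentages to one decimal).  Knees lacking one of the two
#' timepoints are listed and excluded with a warning.
#'
#' @param records A data frame with columns `patient_id`, `side`,
#'   `timepoint` (`"pre"`/`"post"`) and one or more of `wbl_ratio`,
#'   `mfta`, `mpta`, `wedge_angle`.
#' @param params [plan_parameters()]; sets the classification band.
#' @return An object of class `"hto_cohort_summary"`: list with
#'   `n_knees`, `measures` (a data frame of pre/post mean, sd, t, p
#'   per measure), `classification` (data frame with class, count,
#'   percent, mean and sd of the ratios in each class) and
#'   `excluded` (knee ids lacking a timepoint).
#' @export
cohort_summary <- function(records, params = plan_parameters()) {
  records <- as.data.frame(records)
  for (col in c("patient_id", "side", "timepoint"))
    if (!col %in% names(records))
      stop(sprintf("cohort table missing column '%s'", col), call. = FALSE)
  measures <- intersect(c("wbl_ratio", "mfta", "mpta", "wedge_angle"),
                        names(records))
  if (length(measures) == 0L)
    stop("cohort table has no measure columns", call. = FALSE)
  records$knee <- paste(records$patient_id, records$side, sep = "/")
  pre <- records[records$timepoint == "pre", ]
  post <- records[records$timepoint == "post", ]
  matched <- intersect(pre$knee, post$knee)
  excluded <- setdiff(unique(records$knee), matched)
  if (length(excluded) > 0L)
    warning(sprintf("%d knee(s) lack a matched timepoint and were excluded: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  if (length(matched) == 0L)
    stop("no knee has both timepoints", call. = FALSE)
  pre <- pre[match(matched, pre$knee), ]
  post <- post[match(matched, post$knee), ]

  rows <- lapply(measures, function(mm) {
    a <- pre[[mm]]; b <- post[[mm]]
    tt <- if (length(matched) >= 2L && stats::sd(b - a) > 0)
      paired_t(a, b) else NULL
    data.frame(measure = mm,
               pre_mean = mean(a), pre_sd = stats::sd(a),
               post_mean = mean(b), post_sd = stats::sd(b),
               t = if (is.null(tt)) NA_real_ else tt$t,
               p = if (is.null(tt)) NA_real_ else tt$p)
  })
  measure_tab <- do.call(rbind, rows)

  classification <- NULL
  if ("wbl_ratio" %in% measures) {
    cls <- classify_correction(post$wbl_ratio, params)
    lev <- c("under", "acceptable", "over")
    counts <- vapply(lev, function(l) sum(cls == l), 0L)
    classification <- data.frame(
      class = lev,
      count = counts,
      percent = round(100 * counts / length(cls), 1),
      mean_ratio = vapply(lev, function(l)
        if (counts[[l]] > 0L) mean(post$wbl_ratio[cls == l]) else NA_real_, 0),
      sd_ratio = vapply(lev, function(l)
        if (counts[[l]] > 1L) stats::sd(post$wbl_ratio[cls == l]) else NA_real_, 0),
      row.names = NULL)
  }
  structure(list(n_knees = length(matched), measures = measure_tab,
                 classification = classification, excluded = excluded,
                 t_test_skipped = length(matched) < 2L),
            class = "hto_cohort_summary")
}

#' @export
print.hto_cohort_summary <- function(x, ...) {
  cat(sprintf("<hto_cohort_summary> %d knees with both timepoints\n", x$n_knees))
  print(x$measures, row.names = FALSE, digits = 4)
  if (!is.null(x$classification)) {
    cat("correction classification (postoperative WBL ratio):\n")
    print(x$classification, row.names = FALSE, digits = 4)
  }
  if (x$t_test_skipped)
    cat("note: paired t-test skipped (fewer than 2 matched knees)\n")
  invisible(x)
}

# quantile set with exact sample mean/sd: arcsine-distributed shoulders
# keep the extremes within ~1.42 sd of the mean
arcsine_scores <- function(n, mean, sd) {
  if (n == 1L) return(mean)
  z <- cos(pi * (seq_len(n) - 0.5) / n)
  z <- z - mean(z)
  mean + sd * z / stats::sd(z)
}

#' Deterministic 54-knee demonstration cohort
#'
#' A synthetic reconstruction of the published summary structure of a
#' 54-knee medial open-wedge HTO series: 43 knees corrected into the
#' acceptable 45--55 % band (category mean 49.3 %, sd 2.6),
#' 2 under-corrected (mean 41.8 %, sd 1.7; values 40.6 and 43.0) and
#' 9 over-corrected (mean 58.1 %, sd 1.8), with matching pre/post
#' means and sds for WBL ratio, mFTA, mMPTA and wedge angle.  Values
#' within each column are arcsine-spaced quantiles with the exact
#' target mean and sd (evenly spaced for the small categories), so the
#' cohort is fully deterministic; the pairing of pre and post values
#' across knees is arbitrary, so paired t statistics are illustrative
#' only.  Individual radiographs are not reconstructed — only the
#' reported category structure is.
#'
#' @return A long data frame in the [cohort_summary()] layout: columns
#'   `patient_id`, `side`, `timepoint`, `wbl_ratio`, `mfta`, `mpta`,
#'   `wedge_angle`; 108 rows (54 knees, two timepoints).
#' @export
#' @examples
#' cohort_summary(demo_cohort())$classification
demo_cohort <- function() {
  n <- 54L
  evenly <- function(n, mean, sd) {
    if (n == 1L) return(mean)
    z <- seq_len(n) - (n + 1) / 2
    mean + sd * z / stats::sd(z)
  }
  post_wbl <- c(evenly(2L, 41.8, 1.7),          # under: 40.598, 43.002
                arcsine_scores(43L, 49.3, 2.6), # acceptable, inside (45, 55)
                evenly(9L, 58.1, 1.8))          # over, inside (55, 62.3)
  knees <- data.frame(
    patient_id = sprintf("P%02d", ((seq_len(n) - 1L) %/% 2L) + 1L),
    side = rep(c("right", "left"), length.out = n))
  mk <- function(timepoint, wbl, mfta, mpta, wedge)
    cbind(knees, timepoint = timepoint, wbl_ratio = wbl, mfta = mfta,
          mpta = mpta, wedge_angle = wedge)
  rbind(
    mk("pre",
       wbl = arcsine_scores(n, 16.8, 13.0),
       mfta = arcsine_scores(n, 6.4, 2.8),      # varus positive
       mpta = arcsine_scores(n, 83.4, 2.7),
       wedge = arcsine_scores(n, 8.5, 3.5)),    # planned opening angle
    mk("post",
       wbl = post_wbl,
       mfta = arcsine_scores(n, -1.2, 1.3),     # mean 1.2 valgus
       mpta = arcsine_scores(n, 89.3, 1.9),
       wedge = arcsine_scores(n, 8.8, 2.9))     # measured correction angle
  )
}
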
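## Statistics battery: correlations, tertile cross-classification,
## Bland-Altman agreement, and two-way absolute-agreement ICC.

#' Correlation between two cohort vectors
#'
#' Spearman (average ranks for ties) for skewed food intakes, Pearson for
#' nutrients and index scores; pairwise-complete handling of missing values.
#' Zero variance in either vector yields an NA coefficient rather than an
#' error.
#'
#' @param x,y numeric vectors of equal length.
#' @param method "spearman" or "pearson".
#' @return list `coefficient`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    return(list(coefficient = NA_real_, p_value = NA_real_, n = n,
                method = method))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = method)
}

# tertile assignment: average ranks, boundaries at ceiling(n/3) and
# ceiling(2n/3) positions of the stable (value, id) ordering, so ties at a
# boundary resolve deterministically by id order
.tertile_assign <- function(values, ids = seq_along(values)) {
  n <- length(values)
  ord <- order(values, ids)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  1L + (pos > ceiling(n / 3)) + (pos > ceiling(2 * n / 3))
}

#' Tertile cross-classification of two methods
#'
#' Participants are ranked into tertiles separately by the reference and test
#' methods and cross-tabulated. Reports the 3 x 3 count table and the summary
#' percentages: same tertile (overall and for the lowest/highest tertile),
#' adjacent tertile, and gross misclassification (opposite extremes).
#' Ties are broken deterministically by participant order.
#'
#' @param ref,test numeric vectors (reference and test method values).
#' @param ids optional stable participant identifiers used in tie-breaking.
#' @return list with `table` (3 x 3, reference rows), `pct_same`,
#'   `pct_same_lowest`, `pct_same_highest`, `pct_adjacent`, `pct_gross`, `n`.
#' @export
tertile_cross_classify <- function(ref, test, ids = NULL) {
  stopifnot(length(ref) == length(test))
  n <- length(ref)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  tr <- .tertile_assign(ref, ids)
  tt <- .tertile_assign(test, ids)
  tab <- table(factor(tr, 1:3), factor(tt, 1:3))
  dimnames(tab) <- list(reference = paste0("T", 1:3), test = paste0("T", 1:3))
  same <- tr == tt
  list(
    table = tab,
    pct_same = 100 * mean(same),
    pct_same_lowest = 100 * sum(same & tr == 1) / sum(tr == 1),
    pct_same_highest = 100 * sum(same & tr == 3) / sum(tr == 3),
    pct_adjacent = 100 * mean(abs(tr - tt) == 1),
    pct_gross = 100 * mean(abs(tr - tt) == 2),
    n = n
  )
}

#' Bland-Altman agreement analysis
#'
#' Pairwise differences (test minus reference) against pair means, with the
#' mean difference, its 95% confidence interval, and the conventional 95%
#' limits of agreement (mean difference +/- 1.96 sd of the differences).
#' Counts of points above/below the limits use the limits of agreement; the
#' CI of the mean difference is reported separately for assessing systematic
#' bias. Per-pair plot data are returned, with an optional exclusion flag
#' (e.g. participants outside energy-reporting limits) carried through for
#' highlighting.
#'
#' @param ref,test numeric vectors.
#' @param flagged optional logical vector marking participants to highlight.
#' @return list `mean_diff`, `sd_diff`, `ci_mean` (length 2), `loa`
#'   (length 2), `n_above`, `n_below`, `n`, `data` (data.frame `mean`,
#'   `diff`, `flagged`).
#' @export
bland_altman <- function(ref, test, flagged = NULL) {
  stopifnot(length(ref) == length(test))
  ok <- complete.cases(ref, test)
  ref <- ref[ok]; test <- test[ok]
  n <- length(ref)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  if (is.null(flagged)) flagged <- rep(FALSE, n) else flagged <- flagged[ok]
  d <- test - ref
  m <- (test + ref) / 2
  md <- mean(d)
  sdd <- sd(d)
  ci <- md + c(-1, 1) * qt(0.975, n - 1) * sdd / sqrt(n)
  loa <- md + c(-1, 1) * 1.96 * sdd
  list(mean_diff = md, sd_diff = sdd, ci_mean = ci, loa = loa,
       n_above = sum(d > loa[2]), n_below = sum(d < loa[1]), n = n,
       data = data.frame(mean = m, diff = d, flagged = flagged))
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Computes ICC from the two-way ANOVA mean squares of an n participants x k
#' occasions matrix: the average-measures absolute-agreement coefficient
#' ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n), together with the
#' single-measure ICC(A,1). The 95% CI uses the F-based interval for the
#' single-measure coefficient (McGraw-Wong) transformed to average measures
#' by the Spearman-Brown relation. Reproducibility bands: below 0.5 poor,
#' 0.5 to below 0.75 moderate, 0.75 to 0.9 good, above 0.9 excellent.
#'
#' @param x numeric matrix, participants in rows, occasions in columns;
#'   complete, n >= 3, k >= 2.
#' @param conf confidence level, default 0.95.
#' @return list `icc` (average measures), `icc_single`, `ci` (length 2),
#'   `ms` (MSR, MSC, MSE), `band`, `n`, `k`.
#' @export
icc_agreement_average <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("ICC requires a complete matrix", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) stop("need n >= 3 participants and k >= 2 occasions",
                           call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf
  if (abs(1 - icc_1) < 1e-12 || (msc == 0 && mse == 0)) {
    ci <- c(icc_k, icc_k)  # degenerate: no residual or occasion variance
  } else {
    a <- (k * icc_1) / (n * (1 - icc_1))
    b <- 1 + (k * icc_1 * (n - 1)) / (n * (1 - icc_1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    sb <- function(r) r * k / (1 + (k - 1) * r)
    ci <- c(sb(l1), sb(u1))
  }
  list(icc = icc_k, icc_single = icc_1, ci = ci,
       ms = c(MSR = msr, MSC = msc, MSE = mse),
       band = icc_band(icc_k), n = n, k = k)
}

#' Qualitative reproducibility band for an ICC value
#'
#' Below 0.5: poor; 0.5 to below 0.75: moderate; 0.75 to 0.9: good; above
#' 0.9: excellent.
#' @param icc numeric ICC value(s).
#' @return character vector of bands.
#' @export
icc_band <- function(icc) {
  ifelse(icc < 0.5, "poor",
         ifelse(icc < 0.75, "moderate",
                ifelse(icc <= 0.9, "good", "excellent")))
}
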
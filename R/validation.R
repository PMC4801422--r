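## Method-agreement statistics for comparing two measurement series
## (pipeline vs manual counts): Lin's concordance correlation coefficient
## with a Fisher-z confidence interval, percent deviation, and
## object-level sensitivity/specificity.

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two measurement methods against the
#' identity line: `ccc = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`
#' with population (1/n) moments. The 95% confidence interval uses the
#' Fisher z-transform with Lin's asymptotic standard error.
#'
#' @param x,y numeric vectors of equal length (n >= 3), e.g. manual and
#'   automated counts of the same specimens.
#' @param conf_level confidence level for the interval.
#' @return List with `ccc`, `ci` (length-2 vector) and `n`.
#' @export
concordance_correlation <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  if (sx2 == 0 && sy2 == 0) stop("both series are constant; ccc undefined")
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  d2 <- (mean(x) - mean(y))^2
  ccc <- 2 * sxy / (sx2 + sy2 + d2)
  ## Lin (1989) asymptotic variance of the z-transformed ccc
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  ci <- c(NA_real_, NA_real_)
  if (abs(ccc) < 1 && abs(r) > 0) {
    u <- (mean(x) - mean(y)) / (sx2 * sy2)^(1 / 4)
    se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                    4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                    2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2))
    z <- atanh(ccc)
    q <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se_z, z + q * se_z))
  }
  list(ccc = ccc, ci = ci, n = n)
}

#' Percent deviation between manual and automated measurements
#'
#' `(manual - macro) / manual * 100`; the sign is preserved, so a negative
#' deviation means the automated measurement is larger (typical for
#' perimeter and length-type features, where continuous thresholding
#' traces more detail than manual straight-line measurement).
#'
#' @param manual reference (manual) value(s), nonzero.
#' @param macro automated value(s).
#' @return Percent deviation (vectorized).
#' @export
percent_deviation <- function(manual, macro) {
  if (any(manual == 0)) stop("manual reference value of 0; deviation undefined")
  (manual - macro) / manual * 100
}

#' Object-level sensitivity and specificity
#'
#' Implements the validation formulas used for discrete features
#' (islands, branches, branching points, active zones) on pre-matched
#' object counts: sensitivity = TP / (TP + FP), specificity =
#' TP / (TP + FN). Note these definitions differ from the conventional
#' epidemiological ones — this "sensitivity" is conventionally called
#' precision and this "specificity" recall — so the return value also
#' carries `precision` and `recall` aliases.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative
#'   object counts (matching of automated to manual objects is assumed
#'   done upstream).
#' @return List with `sensitivity_pct`, `specificity_pct` and the aliases
#'   `precision_pct`, `recall_pct`.
#' @export
object_agreement <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0 || tp + fn == 0)
    stop("zero denominator; agreement undefined")
  sens <- tp / (tp + fp) * 100
  spec <- tp / (tp + fn) * 100
  list(sensitivity_pct = sens, specificity_pct = spec,
       precision_pct = sens, recall_pct = spec)
}

#' Agreement report for a paired-measurement table
#'
#' Reads (or accepts) a table with columns `nmj_id`, `feature`, `manual`,
#' `macro` and computes, per feature, Lin's ccc with its 95% CI and the
#' mean percent deviation — the layout of a method-validation summary
#' table.
#'
#' @param table a data.frame or a path to a tab-separated file with
#'   header.
#' @return data.frame with one row per feature: `feature`, `n`, `ccc`,
#'   `ccc_lo`, `ccc_hi`, `mean_pct_deviation`.
#' @export
agreement_report <- function(table) {
  if (is.character(table))
    table <- read.table(table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  stopifnot(all(c("nmj_id", "feature", "manual", "macro") %in% names(table)))
  feats <- unique(table$feature)
  rows <- lapply(feats, function(f) {
    sub <- table[table$feature == f, ]
    cc <- concordance_correlation(sub$manual, sub$macro)
    dev <- mean(percent_deviation(sub$manual, sub$macro))
    data.frame(feature = f, n = cc$n, ccc = cc$ccc,
               ccc_lo = cc$ci[1], ccc_hi = cc$ci[2],
               mean_pct_deviation = dev)
  })
  do.call(rbind, rows)
}
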
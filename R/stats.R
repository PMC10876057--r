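# Small-sample nonparametric statistics for two-group cohort comparison.
#
# The exact Mann-Whitney two-sided p-value is defined over the permutation
# distribution of U under random relabelling of the pooled sample (ties
# handled by midranks, so U counts tied pairs as 1/2):
#   p = P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|).
# The tail mass is computed by a shift-algorithm dynamic programme over
# doubled midranks (exact also under ties, where the classical tables do
# not apply), which is feasible far beyond direct enumeration.

.mwExactP <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))                       # midranks
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  d <- as.integer(round(2 * r))            # doubled midranks: integers
  maxS <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  # count[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  count <- matrix(0, n1 + 1L, maxS + 1L)
  count[1L, 1L] <- 1
  for (x in d) {
    kmax <- n1
    for (k in kmax:1) {
      shifted <- c(rep(0, x), count[k, seq_len(maxS + 1L - x)])
      count[k + 1L, ] <- count[k + 1L, ] + shifted
    }
  }
  sums <- 0:maxS
  uVals <- sums / 2 - n1 * (n1 + 1) / 2
  dev <- abs(uVals - n1 * n2 / 2)
  devObs <- abs(uObs - n1 * n2 / 2)
  tail <- sum(count[n1 + 1L, dev >= devObs - 1e-9])
  list(u = uObs, p = min(1, tail / choose(n, n1)))
}

.mwApproxP <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = uObs, p = 1))
  z <- (abs(uObs - n1 * n2 / 2) - 0.5) / sqrt(sigma2)  # continuity corrected
  list(u = uObs, p = min(1, 2 * pnorm(-max(0, z))))
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' U is computed by pair counting via midranks (tied pairs count 1/2).  The
#' two-sided p-value is exact -- the permutation tail mass
#' `P(|U - n1 n2/2| >= |U_obs - n1 n2/2|)` over all relabellings of the
#' pooled sample, valid under ties -- whenever `mode = "exact"`, or in
#' `"auto"` mode when `n1 * n2 <= 400`; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param a,b numeric samples (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return An object of class `"htest"`: `statistic` (U of sample `a`),
#'   `p.value`, `method`, `data.name`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  dname <- paste(deparse1(substitute(a)), "and", deparse1(substitute(b)))
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite")
  useExact <- mode == "exact" || (mode == "auto" && length(a) * length(b) <= 400)
  res <- if (useExact) .mwExactP(a, b) else .mwApproxP(a, b)
  structure(list(
    statistic = c(U = res$u),
    p.value = res$p,
    alternative = "two.sided",
    method = paste0("Mann-Whitney U test (",
                    if (useExact) "exact permutation" else
                      "normal approximation, tie and continuity corrected",
                    ")"),
    data.name = dname),
    class = "htest")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value: total hypergeometric probability, at fixed margins, of
#' the tables no more probable than the observed one.  Degenerate tables
#' with an all-zero margin return p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  fisher.test(table)$p.value
}

#' Mean and sample standard deviation of one group
#'
#' @param values numeric vector (NAs dropped) with at least one value.
#' @param variable optional variable name carried into the output.
#' @return data.frame with `variable`, `n`, `mean`, `sd`; `sd` is the
#'   sample (n - 1) standard deviation, reported as 0 with
#'   `singleValue = TRUE` when only one value is present.
#' @export
describeGroup <- function(values, variable = NA_character_) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise")
  data.frame(variable = variable, n = length(values), mean = mean(values),
             sd = if (length(values) > 1L) sd(values) else 0,
             singleValue = length(values) == 1L)
}

.reportVariables <- c(
  upperEuclidCm = "Mean EUC upper chest (cm)",
  lowerEuclidCm = "Mean EUC lower chest (cm)",
  euclidRatio = "EUC ratio",
  upperGeodesicCm = "Mean GEO upper chest (cm)",
  lowerGeodesicCm = "Mean GEO lower chest (cm)",
  geodesicRatio = "GEO ratio",
  cxrDist2Cm = "X-ray 2nd rib (cm)",
  cxrDist9Cm = "X-ray 9th rib (cm)",
  cxrRatio29 = "X-ray ratio 2nd/9th",
  cxrDist4Cm = "X-ray 4th rib (cm)",
  cxrDist8Cm = "X-ray 8th rib (cm)",
  cxrRatio48 = "X-ray ratio 4th/8th")

#' Two-group comparison report
#'
#' For every measurement variable present in the cohort (3D distances,
#' bell-shape ratios, radiograph distances and ratios) this computes group
#' means and SDs (cohort-level ratio summaries average per-subject ratios)
#' and the Mann-Whitney U test between the groups, flagging p < alpha.
#' Subjects missing a variable are dropped from that variable only, with
#' the per-group n reported.
#'
#' @param cohort data.frame with columns `subjectId`, `group` (exactly two
#'   levels) and any of: `upperEuclidCm`, `lowerEuclidCm`, `euclidRatio`,
#'   `upperGeodesicCm`, `lowerGeodesicCm`, `geodesicRatio`, `cxrDist2Cm`,
#'   `cxrDist4Cm`, `cxrDist8Cm`, `cxrDist9Cm`, `cxrRatio29`, `cxrRatio48`.
#' @param groups optional length-2 character giving the (reference,
#'   comparison) group order; defaults to sorted unique labels.
#' @param mode p-value mode passed to [mannWhitneyU()].
#' @param alpha significance level for the flag column.
#' @return data.frame with one row per variable: n, mean, sd per group, `U`,
#'   `p`, `method`, `significant`.
#' @export
compareGroups <- function(cohort, groups = NULL,
                          mode = c("auto", "exact", "approx"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (!all(c("subjectId", "group") %in% names(cohort)))
    stop("cohort needs 'subjectId' and 'group' columns")
  labs <- if (is.null(groups)) sort(unique(as.character(cohort$group))) else groups
  if (length(labs) != 2L || !all(labs %in% cohort$group))
    stop("both groups must be represented in the cohort")
  vars <- intersect(names(.reportVariables), names(cohort))
  if (!length(vars)) stop("no measurement variables found in the cohort")
  rows <- lapply(vars, function(v) {
    x <- cohort[cohort$group == labs[1], v]; x <- x[!is.na(x)]
    y <- cohort[cohort$group == labs[2], v]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
      return(data.frame(variable = v, label = .reportVariables[[v]],
                        n1 = length(x), mean1 = NA, sd1 = NA,
                        n2 = length(y), mean2 = NA, sd2 = NA,
                        U = NA, p = NA, method = "not testable",
                        significant = NA))
    s1 <- describeGroup(x); s2 <- describeGroup(y)
    ht <- mannWhitneyU(x, y, mode = mode)
    data.frame(variable = v, label = .reportVariables[[v]],
               n1 = s1$n, mean1 = s1$mean, sd1 = s1$sd,
               n2 = s2$n, mean2 = s2$mean, sd2 = s2$sd,
               U = unname(ht$statistic), p = ht$p.value, method = ht$method,
               significant = ht$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "n1"] <- paste0("n_", labs[1])
  names(out)[names(out) == "mean1"] <- paste0("mean_", labs[1])
  names(out)[names(out) == "sd1"] <- paste0("sd_", labs[1])
  names(out)[names(out) == "n2"] <- paste0("n_", labs[2])
  names(out)[names(out) == "mean2"] <- paste0("mean_", labs[2])
  names(out)[names(out) == "sd2"] <- paste0("sd_", labs[2])
  rownames(out) <- NULL
  out
}

#' Correlation utility (Pearson or Spearman)
#'
#' Provided for exploratory use; no correlation analysis is part of the
#' standard group report.
#'
#' @param x,y numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return An object of class `"htest"` from [stats::cor.test()].
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stats::cor.test(x, y, method = method, exact = FALSE)
}
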
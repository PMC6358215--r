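new_estimate <- function(point, se, n, ci, estimator) {
  structure(list(point = point, se = se, n = n,
                 ci_low = ci[1L], ci_high = ci[2L], estimator = estimator),
            class = "drive_estimate")
}

#' @export
print.drive_estimate <- function(x, ...) {
  cat(sprintf("<drive_estimate> %s: %.1f%% +/- %.1f%% (95%% CI %.1f-%.1f%%, n = %d)\n",
              x$estimator, 100 * x$point, 100 * x$se,
              100 * x$ci_low, 100 * x$ci_high, x$n))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes (0 <= successes <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level, default 0.95.
#' @return Numeric \code{c(low, high)}, both in [0, 1].
#' @examples
#' wilson_ci(50, 100)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == 1L, length(n) == 1L,
            successes >= 0, n >= 1, successes <= n,
            level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

ct_check <- function(t) {
  if (!inherits(t, "count_table")) stop("expected a count_table")
  t
}

proportion_estimate <- function(k, n, estimator) {
  if (n < 1)
    stop(sprintf("%s: undefined estimate, denominator is zero", estimator))
  p <- k / n
  new_estimate(p, sqrt(p * (1 - p) / n), n, wilson_ci(k, n), estimator)
}

#' Drive inheritance rate from a phenotype count table
#'
#' The fraction of scoreable offspring carrying the dsRed drive marker. For
#' designs where the drive-heterozygous parent transmits to all offspring
#' (maternal transmission, or paternal at an autosomal target) the
#' denominator is all offspring; for readouts of the paternal allele at an
#' X-linked target only daughters are informative
#' (\code{denominator = "daughters"}).
#'
#' @param t a \code{\link{count_table}}.
#' @param denominator \code{"all"} or \code{"daughters"}.
#' @return A \code{drive_estimate} (point, binomial SE, Wilson 95\% CI, n).
#' @export
drive_inheritance_rate <- function(t, denominator = c("all", "daughters")) {
  ct_check(t)
  denominator <- match.arg(denominator)
  rows <- if (denominator == "daughters") t$sex == "female" else rep(TRUE, nrow(t))
  n <- sum(t$count[rows])
  k <- sum(t$count[rows & t$dsred])
  proportion_estimate(k, n, "drive_inheritance_rate")
}

#' Drive conversion efficiency
#'
#' The fraction of wild-type (or synthetic-target) alleles converted to
#' drive alleles in the heterozygous germline, computed from the drive
#' inheritance rate p as 2p - 1. A Mendelian cross gives 0; estimates are not
#' clamped, so sub-Mendelian transmission yields a negative value. SE and CI
#' are the inheritance-rate uncertainties on the same 2p - 1 scale.
#'
#' @inheritParams drive_inheritance_rate
#' @return A \code{drive_estimate}.
#' @examples
#' t <- count_table(data.frame(sex = "female", dsred = c(TRUE, FALSE),
#'                             egfp = "not_applicable", body = "wild",
#'                             count = c(87L, 13L)))
#' conversion_efficiency(t)   # 2*0.87 - 1 = 0.74
#' @export
conversion_efficiency <- function(t, denominator = c("all", "daughters")) {
  e <- drive_inheritance_rate(t, denominator)
  new_estimate(2 * e$point - 1, 2 * e$se, e$n,
               c(2 * e$ci_low - 1, 2 * e$ci_high - 1),
               "conversion_efficiency")
}

#' Early-embryo r2 resistance rate, yellow-body readout
#'
#' For crosses of a drive-heterozygous female (depositing both Cas9 and
#' gRNA) to a male wild-type at an X-linked recessive body-marker target:
#' among dsRed daughters, whose maternal allele is the drive, a fully yellow
#' body means the paternal wild-type allele was disrupted in the early
#' embryo. The rate is (fully yellow dsRed daughters) / (dsRed daughters).
#' Mosaic-yellow daughters count in the denominator only (their paternal
#' allele keeps germline function).
#'
#' @param t a \code{\link{count_table}}.
#' @return A \code{drive_estimate}.
#' @export
embryo_r2_rate_yellow <- function(t) {
  ct_check(t)
  den_rows <- t$sex == "female" & t$dsred
  n <- sum(t$count[den_rows])
  k <- sum(t$count[den_rows & t$body == "yellow"])
  proportion_estimate(k, n, "embryo_r2_rate_yellow")
}

#' Early-embryo r2 resistance rate, EGFP readout
#'
#' For crosses of a drive/EGFP heterozygous female to an EGFP-homozygous
#' male (synthetic target site): among dsRed offspring, whose maternal
#' allele is the drive, complete loss of eye EGFP means the paternal EGFP
#' allele was disrupted in the early embryo. The rate is (dsRed offspring
#' with no EGFP) / (dsRed offspring); mosaic-EGFP offspring count in the
#' denominator only. For an autosomal target both sexes are informative
#' (\code{denominator = "all"}); for an X-linked synthetic target sons are
#' hemizygous for the maternal allele and show no EGFP whenever they carry
#' the drive, so only daughters read out the paternal allele
#' (\code{denominator = "daughters"}).
#'
#' @param t a \code{\link{count_table}}.
#' @param denominator \code{"all"} or \code{"daughters"}.
#' @return A \code{drive_estimate}.
#' @export
embryo_r2_rate_egfp <- function(t, denominator = c("all", "daughters")) {
  ct_check(t)
  denominator <- match.arg(denominator)
  den_rows <- t$dsred
  if (denominator == "daughters") den_rows <- den_rows & t$sex == "female"
  n <- sum(t$count[den_rows])
  k <- sum(t$count[den_rows & t$egfp == "none"])
  proportion_estimate(k, n, "embryo_r2_rate_egfp")
}

#' Germline r2 formation rate from sons
#'
#' For X-linked-target crosses with no embryo cutting in the offspring
#' generation, sons are hemizygous for a single maternal gamete, so a fully
#' yellow, dsRed-negative son directly reveals a maternal germline r2
#' gamete. Since non-converted maternal alleles are transmitted to half the
#' gametes, the per-wild-type-allele germline r2 rate is
#' 2 x (yellow non-dsRed sons) / (all sons).
#'
#' @param t a \code{\link{count_table}}.
#' @return A \code{drive_estimate} (SE and CI on the doubled scale).
#' @export
germline_r2_rate_sons <- function(t) {
  ct_check(t)
  son_rows <- t$sex == "male"
  n <- sum(t$count[son_rows])
  if (n < 1) stop("germline_r2_rate_sons: no sons in table")
  k <- sum(t$count[son_rows & !t$dsred & t$body == "yellow"])
  p <- k / n
  ci <- wilson_ci(k, n)
  new_estimate(2 * p, 2 * sqrt(p * (1 - p) / n), n, 2 * ci,
               "germline_r2_rate_sons")
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Computes the two-sided p-value by enumerating, at fixed margins, all
#' tables whose hypergeometric probability does not exceed that of the
#' observed table (the sum-of-small-p-values convention; ties accepted
#' within relative tolerance 1e-7).
#'
#' @param a,b,c,d the four cell counts, rows = groups, columns = outcome;
#'   alternatively \code{a} may be a 2x2 matrix.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)   # 34/70
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    b <- a[1L, 2L]; c0 <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  } else {
    c0 <- c
  }
  cells <- c(a, b, c0, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("fisher_exact_2x2: cells must be non-negative integers")
  if (sum(cells) == 0) {
    warning("fisher_exact_2x2: empty table, p = 1 by convention")
    return(1)
  }
  m <- a + b          # row 1 total
  n2 <- c0 + d        # row 2 total
  k <- a + c0         # column 1 total
  x <- max(0, k - n2):min(k, m)
  probs <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Jackknife standard error of a pooled estimate over crosses
#'
#' Leave-one-cross-out jackknife on a list of per-cross count tables:
#' flags overdispersion relative to the pooled binomial SE when broods
#' differ more than sampling alone allows.
#'
#' @param crosses list of per-cross \code{\link{count_table}}s (e.g. from
#'   \code{simulate_experiment(..., keep_crosses = TRUE)}).
#' @param estimator an estimator function mapping a count table to a
#'   \code{drive_estimate}.
#' @return A list with \code{point} (pooled estimate) and \code{se_jackknife}.
#' @export
jackknife_se <- function(crosses, estimator) {
  m <- length(crosses)
  if (m < 2L) stop("jackknife_se: need at least two crosses")
  pooled <- Reduce(merge_tallies, crosses)
  theta <- estimator(pooled)$point
  loo <- vapply(seq_len(m), function(i) {
    estimator(Reduce(merge_tallies, crosses[-i]))$point
  }, numeric(1))
  list(point = theta,
       se_jackknife = sqrt((m - 1) / m * sum((loo - mean(loo))^2)))
}
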
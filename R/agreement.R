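#' Lin's concordance correlation coefficient with confidence interval
#'
#' The agreement index of the study:
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with 1/n moment estimators (Lin 1989). The confidence interval uses the
#' inverse-hyperbolic-tangent (Fisher-type) transformation with Lin's
#' asymptotic standard error, back-transformed.
#'
#' Degenerate inputs: if both series are constant the coefficient is
#' undefined and the call fails; if exactly one series is constant the
#' formula gives 0, returned with `degenerate = TRUE` and an `NA` interval.
#'
#' @param x,y Paired measurement series (reference first: the mean
#'   difference convention elsewhere is `x - y`).
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return A one-row data.frame: `ccc`, `ci_lower`, `ci_upper`, `pearson_r`,
#'   `n`, `degenerate`.
#' @export
ccc <- function(x, y, conf_level = 0.95) {
  check_paired(x, y, min_n = 3L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)   # 1/n estimators, per Lin's definition
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) {
    stop("ccc: both series are constant; concordance undefined")
  }
  pc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  if (sx2 == 0 || sy2 == 0) {
    return(data.frame(ccc = pc, ci_lower = NA_real_, ci_upper = NA_real_,
                      pearson_r = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  # Lin's asymptotic variance of atanh(ccc) (1989, with the 2000 erratum)
  se_z2 <- ((1 - r^2) * pc^2 / ((1 - pc^2) * r^2) +
            4 * pc^3 * (1 - pc) * u^2 / (r * (1 - pc^2)^2) -
            2 * pc^4 * u^4 / (r^2 * (1 - pc^2)^2)) / (n - 2)
  z <- atanh(pc)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- q * sqrt(max(se_z2, 0))
  data.frame(ccc = pc, ci_lower = tanh(z - half), ci_upper = tanh(z + half),
             pearson_r = r, n = n, degenerate = FALSE)
}

#' Mean difference and its standard deviation
#'
#' `mean(x - y)` and the sample SD (n - 1 denominator) of the paired
#' differences, with `x` the first-listed series (histology proxy, or the
#' original virtual section) so the sign convention is first minus
#' comparator.
#'
#' @inheritParams ccc
#' @return A one-row data.frame: `mean_diff`, `sd_diff`, `n`.
#' @export
mean_diff_sd <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  d <- x - y
  data.frame(mean_diff = mean(d), sd_diff = stats::sd(d), n = length(d))
}

#' Bland-Altman agreement analysis
#'
#' Per pair, abscissa `(x + y)/2` and ordinate `x - y`; the bias is the mean
#' ordinate (the estimated systematic difference) and the 95% limits of
#' agreement are `bias +/- 1.96 * SD` of the ordinates (random fluctuation
#' around the bias).
#'
#' @inheritParams ccc
#' @return A list with `bias`, `sd`, `loa_lower`, `loa_upper`, and `points`
#'   (data.frame of per-pair `mean`, `diff`).
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  d <- x - y
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       points = data.frame(mean = (x + y) / 2, diff = d))
}

#' Intraclass correlation, two-way mixed, absolute agreement, single measure
#'
#' The comparator reliability statistic discussed against the concordance
#' coefficient: ICC(A,1) from the standard two-way mean-squares
#' decomposition with k = 2 raters,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`. Unlike the
#' concordance coefficient it presumes equal marginal distributions, which
#' is why the study prefers the latter.
#'
#' @inheritParams ccc
#' @return A one-row data.frame: `icc`, `n`.
#' @export
icc <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  n <- length(x); k <- 2
  grand <- mean(c(x, y))
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - row_means - col_means[1] + grand)^2) +
         sum((y - row_means - col_means[2] + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0) {
    stop(sprintf("icc: degenerate variance decomposition (MSR=%.3g, MSC=%.3g, MSE=%.3g)",
                 msr, msc, mse))
  }
  data.frame(icc = (msr - mse) / denom, n = n)
}

check_paired <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("paired series must have equal length")
  if (length(x) < min_n) {
    stop(sprintf("need at least %d pairs, got %d", min_n, length(x)))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("paired series must be finite")
  }
  invisible(TRUE)
}

# One row of the agreement tables: CCC + CI, mean diff +/- SD, limits of
# agreement, Pearson r.
agreement_row <- function(x, y, conf_level = 0.95) {
  cc <- ccc(x, y, conf_level = conf_level)
  md <- mean_diff_sd(x, y)
  ba <- bland_altman(x, y)
  data.frame(ccc = cc$ccc, ci_lower = cc$ci_lower, ci_upper = cc$ci_upper,
             mean_diff = md$mean_diff, sd_diff = md$sd_diff,
             loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
             pearson_r = cc$pearson_r, n = cc$n)
}

#' Study-style agreement table for one phase
#'
#' Reproduces the layout of the study's per-phase tables from a long
#' measurement data.frame: a "Comparison with HM" block (histology proxy
#' versus the original section and its four plane variants, 5 rows) and a
#' "Comparison with original MCT" block (original section versus the four
#' variants, 4 rows), 9 rows in the fixed order original, +4 offset,
#' -4 offset, +10 deg rotation, -10 deg rotation.
#'
#' @param measurements data.frame with columns `specimen`, `variant` (one of
#'   `"HM"`, `"original"`, `"offset+4"`, `"offset-4"`, `"rot+10"`,
#'   `"rot-10"`) and the percent-area columns; every specimen must carry all
#'   six variants.
#' @param phase `"bone"` or `"graft"` (the study tabulates these two).
#' @param conf_level Confidence level for the concordance CI.
#' @return data.frame of 9 agreement rows with `reference`, `comparator`
#'   columns; difference sign is reference minus comparator.
#' @export
agreement_table <- function(measurements, phase = c("bone", "graft"),
                            conf_level = 0.95) {
  phase <- match.arg(phase)
  col <- paste0("pct_", phase)
  stopifnot(all(c("specimen", "variant", col) %in% names(measurements)))
  variants <- c("HM", "original", "offset+4", "offset-4", "rot+10", "rot-10")
  specimens <- sort(unique(measurements$specimen))
  series <- lapply(variants, function(vv) {
    sub <- measurements[measurements$variant == vv, ]
    miss <- setdiff(specimens, sub$specimen)
    if (length(miss)) {
      stop(sprintf("agreement_table: specimen %s missing variant '%s'",
                   paste(miss, collapse = ", "), vv))
    }
    sub[[col]][match(specimens, sub$specimen)]
  })
  names(series) <- variants
  comparators <- c("original", "offset+4", "offset-4", "rot+10", "rot-10")
  rows <- list()
  for (ref in c("HM", "original")) {
    for (cmp in setdiff(comparators, ref)) {
      row <- agreement_row(series[[ref]], series[[cmp]],
                           conf_level = conf_level)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(reference = ref, comparator = cmp, phase = phase),
              row)
    }
  }
  do.call(rbind, rows)
}
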
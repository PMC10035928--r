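# Statistical layer: two-sample KS tests, Pearson correlation matrix,
# intraclass correlation reliability, BMI classification, group contrasts.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical
#' distribution functions. The p-value uses the exact small-sample
#' distribution when `n1 * n2 <= 10^4` (mode `"auto"`), and otherwise the
#' asymptotic Kolmogorov distribution with effective size
#' `n1 * n2 / (n1 + n2)`.
#'
#' @param x,y Numeric samples (each with at least 2 observations).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param alpha Significance level for the `significant` flag, default 0.05.
#' @return An object of class `ks_result`: list with `d`, `p`, `n1`, `n2`,
#'   `mode` (the p-value mode actually used) and `significant`
#'   (`p < alpha`).
#' @export
ks_two_sample <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                          alpha = 0.05) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop_input("each sample needs at least 2 observations")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_input("samples must be finite")
  }
  n1 <- length(x)
  n2 <- length(y)
  exact <- switch(mode,
    auto = n1 * n2 <= 1e4,
    exact = TRUE,
    asymptotic = FALSE
  )
  res <- suppressWarnings(ks.test(x, y, exact = exact))
  structure(
    list(
      d = unname(res$statistic),
      p = min(max(res$p.value, 0), 1),
      n1 = n1,
      n2 = n2,
      mode = if (exact) "exact" else "asymptotic",
      alpha = alpha,
      significant = res$p.value < alpha
    ),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "<ks_result> D = %.4f, p = %.4g (%s, n1=%d, n2=%d)%s\n",
    x$d, x$p, x$mode, x$n1, x$n2,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Strength category for a Pearson coefficient
#'
#' Strong for `|r| >= 0.5`, moderate for `0.3 <= |r| < 0.5`, low otherwise.
#'
#' @param r Pearson coefficient(s).
#' @return Character vector of categories (NA stays NA).
#' @export
correlation_strength <- function(r) {
  ifelse(is.na(r), NA_character_,
    ifelse(abs(r) >= 0.5, "strong",
      ifelse(abs(r) >= 0.3, "moderate", "low")
    )
  )
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Pearson r for every variable pair with the two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom. Zero-variance variables are
#' flagged (`r = NA`, `note = "zero variance"`) rather than propagating NaN.
#'
#' @param data Data frame of numeric subject-level variables.
#' @param vars Variables to correlate; default all numeric columns.
#' @return Data frame with one row per unordered pair: `var_a`, `var_b`, `n`,
#'   `r`, `p`, `strength`, `note`.
#' @export
pearson_matrix <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (length(vars) < 2L) stop_input("need at least two variables")
  if (nrow(data) < 4L) stop_input("need at least 4 complete subjects")
  combos <- utils::combn(vars, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    va <- combos[1, i]
    vb <- combos[2, i]
    xa <- data[[va]]
    xb <- data[[vb]]
    keep <- is.finite(xa) & is.finite(xb)
    xa <- xa[keep]
    xb <- xb[keep]
    base <- data.frame(
      var_a = va, var_b = vb, n = length(xa),
      r = NA_real_, p = NA_real_, strength = NA_character_,
      note = NA_character_, stringsAsFactors = FALSE
    )
    if (length(xa) < 4L) {
      base$note <- "fewer than 4 complete pairs"
      return(base)
    }
    if (var(xa) == 0 || var(xb) == 0) {
      base$note <- "zero variance"
      return(base)
    }
    ct <- cor.test(xa, xb, method = "pearson")
    base$r <- unname(ct$estimate)
    base$p <- ct$p.value
    base$strength <- correlation_strength(base$r)
    base
  })
  do.call(rbind, rows)
}

# Two-way mean squares for an n x k complete ratings matrix.
two_way_mean_squares <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  list(
    msr = ssr / (n - 1),
    msc = ssc / (k - 1),
    mse = sse / ((n - 1) * (k - 1)),
    n = n, k = k
  )
}

icc_agreement_category <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc > 0.81) "almost perfect"
  else if (icc > 0.60) "substantial"
  else if (icc > 0.40) "moderate"
  else if (icc > 0.20) "fair"
  else "slight"
}

#' Intraclass correlation between two selection sessions
#'
#' Single-measure two-way random-effects ICC. The default is the absolute
#' agreement form ICC(2,1),
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n),}
#' with the consistency form ICC(C,1) available behind `type =
#' "consistency"`. ICC above 0.81 is labelled "almost perfect" agreement.
#'
#' @param session1,session2 Matched coordinate vectors (one value per point,
#'   same order), n >= 3.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param axis Optional axis tag carried into the result.
#' @return An object of class `icc_result`: list with `icc`, `agreement`,
#'   `type`, `n`, `axis`.
#' @export
icc_two_session <- function(session1, session2,
                            type = c("agreement", "consistency"),
                            axis = NULL) {
  type <- match.arg(type)
  x1 <- as.numeric(session1)
  x2 <- as.numeric(session2)
  if (length(x1) != length(x2)) {
    stop_input("sessions must have matching lengths")
  }
  if (length(x1) < 3L) stop_input("ICC needs at least 3 matched points")
  y <- cbind(x1, x2)
  ms <- two_way_mean_squares(y)
  icc <- if (ms$msr == 0 && ms$mse == 0) {
    NA_real_ # degenerate: no variance anywhere
  } else if (type == "agreement") {
    (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
  } else {
    (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
  }
  structure(
    list(
      icc = icc,
      agreement = icc_agreement_category(icc),
      type = type,
      n = ms$n,
      axis = axis
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result>%s ICC(%s,1) = %.4f [%s], n = %d\n",
    if (!is.null(x$axis)) paste0(" ", x$axis) else "",
    if (x$type == "agreement") "2" else "C",
    x$icc, x$agreement, x$n
  ))
  invisible(x)
}

#' Body mass index and weight class
#'
#' BMI = weight (kg) / height (m)^2. Classes: underweight (BMI < 18.5),
#' healthy (18.5 to 24.9), overweight (BMI >= 25); the boundary values 18.5
#' and 25.0 fall into healthy and overweight respectively.
#'
#' @param weight_kg,height_m Positive numeric vectors.
#' @return Data frame with columns `bmi` and `bmi_class` (factor).
#' @export
bmi_and_class <- function(weight_kg, height_m) {
  if (any(!(weight_kg > 0)) || any(!(height_m > 0))) {
    stop_input("weight and height must be positive")
  }
  bmi <- weight_kg / height_m^2
  data.frame(bmi = bmi, bmi_class = bmi_class(bmi))
}

#' Classify BMI values
#'
#' @param bmi Numeric BMI values (kg/m2).
#' @return Factor with levels underweight, healthy, overweight.
#' @export
bmi_class <- function(bmi) {
  cut(bmi,
    breaks = c(-Inf, 18.5, 25, Inf),
    labels = c("underweight", "healthy", "overweight"),
    right = FALSE
  )
}

#' Percent change of a group mean between BMI classes
#'
#' `100 * (mean(to) - mean(from)) / mean(from)`.
#'
#' @param values Per-subject metric.
#' @param classes Class labels aligned with `values`.
#' @param from_class,to_class Class names to contrast.
#' @return Percent change (scalar); `NA` with a warning when the from-mean is
#'   zero.
#' @export
group_percent_change <- function(values, classes, from_class, to_class) {
  from <- values[classes == from_class & !is.na(values)]
  to <- values[classes == to_class & !is.na(values)]
  if (!length(from)) stop_input("empty class '", from_class, "'")
  if (!length(to)) stop_input("empty class '", to_class, "'")
  mf <- mean(from)
  if (mf == 0) {
    warning("from-class mean is zero; percent change undefined")
    return(NA_real_)
  }
  100 * (mean(to) - mf) / mf
}
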
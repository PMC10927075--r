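#' Paired Student's t-test on per-donor values
#'
#' Each donor contributes one (control, treated) pair — typically the mean of
#' a metric over that donor's images in each arm. The statistic is
#' \eqn{t = \bar d / (s_d / \sqrt n)} on the differences \eqn{d = treated -
#' control}, with \eqn{n - 1} degrees of freedom and a two-tailed p-value.
#'
#' @param control,treated numeric vectors of equal length (>= 2), matched by
#'   donor.
#' @return list of class \code{test_result}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{estimate} (mean difference), \code{test_name}.
#' @export
paired_t_test <- function(control, treated) {
  if (length(control) != length(treated))
    stop("control and treated must be matched (equal length)")
  n <- length(control)
  if (n < 2L) stop("need at least 2 donor pairs")
  if (any(is.na(control)) || any(is.na(treated)))
    stop("missing donor values")
  d <- treated - control
  sdd <- sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(structure(list(statistic = 0, df = n - 1L, p_value = 1,
                            estimate = 0, test_name = "paired t-test"),
                       class = "test_result"))
    stop("degenerate sample: zero variance of the paired differences")
  }
  t <- mean(d) / (sdd / sqrt(n))
  structure(list(
    statistic = t, df = n - 1L,
    p_value = 2 * pt(-abs(t), df = n - 1L),
    estimate = mean(d), test_name = "paired t-test"
  ), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test_name, x$statistic,
              paste(format(x$df), collapse = ", "), x$p_value))
  invisible(x)
}

#' Repeated-measures ANOVA with Tukey post-hoc comparisons
#'
#' One-way repeated-measures F-test for k matched conditions (subject as
#' block): \eqn{F = MS_{cond} / MS_{error}} with degrees of freedom
#' \eqn{(k-1, (k-1)(n-1))}, followed by Tukey HSD on the condition means
#' using the within-subject error mean square and the studentized-range
#' distribution.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns
#'   (no missing cells), or a data.frame thereof.
#' @return list of class \code{rm_anova_result}: \code{omnibus}
#'   (a \code{test_result}), \code{tukey} (data.frame of pairwise adjusted
#'   p-values), \code{ms_error}, \code{means}, \code{degenerate}.
#' @export
rm_anova_tukey <- function(values) {
  m <- as.matrix(values)
  if (any(is.na(m))) stop("missing cells are not supported")
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("need at least 2 matched conditions")
  if (n < 2L) stop("need at least 2 subjects")
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(k))
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_subj <- k * sum((row_m - gm)^2)
  ss_cond <- n * sum((col_m - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  degenerate <- ss_cond <= .Machine$double.eps * max(1, ss_tot)
  f <- if (degenerate) 0 else ms_cond / ms_err
  p <- if (degenerate) 1 else pf(f, df1, df2, lower.tail = FALSE)
  omnibus <- structure(list(statistic = f, df = c(df1, df2), p_value = p,
                            estimate = NA_real_,
                            test_name = "repeated-measures ANOVA"),
                       class = "test_result")
  pairs <- utils::combn(k, 2L)
  tukey <- data.frame(
    group1 = colnames(m)[pairs[1L, ]],
    group2 = colnames(m)[pairs[2L, ]],
    diff = col_m[pairs[2L, ]] - col_m[pairs[1L, ]],
    q = NA_real_, p_adj = NA_real_
  )
  se <- sqrt(ms_err / n)
  for (i in seq_len(ncol(pairs))) {
    q <- abs(tukey$diff[i]) / se
    tukey$q[i] <- q
    tukey$p_adj[i] <- if (ms_err == 0) as.numeric(tukey$diff[i] == 0) else
      ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
  }
  rownames(tukey) <- NULL
  structure(list(omnibus = omnibus, tukey = tukey, ms_error = ms_err,
                 means = col_m, degenerate = degenerate),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  print(x$omnibus)
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Type-I error calibration of the paired design at summary level
#'
#' Simulates the donor-level summary values of a null paired experiment
#' (treatment effect 1): each donor has a log-normal offset shared by both
#' arms, and each arm value adds independent within-donor sampling noise
#' (the standard error of a mean over \code{images_per_arm} images). The
#' fraction of replicates rejected by the paired t-test at \code{alpha} is
#' returned; under the null it should sit at the nominal level.
#'
#' @param n_reps simulation replicates.
#' @param n_donors donors per replicate.
#' @param images_per_arm images averaged per donor value.
#' @param cv_image per-image coefficient of variation of the metric.
#' @param donor_sdlog donor-level log-normal sdlog.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return rejection rate (numeric scalar) with attribute \code{n_reps}.
#' @export
simulate_null_rejection <- function(n_reps = 1000L, n_donors = 6L,
                                    images_per_arm = 8L, cv_image = 0.2,
                                    donor_sdlog = 0.15, alpha = 0.05,
                                    seed = 1L) {
  rate <- withr::with_seed(seed, {
    se_arm <- cv_image / sqrt(images_per_arm)
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      donor <- rlnorm(n_donors, 0, donor_sdlog)
      ctrl <- donor * (1 + rnorm(n_donors, 0, se_arm))
      trt <- donor * (1 + rnorm(n_donors, 0, se_arm))
      rej[r] <- paired_t_test(ctrl, trt)$p_value < alpha
    }
    mean(rej)
  })
  attr(rate, "n_reps") <- n_reps
  rate
}
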
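#' Condition brain scores with bootstrap confidence intervals
#'
#' Centers the per-scan LV brain scores by the grand mean over all scans,
#' then summarizes each group-by-season condition by its mean and a
#' percentile bootstrap 95% confidence interval (resampling scans within
#' each condition).
#'
#' The grand mean is the mean over all scans, not the unweighted mean of
#' the four condition means; with unequal group sizes the two differ, and
#' `center` switches between the conventions.
#'
#' @param scores a `brain_scores` object carrying a design, or a numeric
#'   vector of per-scan scores with `design` supplied.
#' @param design a [cohort_design()] (needed when `scores` is a vector).
#' @param lv which latent variable's scores to summarize (default 1).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param center `"scans"` (grand mean over scans, default) or
#'   `"condition_means"` (unweighted mean of condition means).
#' @return A `condition_scores` object: list with `table` (condition, n,
#'   mean, ci_low, ci_high), `centered` (per-scan centered scores),
#'   `design`, `grand_mean`.
#' @export
condition_brain_scores <- function(scores, design = NULL, lv = 1L,
                                   n_boot = 1000L, seed = 1L, conf = 0.95,
                                   center = c("scans", "condition_means")) {
  center <- match.arg(center)
  if (inherits(scores, "brain_scores")) {
    if (is.null(design)) design <- scores$row_design
    scores <- scores$scores[, lv]
  }
  if (is.null(design)) stop("a cohort_design is required")
  stopifnot(inherits(design, "cohort_design"),
            length(scores) == nrow(design))
  if (n_boot < 1L) stop("`n_boot` must be >= 1")
  cond <- factor(paste(design$group, design$season, sep = "."),
                 levels = design_cells())
  if (any(table(cond) == 0L))
    stop("empty condition: ",
         paste(levels(cond)[table(cond) == 0L], collapse = ", "))
  grand <- if (center == "scans") mean(scores)
  else mean(tapply(scores, cond, mean))
  centered <- scores - grand

  set.seed(seed)
  alpha <- (1 - conf) / 2
  rows <- lapply(levels(cond), function(cl) {
    x <- centered[cond == cl]
    bm <- vapply(seq_len(n_boot), function(b)
      mean(sample(x, length(x), replace = TRUE)), 0)
    ci <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
    data.frame(condition = cl, n = length(x), mean = mean(x),
               ci_low = ci[1], ci_high = ci[2])
  })
  structure(
    list(table = do.call(rbind, rows), centered = centered,
         design = design, grand_mean = grand),
    class = "condition_scores"
  )
}

#' @export
print.condition_scores <- function(x, ...) {
  cat("<condition_scores> grand mean", signif(x$grand_mean, 4), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# The six condition contrasts, in fixed reporting order; within-group
# season comparisons are paired on subject.
contrast_spec <- function() {
  list(
    list(a = "nonSAD.summer", b = "nonSAD.winter", paired = TRUE),
    list(a = "SAD.summer",    b = "SAD.winter",    paired = TRUE),
    list(a = "nonSAD.summer", b = "SAD.summer",    paired = FALSE),
    list(a = "nonSAD.summer", b = "SAD.winter",    paired = FALSE),
    list(a = "nonSAD.winter", b = "SAD.summer",    paired = FALSE),
    list(a = "nonSAD.winter", b = "SAD.winter",    paired = FALSE)
  )
}

#' Pairwise condition contrasts on brain scores
#'
#' Tests the six pairwise group-by-season contrasts: within-group seasonal
#' comparisons by paired t-tests (paired on subject), all others by
#' two-sample pooled-variance (Student) t-tests.  The Bonferroni column is
#' the uncorrected p multiplied by exactly 6 and deliberately NOT capped at
#' 1, so the reported value is the raw multiple of the uncorrected p.
#'
#' @param scores a `condition_scores` object (or numeric per-scan scores
#'   with `design`).
#' @param design a [cohort_design()] if `scores` is a vector.
#' @return Data frame with columns `contrast`, `paired`, `t`, `df`,
#'   `p_uncorrected`, `p_bonferroni`.
#' @export
contrast_tests <- function(scores, design = NULL) {
  if (inherits(scores, "condition_scores")) {
    design <- scores$design
    x <- scores$centered
  } else {
    x <- as.numeric(scores)
  }
  stopifnot(inherits(design, "cohort_design"), length(x) == nrow(design))
  cond <- paste(design$group, design$season, sep = ".")
  cs <- contrast_spec()
  rows <- lapply(cs, function(ct) {
    ia <- which(cond == ct$a)
    ib <- which(cond == ct$b)
    if (ct$paired) {
      sa <- design$subject[ia]
      sb <- design$subject[ib]
      if (!setequal(sa, sb))
        stop("cannot pair ", ct$a, " vs ", ct$b,
             ": subject sets differ")
      ib <- ib[match(sa, sb)]
      tt <- stats::t.test(x[ia], x[ib], paired = TRUE)
    } else {
      tt <- stats::t.test(x[ia], x[ib], var.equal = TRUE)
    }
    data.frame(contrast = paste(ct$a, "vs", ct$b),
               paired = ct$paired,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_uncorrected = tt$p.value,
               p_bonferroni = tt$p.value * length(cs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample pooled t-test from printed summary statistics
#'
#' Recomputes a two-sample Student t-test (pooled variance,
#' `df = n1 + n2 - 2`, two-sided) from group means, SDs and sizes, as
#' printed in a demographics table.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (`n1 >= 2`,
#'   `sd1 >= 0`).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("both SDs are zero but the means differ; t is undefined")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
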
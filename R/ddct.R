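# Relative expression by 2^-ddCt, amplification efficiencies from standard
# curves, and normality-gated two-group comparisons.
#
# Model: a replicate's quantification cycle Cq falls by one for every
# doubling of starting template (amplification factor E per cycle; E = 2 for
# a perfect reaction). Normalizing the target gene to a reference gene
# (dCt = Cq_target - Cq_reference) cancels input differences; normalizing to
# the calibrator group's mean dCt (ddCt) scales the calibrator to 1; the
# per-replicate fold change is then 2^-ddCt, or the Pfaffl efficiency-
# corrected ratio when per-gene efficiencies are supplied.

#' Fit a qPCR standard curve and derive amplification efficiency
#'
#' Ordinary least squares of Cq on log10 template amount. A perfect
#' doubling reaction has slope `-1/log10(2) ~ -3.3219`; the amplification
#' factor is `E = 10^(-1/slope)`.
#'
#' @param points data.frame with columns `log10_amount` and `cq` (at least
#'   3 points over at least 2 distinct dilutions).
#' @param gene optional gene label.
#' @return a `standard_curve`: `gene`, `points`, `slope` (cycles per log10
#'   unit), `intercept`, `r2`, `efficiency` (amplification factor per
#'   cycle), `valid` (FALSE for a non-negative slope), `flagged` (TRUE when
#'   `efficiency` falls outside the plausible `(1, 2.5]` range).
#' @export
fit_standard_curve <- function(points, gene = NA_character_) {
  if (!all(c("log10_amount", "cq") %in% names(points))) {
    stop("points needs columns 'log10_amount' and 'cq'", call. = FALSE)
  }
  if (nrow(points) < 3L) {
    stop("a standard curve needs at least 3 points", call. = FALSE)
  }
  if (length(unique(points$log10_amount)) < 2L) {
    stop("all dilutions are equal; cannot fit a slope", call. = FALSE)
  }
  fit <- lm(cq ~ log10_amount, data = points)
  slope <- unname(coef(fit)[["log10_amount"]])
  if (abs(slope) < 1e-9) {  # flat series: lm slope is zero up to rounding
    stop("standard curve has zero slope: efficiency undefined", call. = FALSE)
  }
  eff <- 10^(-1 / slope)
  valid <- slope < 0
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(
    list(gene = gene, points = points, slope = slope,
         intercept = unname(coef(fit)[[1L]]),
         r2 = r2, efficiency = eff, valid = valid,
         flagged = !valid || eff <= 1 || eff > 2.5),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve%s: slope %.4f, E = %.3f, R2 = %.4f%s\n",
    if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
    x$slope, x$efficiency, x$r2,
    if (x$flagged) " (FLAGGED)" else ""
  ))
  invisible(x)
}

#' Amplification factor from a standard-curve slope
#'
#' @param slope cycles per log10 template unit (negative for a valid
#'   dilution series).
#' @return `E = 10^(-1/slope)`.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) stop("slope of zero has no defined efficiency", call. = FALSE)
  10^(-1 / slope)
}

#' Read a Cq table
#'
#' Delimited text with header `sample,group,gene,replicate,cq` (comma or
#' tab separated, detected from the header line).
#'
#' @param path input file.
#' @return data.frame with those five columns; `cq` numeric.
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("Cq table not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  required <- c("sample", "group", "gene", "replicate", "cq")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("Cq table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df$cq <- as.numeric(df$cq)
  if (anyNA(df$cq) || any(df$cq <= 0)) {
    stop("cq values must be positive numbers", call. = FALSE)
  }
  df[required]
}

#' Relative expression by the 2^-ddCt method
#'
#' Per biological replicate, `dCt = Cq_gene - Cq_reference`; `ddCt` subtracts
#' the calibrator group's mean `dCt`; the per-replicate fold change is
#' `2^-ddCt`, or the Pfaffl efficiency-corrected ratio
#' `E_gene^(dCq_gene) / E_ref^(dCq_ref)` (each `dCq` relative to the
#' calibrator-group mean Cq of that gene) when per-gene efficiencies are
#' supplied. Technical replicates (duplicated `(sample, gene, replicate)`
#' rows) are averaged before dCt.
#'
#' Because fold changes are log-normal under Gaussian cycle noise, the
#' summary `mean_fold` is the geometric mean (so the calibrator group's own
#' mean fold is exactly 1 and the estimator is unbiased for the true fold);
#' the arithmetic mean and its SEM, as usually drawn on bar plots, are
#' reported alongside. The 95% CI is a Student-t interval with n-1 df on
#' log2 folds, back-transformed.
#'
#' @param records Cq data.frame (see [read_cq_table()]).
#' @param gene gene of interest.
#' @param reference_gene stably-expressed normalizer gene.
#' @param group treatment group to quantify.
#' @param calibrator_group baseline group scaled to fold 1.
#' @param efficiencies optional named numeric vector of per-gene
#'   amplification factors (e.g. `c(geneX = 1.97, tubulin = 2.01)`); genes
#'   missing from it default to 2 (the Livak assumption).
#' @return an `expression_result`: `per_replicate_folds`, `n`, `mean_fold`
#'   (geometric), `mean_fold_arith`, `sem` (SEM of arithmetic folds),
#'   `ci95`, `percent_of_control` (geometric mean x 100),
#'   `percent_of_control_ratio_means` (ratio of arithmetic group means x
#'   100), plus the labels used.
#' @export
delta_delta_ct <- function(records, gene, reference_gene, group,
                           calibrator_group, efficiencies = NULL) {
  required <- c("sample", "group", "gene", "replicate", "cq")
  stopifnot(all(required %in% names(records)))
  e_of <- function(g) {
    if (!is.null(efficiencies) && g %in% names(efficiencies)) {
      e <- efficiencies[[g]]
      if (e <= 1) stop(sprintf("efficiency for '%s' must exceed 1", g), call. = FALSE)
      e
    } else 2
  }
  # average technical replicates
  agg <- stats::aggregate(cq ~ sample + group + gene + replicate,
                          data = records, FUN = mean)
  unit_cq <- function(grp, g) {
    rows <- agg[agg$group == grp & agg$gene == g, , drop = FALSE]
    rows[order(rows$sample, rows$replicate), , drop = FALSE]
  }
  fold_units <- function(grp) {
    tg <- unit_cq(grp, gene)
    rf <- unit_cq(grp, reference_gene)
    if (nrow(tg) == 0L) {
      stop(sprintf("no Cq records for gene '%s' in group '%s'", gene, grp),
           call. = FALSE)
    }
    key <- function(d) paste(d$sample, d$replicate, sep = "\r")
    miss <- setdiff(key(tg), key(rf))
    if (length(miss) > 0L) {
      stop(sprintf("sample '%s' lacks a reference-gene (%s) Cq",
                   sub("\r.*", "", miss[[1L]]), reference_gene), call. = FALSE)
    }
    rf <- rf[match(key(tg), key(rf)), , drop = FALSE]
    list(target = tg$cq, ref = rf$cq)
  }
  cal <- fold_units(calibrator_group)
  if (length(cal$target) == 0L) {
    stop(sprintf("calibrator group '%s' is empty", calibrator_group),
         call. = FALSE)
  }
  grp <- fold_units(group)
  e_t <- e_of(gene)
  e_r <- e_of(reference_gene)
  # Pfaffl ratio relative to calibrator-group mean Cq of each gene;
  # reduces to 2^-ddCt when both efficiencies are 2.
  folds <- e_t^(mean(cal$target) - grp$target) / e_r^(mean(cal$ref) - grp$ref)
  cal_folds <- e_t^(mean(cal$target) - cal$target) / e_r^(mean(cal$ref) - cal$ref)
  n <- length(folds)
  log2f <- log2(folds)
  mean_fold <- 2^mean(log2f)
  sem <- if (n > 1L) sd(folds) / sqrt(n) else NA_real_
  ci95 <- if (n > 1L && sd(log2f) > 0) {
    2^(mean(log2f) + qt(c(0.025, 0.975), df = n - 1L) * sd(log2f) / sqrt(n))
  } else {
    c(mean_fold, mean_fold)
  }
  structure(
    list(gene = gene, reference_gene = reference_gene, group = group,
         calibrator_group = calibrator_group,
         efficiencies = c(gene = e_t, reference = e_r),
         per_replicate_folds = unname(folds), n = n,
         mean_fold = mean_fold, mean_fold_arith = mean(folds), sem = sem,
         ci95 = ci95,
         percent_of_control = 100 * mean_fold,
         percent_of_control_ratio_means = 100 * mean(folds) / mean(cal_folds)),
    class = "expression_result"
  )
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf(
    "%s in %s vs %s (ref %s): fold %.3f (%.1f%% of control), n = %d\n",
    x$gene, x$group, x$calibrator_group, x$reference_gene, x$mean_fold,
    x$percent_of_control, x$n
  ))
  if (!is.na(x$sem)) {
    cat(sprintf("  arithmetic mean %.3f +/- %.3f SEM, CI95 [%.3f, %.3f]\n",
                x$mean_fold_arith, x$sem, x$ci95[[1L]], x$ci95[[2L]]))
  }
  invisible(x)
}

#' Compare two groups of fold changes with a normality-gated test
#'
#' Shapiro-Wilk on each group; when both retain normality at `alpha` the
#' groups are compared with an unpaired two-sided Student's t-test (equal
#' variances), otherwise with a two-sided Mann-Whitney U test. A constant
#' group (Shapiro-Wilk undefined) forces Mann-Whitney and is flagged.
#'
#' @param folds_a,folds_b numeric vectors, each of length >= 3.
#' @param alpha significance level for both the normality gate and the
#'   comparison (0.05).
#' @param labels optional c(name_a, name_b).
#' @return a `group_comparison`: `normality_p_a`, `normality_p_b`,
#'   `test_used` (`"t_test"` or `"mann_whitney"`), `p_value`, `significant`
#'   (`p < alpha`), `degenerate` (constant group encountered).
#' @export
compare_groups <- function(folds_a, folds_b, alpha = 0.05,
                           labels = c("A", "B")) {
  if (length(folds_a) < 3L || length(folds_b) < 3L) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  shapiro_p <- function(x) {
    if (length(unique(x)) == 1L) return(NA_real_)
    shapiro.test(x)$p.value
  }
  p_a <- shapiro_p(folds_a)
  p_b <- shapiro_p(folds_b)
  degenerate <- is.na(p_a) || is.na(p_b)
  normal <- !degenerate && p_a >= alpha && p_b >= alpha
  if (normal) {
    test_used <- "t_test"
    p <- t.test(folds_a, folds_b, var.equal = TRUE)$p.value
  } else {
    test_used <- "mann_whitney"
    p <- suppressWarnings(wilcox.test(folds_a, folds_b, exact = NULL)$p.value)
  }
  structure(
    list(label_a = labels[[1L]], label_b = labels[[2L]],
         normality_p_a = p_a, normality_p_b = p_b, test_used = test_used,
         p_value = p, significant = p < alpha, degenerate = degenerate),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: %s p = %.4g%s%s\n", x$label_a, x$label_b,
    if (x$test_used == "t_test") "Student's t" else "Mann-Whitney U",
    x$p_value, if (x$significant) " *" else "",
    if (x$degenerate) " (constant group: normality gate skipped)" else ""
  ))
  invisible(x)
}
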
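# Nonparametric paired comparisons across experimental conditions.

#' Compare paired outcomes across two or three conditions
#'
#' The decision procedure used for all condition comparisons: normality is
#' assessed per condition with the Shapiro-Wilk test and reported, but the
#' nonparametric path is always taken. Two conditions are compared with the
#' Wilcoxon signed-rank test (exact null for small samples without ties,
#' normal approximation with continuity correction otherwise; alpha = 0.05).
#' Three conditions are compared with the Friedman test (alpha = 0.05) and,
#' if significant, pairwise Wilcoxon signed-rank tests with a
#' Bonferroni-adjusted pairwise threshold of alpha = 0.017.
#'
#' @param data a data frame or matrix with one column per condition and one
#'   row per specimen (paired observations), or a named list of equal-length
#'   vectors.
#' @param alternative alternative hypothesis passed to the two-condition
#'   Wilcoxon test (default two-sided).
#' @return A list of class `condition_comparison` with elements
#'   `n_conditions`, `n`, `shapiro` (per-condition p-values), and either
#'   `wilcoxon` (2 conditions: statistic `V`, `p`, `significant` at 0.05) or
#'   `friedman` (statistic, `p`, `significant`) plus `pairwise` (data frame
#'   of pairwise Wilcoxon results judged at `alpha_pairwise` = 0.017;
#'   only populated when the Friedman test is significant).
#' @examples
#' x <- cbind(up = rnorm(10, 10), down = rnorm(10, 12), horiz = rnorm(10, 15))
#' compare_conditions(x)
#' @export
compare_conditions <- function(data, alternative = "two.sided") {
  if (is.list(data) && !is.data.frame(data)) data <- as.data.frame(data)
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("compare_conditions: conditions must be numeric")
  k <- ncol(m)
  if (k < 2 || k > 3) stop("compare_conditions: need 2 or 3 conditions")
  if (anyNA(m)) stop("compare_conditions: unpaired data (missing values)")
  n <- nrow(m)
  if (n < 5) stop("compare_conditions: need at least 5 paired specimens")
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(k))

  shapiro <- apply(m, 2, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  })

  out <- list(n_conditions = k, n = n, shapiro = shapiro,
              alpha = 0.05, alpha_pairwise = 0.017)
  if (k == 2) {
    w <- wilcoxon_signed_rank(m[, 1], m[, 2], alternative)
    out$wilcoxon <- c(w, list(significant = is.finite(w$p) && w$p < 0.05))
  } else {
    fr <- stats::friedman.test(m)
    stat <- unname(fr$statistic); pval <- fr$p.value
    if (!is.finite(stat) && all(apply(m, 1, stats::sd) == 0)) {
      # every specimen identical across conditions: no evidence of any effect
      stat <- 0; pval <- 1
    }
    sig <- is.finite(pval) && pval < 0.05
    pairs <- utils::combn(k, 2)
    pw <- NULL
    if (sig) {
      pw <- do.call(rbind, apply(pairs, 2, function(ij) {
        w <- wilcoxon_signed_rank(m[, ij[1]], m[, ij[2]], "two.sided")
        data.frame(cond1 = colnames(m)[ij[1]], cond2 = colnames(m)[ij[2]],
                   V = w$V, p = w$p, significant = is.finite(w$p) & w$p < 0.017)
      }))
    }
    out$friedman <- list(statistic = stat, p = pval, significant = sig)
    out$pairwise <- pw
  }
  class(out) <- "condition_comparison"
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Thin wrapper over the signed-rank test with the policy used throughout
#' the package: exact null distribution for small samples without ties or
#' zero differences (n < 50), normal approximation with continuity
#' correction otherwise. For n paired observations the exact two-sided
#' p-value is a multiple of 2^(1-n) and matches full enumeration of the
#' 2^n sign assignments.
#'
#' @param x,y paired observation vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `V` (signed-rank statistic), `p`, and `exact`
#'   (whether the exact null was used).
#' @examples
#' wilcoxon_signed_rank(c(3, 5, 4), c(1, 2, 3.5), "greater")$p  # 1/8
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided") {
  d <- x - y
  if (all(d == 0)) return(list(V = 0, p = 1, exact = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = alternative,
                                            exact = TRUE, correct = TRUE))
  ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
  list(V = unname(wt$statistic), p = wt$p.value,
       exact = sum(d != 0) < 50 && !ties)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %d conditions, n = %d paired specimens\n",
              x$n_conditions, x$n))
  cat("  Shapiro-Wilk p:", paste(sprintf("%s = %.3f", names(x$shapiro), x$shapiro),
                                 collapse = ", "), "\n")
  if (x$n_conditions == 2) {
    cat(sprintf("  Wilcoxon signed-rank: V = %g, p = %.4g%s\n", x$wilcoxon$V,
                x$wilcoxon$p, if (x$wilcoxon$significant) " *" else ""))
  } else {
    cat(sprintf("  Friedman: chi^2 = %.3f, p = %.4g%s\n",
                x$friedman$statistic, x$friedman$p,
                if (x$friedman$significant) " *" else ""))
    if (!is.null(x$pairwise)) {
      for (i in seq_len(nrow(x$pairwise)))
        cat(sprintf("    %s vs %s: V = %g, p = %.4g%s  (alpha = 0.017)\n",
                    x$pairwise$cond1[i], x$pairwise$cond2[i], x$pairwise$V[i],
                    x$pairwise$p[i], if (x$pairwise$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}
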
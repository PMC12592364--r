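#' Two-tailed Mann-Whitney U test
#'
#' The statistic is `U = #\{(i,j): x_i > y_j\} + 0.5 * #ties`, computed via
#' the rank-sum identity. The two-tailed p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' Modes: `"exact"` enumerates the permutation null — through the exact
#' Wilcoxon distribution when there are no ties, or full enumeration of all
#' `choose(n1+n2, n1)` group assignments when there are (falling back to the
#' normal approximation with a warning if that enumeration is infeasible);
#' `"normal"` uses the normal approximation with tie and continuity
#' corrections; `"auto"` (default) is exact when `n1 * n2 <= 400`, normal
#' otherwise. Two identical samples give p = 1.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param enum_limit Maximum number of assignments enumerated in the tied
#'   exact path.
#' @return Object of class `mwu_test`: `U`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           enum_limit = 5e5) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  check_that(length(x) >= 1 && length(y) >= 1,
             "both samples must be non-empty")
  check_that(all(is.finite(c(x, y))), "samples must be finite")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = n1 * n2 <= 400)
  method <- NULL
  if (use_exact && !ties) {
    plo <- pwilcox(u, n1, n2)
    phi <- 1 - pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(plo, phi))
    method <- "exact"
  } else if (use_exact && ties) {
    n_comb <- choose(n1 + n2, n1)
    if (n_comb <= enum_limit) {
      sel <- utils::combn(n1 + n2, n1)
      base <- n1 * (n1 + 1) / 2
      u_all <- colSums(matrix(r[sel], nrow = n1)) - base
      eps <- 1e-9
      plo <- mean(u_all <= u + eps)
      phi <- mean(u_all >= u - eps)
      p <- min(1, 2 * min(plo, phi))
      method <- "exact-enumeration"
    } else {
      warning("tied exact test infeasible (", n_comb,
              " assignments); using the normal approximation")
      use_exact <- FALSE
    }
  }
  if (!use_exact) {
    n <- n1 + n2
    t_counts <- table(pooled)
    tie_term <- sum(t_counts^3 - t_counts)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(U = u, p = p, n1 = n1, n2 = n2, method = method),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-tailed p = %g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at
#' 1, returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals Numeric p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  check_that(all(pvals[ok] >= 0 & pvals[ok] <= 1),
             "p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Significance stars
#'
#' `"***"` for q <= 0.001, `"**"` for q <= 0.01, `"*"` for q <= 0.05
#' (all thresholds inclusive), `"ns"` otherwise.
#'
#' @param q Adjusted p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
star_code <- function(q) {
  check_that(all(is.na(q) | (q >= 0 & q <= 1)), "q must be in [0, 1]")
  ifelse(is.na(q), NA_character_,
         ifelse(q <= 0.001, "***",
                ifelse(q <= 0.01, "**",
                       ifelse(q <= 0.05, "*", "ns"))))
}
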
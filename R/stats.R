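#' Compare ASL heights between two groups
#'
#' Two-tailed unpaired or paired Student's t-test, or Wilcoxon signed rank
#' test, on per-well values. A degenerate paired comparison (all
#' differences zero) is reported as no effect (statistic 0, p = 1) rather
#' than an error.
#'
#' @param a,b Numeric vectors of per-well heights (um); paired tests
#'   require equal lengths.
#' @param test One of `"unpaired_t"`, `"paired_t"`,
#'   `"wilcoxon_signed_rank"`.
#' @return One-row tibble: `test`, `n_a`, `n_b`, `estimate` (difference of
#'   means, a - b), `statistic`, `p_value`.
#' @export
compare_groups <- function(a, b,
                           test = c("unpaired_t", "paired_t",
                                    "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  paired <- test %in% c("paired_t", "wilcoxon_signed_rank")
  if (paired && length(a) != length(b)) {
    stop("paired tests require equal group sizes", call. = FALSE)
  }
  if (paired && all(a - b == 0)) {
    return(tibble::tibble(test = test, n_a = length(a), n_b = length(b),
                          estimate = 0, statistic = 0, p_value = 1))
  }
  ht <- switch(test,
    unpaired_t = stats::t.test(a, b, paired = FALSE, var.equal = FALSE),
    paired_t = stats::t.test(a, b, paired = TRUE),
    wilcoxon_signed_rank = stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE)
  )
  tibble::tibble(
    test = test, n_a = length(a), n_b = length(b),
    estimate = mean(a) - mean(b),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Two-stage step-up FDR adjustment (Benjamini-Krieger-Yekutieli)
#'
#' Adaptive two-stage linear step-up procedure: a first Benjamini-Hochberg
#' pass at level `alpha / (1 + alpha)` estimates the number of true null
#' hypotheses `m0`; the second pass is sharpened by `m0 / m`. Returned
#' adjusted p-values are specific to `alpha` and reject when
#' `adjusted <= alpha`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Target FDR level (default 0.05).
#' @return Adjusted p-values, same order as the input, clipped at 1.
#' @export
bky_adjust <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  fact <- 1 + alpha
  alpha_prime <- alpha / fact
  bh <- stats::p.adjust(p, method = "BH")
  r1 <- sum(bh <= alpha_prime)
  adj <- if (r1 == 0 || r1 == m) {
    bh * fact
  } else {
    bh * ((m - r1) / m) * fact
  }
  pmin(adj, 1)
}

#' Treated group mean as percent of control
#'
#' @param treated_mean,control_mean Group means (um); control must be > 0.
#' @return `100 * treated_mean / control_mean`.
#' @export
percent_of_control <- function(treated_mean, control_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0", call. = FALSE)
  100 * treated_mean / control_mean
}
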
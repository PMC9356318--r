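#' Test a contingency table for differences in distribution
#'
#' Two-sided test of independence for a contingency table of counts,
#' following the usual small-sample rule: Pearson's chi-squared test
#' (without continuity correction) when every expected cell count is at
#' least 5, otherwise Fisher's exact test (Cochran's rule).
#'
#' @param table A matrix of nonnegative integer counts (at least 2 x 2),
#'   or a data frame coercible to one (an optional first character column
#'   is used as row labels).
#' @param alpha Significance threshold; default 0.05.
#' @return One-row tibble: `method` (`"chisq"` or `"fisher"`),
#'   `statistic` (`NA` for Fisher), `df` (`NA` for Fisher), `p_value`,
#'   `significant`.
#' @export
#' @examples
#' contingency_test(matrix(c(20, 20, 20, 20), 2))
#' contingency_test(matrix(c(1, 11, 9, 3), 2)) # small cells -> Fisher
contingency_test <- function(table, alpha = 0.05) {
  m <- as_count_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate margin: a row or column of the table sums to zero",
      call. = FALSE
    )
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(m)
    res <- tibble::tibble(
      method = "fisher", statistic = NA_real_, df = NA_real_,
      p_value = ft$p.value
    )
  } else {
    ct <- stats::chisq.test(m, correct = FALSE)
    res <- tibble::tibble(
      method = "chisq", statistic = unname(ct$statistic),
      df = unname(ct$parameter), p_value = ct$p.value
    )
  }
  res$significant <- res$p_value < alpha
  res
}

as_count_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else {
    d <- as.data.frame(table)
    if (ncol(d) >= 2 && is.character(d[[1]])) {
      rn <- d[[1]]
      d <- d[-1]
      m <- as.matrix(d)
      rownames(m) <- rn
    } else {
      m <- as.matrix(d)
    }
  }
  if (!is.numeric(m) || any(m < 0) || any(m != round(m))) {
    stop("contingency table must contain nonnegative integer counts", call. = FALSE)
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (sum(m) == 0) stop("contingency table total must be positive", call. = FALSE)
  m
}
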
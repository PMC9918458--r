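# internal helpers shared across modules

# round half away from zero (reporting convention; base round() is half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, rounded half-up
#'
#' Computes `100 * k / n` rounded half away from zero to `digits` decimals,
#' the convention used for all percentages reported by the package (module
#' fractions, percent-expressing, up/down-regulated DEG shares).
#'
#' @param k Numerator count (non-negative).
#' @param n Denominator count (positive).
#' @param digits Decimal places to keep (default 1).
#' @return A numeric percentage in `[0, 100]`.
#' @examples
#' proportion_pct(40, 45)      # 88.9
#' proportion_pct(2651, 5086, digits = 0)
#' @export
proportion_pct <- function(k, n, digits = 1) {
  stopifnot(length(k) == length(n) || length(n) == 1L)
  if (any(n <= 0)) stop("denominator must be positive")
  if (any(k < 0) || any(k > n)) stop("count must lie in [0, n]")
  round_half_up(100 * k / n, digits)
}

check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

check_sample_sheet <- function(sheet, m = NULL) {
  req <- c("sample_id", "tissue", "study_id")
  if (!all(req %in% names(sheet))) stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(sheet$tissue), c("NORM", "DTC", "ATC"))
  if (length(bad)) stop("invalid tissue labels: ", paste(bad, collapse = ", "))
  if (!is.null(m)) {
    if (!setequal(colnames(m), sheet$sample_id))
      stop("sample sheet and matrix sample ids differ")
  }
  invisible(sheet)
}

# row variances with the n-1 denominator, no dependency on matrixStats
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) stop("need >= 2 columns for a variance")
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
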
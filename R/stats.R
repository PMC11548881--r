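#' Two-sided unpaired t-test
#'
#' Classical two-sample Student t-test with pooled variance by default
#' (`var_equal = FALSE` gives Welch's test).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param var_equal pool the variances (classical unpaired t)?
#' @return An object of class `test_result`: list with `statistic`,
#'   `p_value`, `df`, `test_kind`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("degenerate sample: each group needs n >= 2", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    # identical constant samples: no evidence of a difference
    return(structure(list(statistic = 0, p_value = 1,
                          df = length(a) + length(b) - 2,
                          test_kind = if (var_equal) "unpaired t (pooled)"
                                      else "unpaired t (Welch)"),
                     class = "test_result"))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter),
                 test_kind = if (var_equal) "unpaired t (pooled)"
                             else "unpaired t (Welch)"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: t = %.4f, df = %.4g, p = %.4g\n",
              x$test_kind, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' The sharpened two-stage linear step-up procedure: a first-stage
#' Benjamini-Hochberg pass at level `q' = q / (1 + q)` estimates the number
#' of true nulls `m0 = m - r1`; if `0 < r1 < m`, a second pass runs at level
#' `q' * m / m0`. Rejecting all (r1 = m) or none (r1 = 0) short-circuits.
#'
#' @param p_values numeric vector of p-values.
#' @param q nominal false discovery rate (default 0.01).
#' @return An object of class `fdr_decision`: list with `p_values`, `q`,
#'   `rejected` (logical, step-up set), `method`.
#' @export
bky_twostage <- function(p_values, q = 0.01) {
  if (any(p_values < 0 | p_values > 1) || any(!is.finite(p_values)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  m <- length(p_values)
  bh_reject <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    below <- p[o] <= thr
    k <- if (any(below)) max(which(below)) else 0L
    rej <- logical(m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  stage1 <- bh_reject(p_values, q1)
  r1 <- sum(stage1)
  rejected <- if (r1 == 0L || r1 == m) stage1
              else bh_reject(p_values, q1 * m / (m - r1))
  structure(list(p_values = p_values, q = q, rejected = rejected,
                 method = "BKY two-stage"),
            class = "fdr_decision")
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat(sprintf("%s at q = %g: %d of %d rejected\n", x$method, x$q,
              sum(x$rejected), length(x$p_values)))
  invisible(x)
}

#' Paired t-tests with two-stage BKY FDR control
#'
#' Runs a two-sided paired t-test for each (treated, control) pair of
#' matched replicate vectors, then applies [bky_twostage()] at level `q`
#' across the family.
#'
#' @param pairs list of pairs; each element a list or data.frame with
#'   components `treated` and `control` of equal length `n >= 2`.
#' @param q nominal false discovery rate (default 0.01, the level used for
#'   the bystander-panel comparisons).
#' @return An `fdr_decision` with an extra `tests` field (list of
#'   `test_result`).
#' @export
paired_t_fdr <- function(pairs, q = 0.01) {
  tests <- lapply(pairs, function(pr) {
    tr <- pr$treated; ct <- pr$control
    if (is.null(tr) || is.null(ct))
      stop("each pair needs 'treated' and 'control' components", call. = FALSE)
    if (length(tr) != length(ct))
      stop("pairing error: treated and control have different lengths",
           call. = FALSE)
    if (length(tr) < 2)
      stop("each pair needs n >= 2 matched replicates", call. = FALSE)
    if (all(tr == ct)) {
      structure(list(statistic = 0, p_value = 1, df = length(tr) - 1,
                     test_kind = "paired t"), class = "test_result")
    } else {
      ht <- t.test(tr, ct, paired = TRUE)
      structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                     df = unname(ht$parameter), test_kind = "paired t"),
                class = "test_result")
    }
  })
  dec <- bky_twostage(vapply(tests, function(t) t$p_value, numeric(1)), q)
  dec$tests <- tests
  dec
}
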
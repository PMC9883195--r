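# The declared statistical toolkit: Pearson chi-squared homogeneity test for
# composition panels (raw counts only — percentages are refused because the
# test is invalid on them), Wilcoxon rank-sum with exact enumeration at small
# n, the classic pooled-variance unpaired two-tailed t test (Welch by flag),
# Bonferroni-Holm step-down adjustment, the significance star map, the
# regulon specificity score, and the caliper tumor-volume formula
# V = d^2 * D / 2.

STAR_LEVELS <- c("ns", "*", "**", "***", "****")

new_test_result <- function(name, statistic, df = NA_integer_, p,
                            p_adj = NA_real_, warning_msg = NULL) {
  structure(list(test = name, statistic = statistic, df = df,
                 p = p, p_adj = p_adj, stars = stars(p),
                 warning = warning_msg), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.6g [%s]%s\n", x$test,
              x$statistic, ifelse(is.na(x$df), "-", x$df), x$p, x$stars,
              if (!is.null(x$warning)) paste0("  (", x$warning, ")") else ""))
  invisible(x)
}

#' Pearson chi-squared test of composition homogeneity
#'
#' Statistic sum((O - E)^2 / E) with expected counts from the row/column
#' margins, df = (r-1)(c-1), upper-tail p from the chi-squared distribution.
#' No continuity correction by default (2x2 Yates correction behind a flag).
#' Requires raw counts: non-integer tables are refused. A zero expected
#' count is an error; any expected count below 5 attaches a warning to the
#' result (field \code{warning}).
#'
#' @param table r x c matrix of non-negative counts.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return A \code{test_result}.
#' @export
chi_squared_composition <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (!is_wholenumber(tab))
    stop("chi-squared requires raw counts, not percentages", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(tab)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2", call. = FALSE)
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0))
    stop("zero expected count (empty row or column margin)", call. = FALSE)
  warn <- if (any(E < 5))
    sprintf("%d expected count(s) below 5; chi-squared approximation weak",
            sum(E < 5)) else NULL
  dev <- abs(tab - E)
  if (correct && nrow(tab) == 2 && ncol(tab) == 2)
    dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  new_test_result("chi_squared", statistic, df,
                  stats::pchisq(statistic, df, lower.tail = FALSE),
                  warning_msg = warn)
}

mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))  # midranks for ties
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties. Exact two-sided p by full enumeration of all
#' choose(nx+ny, nx) group assignments when both arms have at most
#' \code{exact_max_n} observations and there are no ties; otherwise the
#' normal approximation with the tie-corrected variance (no continuity
#' correction). Two samples with all values identical yield p = 1 with a
#' warning attached to the result.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_max_n per-arm size limit for the exact branch.
#' @return A \code{test_result}; \code{statistic} is the Mann-Whitney U of
#'   the first sample.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 8) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  u <- mann_whitney_u(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1)
    return(new_test_result("wilcoxon_rank_sum", u, p = 1,
                           warning_msg = "all values identical"))
  if (nx <= exact_max_n && ny <= exact_max_n && !ties) {
    # Exact null distribution of U by enumeration of all assignments.
    r_all <- rank(c(x, y))
    combs <- utils::combn(nx + ny, nx)
    u_null <- colSums(matrix(r_all[combs], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_null <= u + eps), mean(u_null >= u - eps))
    return(new_test_result("wilcoxon_rank_sum", u, p = min(1, p)))
  }
  mu <- nx * ny / 2
  tie_counts <- table(c(x, y))
  n <- nx + ny
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_counts^3 - tie_counts) /
                              (n * (n - 1)))
  z <- (u - mu) / sqrt(sigma2)
  new_test_result("wilcoxon_rank_sum", u, p = 2 * stats::pnorm(-abs(z)))
}

#' Unpaired two-tailed t test
#'
#' Classic pooled-variance Student's t by default (matching the named test);
#' \code{welch = TRUE} switches to the Welch-Satterthwaite variant. Zero
#' variance in both arms with equal means yields p = 1 with a warning.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @param welch use the unequal-variance variant.
#' @return A \code{test_result}.
#' @export
t_test_unpaired <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need n >= 2 per arm", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  delta <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (delta == 0)
      return(new_test_result("t_test_unpaired", 0, nx + ny - 2L, 1,
                             warning_msg = "zero variance in both arms"))
    return(new_test_result("t_test_unpaired", sign(delta) * Inf,
                           nx + ny - 2L, 0,
                           warning_msg = "zero variance in both arms"))
  }
  if (welch) {
    se2 <- vx / nx + vy / ny
    statistic <- delta / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    statistic <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  new_test_result("t_test_unpaired", statistic, as.integer(round(df)),
                  2 * stats::pt(-abs(statistic), df))
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sort ascending, multiply the i-th smallest p by (m - i + 1), enforce the
#' running maximum, cap at 1, and return in the input order.
#'
#' @param pvals numeric vector of p values in \code{[0, 1]}.
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  ord <- order(pvals)
  adj <- pmin(1, cummax(pvals[ord] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Significance stars
#'
#' Strict thresholds: p < 1e-4 \code{"****"}, < 1e-3 \code{"***"},
#' < 0.01 \code{"**"}, < 0.05 \code{"*"}, otherwise \code{"ns"}.
#'
#' @param p a p value in \code{[0, 1]}.
#' @return One of \code{ns, *, **, ***, ****}.
#' @export
stars <- function(p) {
  stopifnot(length(p) == 1, is.finite(p), p >= 0, p <= 1)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

# Jensen-Shannon divergence with base-2 logs, bounded in [0, 1].
jsd_base2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity score
#'
#' For each regulon, its activity vector is normalized to a probability
#' distribution over cells and compared with each label's indicator
#' distribution (uniform over the cells carrying the label) by
#' Jensen-Shannon divergence with base-2 logs; RSS = 1 - sqrt(JSD), in
#' \code{[0, 1]}, equal to 1 iff the normalized activity coincides with the
#' indicator. Regulons with all-zero activity get NA for every label, with
#' a warning.
#'
#' @param activity regulon x cell matrix of non-negative activities with
#'   dimnames.
#' @param labels character/factor vector of per-cell labels, length
#'   \code{ncol(activity)}.
#' @return regulon x label matrix of RSS values.
#' @export
regulon_specificity_score <- function(activity, labels) {
  a <- as.matrix(activity)
  if (any(a < 0)) stop("activities must be non-negative", call. = FALSE)
  if (length(labels) != ncol(a))
    stop("labels length must equal the number of cells", call. = FALSE)
  labels <- as.character(labels)
  ulab <- unique(labels)
  out <- matrix(NA_real_, nrow(a), length(ulab),
                dimnames = list(rownames(a), ulab))
  indicators <- lapply(stats::setNames(ulab, ulab), function(L) {
    q <- as.numeric(labels == L)
    q / sum(q)
  })
  zero <- rowSums(a) == 0
  if (any(zero))
    warning(sum(zero), " regulon(s) with all-zero activity: RSS undefined",
            call. = FALSE)
  for (r in which(!zero)) {
    p <- a[r, ] / sum(a[r, ])
    for (L in ulab) out[r, L] <- 1 - sqrt(jsd_base2(p, indicators[[L]]))
  }
  out
}

#' Caliper tumor volume
#'
#' V = d^2 * D / 2 from the shortest (d) and longest (D) diameters in mm.
#'
#' @param d shortest diameter(s), mm; must satisfy 0 < d <= D.
#' @param D longest diameter(s), mm.
#' @return Volume(s) in cubic mm.
#' @export
tumor_volume <- function(d, D) {
  if (any(d <= 0) || any(D <= 0))
    stop("diameters must be positive", call. = FALSE)
  if (any(d > D))
    stop("d must not exceed D (diameters swapped?)", call. = FALSE)
  d^2 * D / 2
}
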
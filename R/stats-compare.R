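#' Wilcoxon signed-rank test for paired samples
#'
#' Paired nonparametric comparison as used for the NT versus TH
#' summaries: zero differences are dropped (Wilcoxon's original rule),
#' ties in |difference| receive midranks, and for n <= `exact_max` the
#' two-sided p-value is computed exactly by enumerating all 2^n sign
#' assignments of the ranks; above that, a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x numeric: paired differences, or the first member of each pair
#'   if `y` is given
#' @param y optional numeric, second member of each pair (`x - y` is
#'   tested)
#' @param exact_max largest n for exact enumeration (default 15)
#' @return a one-row tibble: `statistic` (V, the sum of positive ranks),
#'   `p_value` (two-sided), `n_used` (pairs after dropping zeros),
#'   `method`
#' @examples
#' wilcoxon_signed_rank(c(0.1, 0.2, 0.15, 0.3, 0.12, 0.25, 0.18))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 15) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) abort("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(tibble(statistic = 0, p_value = 1, n_used = 0L,
                  method = "degenerate"))
  }
  if (n < 2) abort("need at least 2 nonzero paired differences")
  r <- rank(abs(d))                       # midranks
  v <- sum(r[d > 0])
  centre <- sum(r) / 2
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    p <- mean(abs(w_all - centre) >= abs(v - centre) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - centre - sign(v - centre) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(statistic = v, p_value = p, n_used = as.integer(n),
         method = method)
}

#' Median (min-max) summary and paired comparison of NT vs TH
#'
#' Summarizes one metric of a paired cohort at one state the way the
#' study reports it: median (min-max) per condition, percent change of
#' the TH median relative to the NT median, and the exact Wilcoxon
#' signed-rank p-value over subject-wise pairs. Subjects missing either
#' condition are excluded with a warning.
#'
#' @param data a tibble with columns `subject`, `condition` ("NT"/"TH"),
#'   `state`, and the metric column (e.g. the output of
#'   [generate_cohort()])
#' @param metric metric column, unquoted (e.g. `fd` or `mean_bf`)
#' @param state which state to compare, `"rest"` or `"stress"`
#' @return a one-row tibble: medians and ranges per condition,
#'   `percent_change`, Wilcoxon `statistic` and `p_value`, `n_pairs`
#' @export
summarize_paired <- function(data, metric, state = "rest") {
  mcol <- rlang::enquo(metric)
  st <- state
  dd <- data %>%
    filter(.data$state == st) %>%
    mutate(.value = !!mcol) %>%
    select("subject", "condition", ".value")
  wide <- tidyr::pivot_wider(dd, names_from = "condition",
                             values_from = ".value")
  if (!all(c("NT", "TH") %in% names(wide)))
    abort("both NT and TH rows are required")
  ok <- stats::complete.cases(wide[, c("NT", "TH")])
  if (any(!ok))
    warn(sprintf("%d subject(s) missing a condition; excluded", sum(!ok)))
  wide <- wide[ok, ]
  if (nrow(wide) < 2) abort("need at least 2 complete subject pairs")
  wt <- wilcoxon_signed_rank(wide$TH, wide$NT)
  med_nt <- median(wide$NT); med_th <- median(wide$TH)
  tibble(metric = rlang::as_label(mcol), state = st,
         n_pairs = nrow(wide),
         median_nt = med_nt, min_nt = min(wide$NT), max_nt = max(wide$NT),
         median_th = med_th, min_th = min(wide$TH), max_th = max(wide$TH),
         percent_change = 100 * (med_th - med_nt) / med_nt,
         statistic = wt$statistic, p_value = wt$p_value)
}
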
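# Group-level inference on excess accuracies: balanced within-subject
# factorial decomposition (context x complexity x hemisphere) and paired
# signed-rank post hoc tests.

#' Within-subject factorial model on excess accuracies
#'
#' Decomposes a balanced participant x context x complexity x hemisphere
#' table of excess accuracies into main effects and interactions with a
#' per-participant random intercept. On a fully balanced table this is
#' computed as a repeated-measures ANOVA with per-effect error strata,
#' which gives the same F ratios as a random-intercept mixed model under
#' balance (the pipeline guarantees balance; unbalanced tables are
#' rejected with a pointer to the mixed-model route).
#'
#' @param table A `data.frame` with columns `participant`, `value`, and the
#'   factor columns named in `factors` (one observation per participant per
#'   factor cell).
#' @param factors Character vector of within-subject factor column names.
#' @param value Name of the response column.
#' @return A `data.frame` with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p`.
#' @export
#' @examples
#' tab <- expand.grid(participant = factor(1:6),
#'                    context = c("reinforcement", "nonreinforcement"),
#'                    complexity = c("simple", "complex"),
#'                    hemisphere = c("left", "right"))
#' tab$value <- rnorm(nrow(tab))
#' factorial_accuracy_model(tab)
factorial_accuracy_model <- function(table,
                                     factors = c("context", "complexity", "hemisphere"),
                                     value = "value") {
  check_param(all(c("participant", value, factors) %in% names(table)),
              paste("table needs columns: participant,", value, ",",
                    paste(factors, collapse = ", ")))
  table$participant <- factor(table$participant)
  check_param(nlevels(table$participant) >= 2, "need at least 2 participants")
  for (f in factors) table[[f]] <- factor(table[[f]])
  cells <- table(table[c("participant", factors)])
  if (!all(cells == 1))
    stop("unbalanced table: every participant must contribute exactly one ",
         "observation per factor cell; fit a random-intercept mixed model ",
         "(e.g. lme4::lmer) instead", call. = FALSE)
  rhs <- paste(factors, collapse = " * ")
  fml <- stats::as.formula(paste(value, "~", rhs,
                                 "+ Error(participant/(", rhs, "))"))
  fit <- stats::aov(fml, data = table)
  s <- summary(fit)
  rows <- lapply(s, function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    data.frame(effect = eff[keep],
               df1 = tab$Df[keep],
               df2 = tab$Df[!keep],
               F = tab$`F value`[keep],
               p = tab$`Pr(>F)`[keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped (signed-rank convention); ties receive average ranks. The null
#' distribution is exact for n <= 25 — via the closed-form signed-rank
#' distribution when ranks are untied, and by full enumeration of the 2^n
#' sign assignments when ties are present and n <= 15 — and a normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Paired numeric vectors of equal length >= 5.
#' @param exact_max Largest n for which an exact null is used.
#' @return A list: `statistic` (V, sum of positive-difference ranks), `p`
#'   (two-sided), `n` (non-zero differences), `method`.
#' @export
#' @examples
#' paired_signed_rank(rnorm(10), rnorm(10))
paired_signed_rank <- function(a, b, exact_max = 25L) {
  check_param(length(a) == length(b), "`a` and `b` must be paired (equal length)")
  check_param(length(a) >= 5, "need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (n <= exact_max && !ties) {
    # exact symmetric null via the signed-rank distribution
    p <- 2 * min(stats::psignrank(v, n), stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else if (n <= min(exact_max, 15L)) {
    # ties: enumerate all sign assignments of the ranked magnitudes
    null_v <- enumerate_signed_rank_null(r)
    p <- min(1, 2 * min(mean(null_v <= v), mean(null_v >= v)))
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  list(statistic = v, p = p, n = n, method = method)
}

# All 2^n values of the signed-rank statistic over sign assignments.
enumerate_signed_rank_null <- function(ranks) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  as.numeric(signs %*% ranks)
}
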
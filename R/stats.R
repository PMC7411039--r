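# Group-comparison battery used for the tracking and phenotype readouts:
# Kruskal-Wallis with Dunn's post hoc z-tests for the tracking metrics,
# two-tailed Mann-Whitney U for two-group phenotype counts, one-way ANOVA
# with Dunnett's many-to-one comparisons for colocalization over time,
# Welch's t for the treatment survival readout, and the significance star
# coding.

test_result <- function(method, comparison, statistic, p_value, n) {
  data.frame(method = method, comparison = comparison,
             statistic = statistic, p_value = p_value,
             n = paste(n, collapse = "/"),
             stars = star_code(p_value), stringsAsFactors = FALSE)
}

#' Significance star coding
#'
#' `"ns"` for p >= 0.05, then `*`, `**`, `***`, `****` for p below 0.05,
#' 0.01, 0.001 and 0.0001 respectively. A p-value exactly on a threshold
#' maps to the weaker code.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return character vector of star codes
#' @export
star_code <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  ifelse(p >= 0.05, "ns",
         ifelse(p >= 0.01, "*",
                ifelse(p >= 0.001, "**",
                       ifelse(p >= 1e-4, "***", "****"))))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected rank-based H test across all groups, followed by Dunn's
#' pairwise z-tests on mean ranks with multiplicity adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 1)
#' @param p_adjust multiplicity adjustment for the Dunn comparisons
#'   (default Holm; any method of [stats::p.adjust()])
#' @return list with `overall` and `pairwise` test-result data frames
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = "holm") {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  if (length(unique(x)) == 1L) {
    overall <- test_result("kruskal_wallis", "all", 0, 1, lengths(groups))
  } else {
    kw <- kruskal.test(x, g)
    overall <- test_result("kruskal_wallis", "all",
                           unname(kw$statistic), kw$p.value, lengths(groups))
  }
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(names(groups), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    data.frame(comparison = paste(i, "vs", j), z = z,
               p_raw = 2 * pnorm(-abs(z)), n = paste(ns[[i]], ns[[j]], sep = "/"))
  })
  pw <- do.call(rbind, pw)
  pw$p_value <- pmin(1, p.adjust(pw$p_raw, method = p_adjust))
  pairwise <- data.frame(method = "dunn", comparison = pw$comparison,
                         statistic = pw$z, p_value = pw$p_value, n = pw$n,
                         stars = star_code(pw$p_value))
  list(overall = overall, pairwise = pairwise)
}

# U statistic for sample a vs b (number of (a, b) pairs with a > b, ties 0.5)
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Exact p by exhaustive enumeration of all group-label arrangements when
#' `min(n) <= exact_max`, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b numeric samples
#' @param two_tailed two-tailed test (default)
#' @param exact_max enumeration threshold on the smaller group size
#' @return a one-row test-result data frame with the `U` statistic for `a`
#' @export
mann_whitney_u <- function(a, b, two_tailed = TRUE, exact_max = 8L) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  u <- u_statistic(a, b)
  mid <- n1 * n2 / 2
  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 5e5) {
    r <- rank(c(a, b))
    combos <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (two_tailed) mean(abs(us - mid) >= abs(u - mid) - 1e-9)
         else mean(us <= u + 1e-9)
    method <- "mann_whitney_exact"
  } else {
    ties <- table(c(a, b))
    N <- n1 + n2
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    z <- if (sigma > 0) (u - mid - sign(u - mid) * 0.5) / sigma else 0
    p <- if (two_tailed) 2 * pnorm(-abs(z)) else pnorm(z)
    p <- min(1, p)
    method <- "mann_whitney_normal"
  }
  test_result(method, "a vs b", u, p, c(n1, n2))
}

#' Welch's two-sample t-test
#'
#' Welch t with Satterthwaite degrees of freedom. If both groups have zero
#' variance, returns p = 1 for equal means and p = 0 otherwise.
#'
#' @param a,b numeric samples (n >= 2 each)
#' @return one-row test-result data frame
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(test_result("welch_t", "a vs b", if (eq) 0 else Inf,
                       if (eq) 1 else 0, c(length(a), length(b))))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  res <- test_result("welch_t", "a vs b", unname(tt$statistic), tt$p.value,
                     c(length(a), length(b)))
  res$df <- unname(tt$parameter)
  res
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' @param control numeric vector for the control group
#' @param treatments named list of treatment group vectors
#' @return list with `overall` (F test) and `pairwise` (Dunnett vs control)
#' @export
anova_dunnett <- function(control, treatments) {
  stopifnot(length(control) >= 2, all(lengths(treatments) >= 2))
  if (is.null(names(treatments)))
    names(treatments) <- paste0("t", seq_along(treatments))
  x <- c(control, unlist(treatments, use.names = FALSE))
  g <- factor(rep(c("control", names(treatments)),
                  c(length(control), lengths(treatments))),
              levels = c("control", names(treatments)))
  if (length(unique(x)) == 1L) {
    overall <- test_result("anova", "all", 0, 1, table(g))
    pairwise <- do.call(rbind, lapply(names(treatments), function(nm)
      test_result("dunnett", paste(nm, "vs control"), 0, 1,
                  c(length(treatments[[nm]]), length(control)))))
    return(list(overall = overall, pairwise = pairwise))
  }
  fit <- aov(x ~ g)
  an <- summary(fit)[[1]]
  overall <- test_result("anova", "all", an[["F value"]][1],
                         an[["Pr(>F)"]][1], table(g))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  pairwise <- data.frame(method = "dunnett",
                         comparison = paste(names(treatments), "vs control"),
                         statistic = unname(sm$test$tstat),
                         p_value = unname(as.numeric(sm$test$pvalues)),
                         n = vapply(treatments, length, 1L),
                         stars = star_code(unname(as.numeric(sm$test$pvalues))))
  list(overall = overall, pairwise = pairwise)
}
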
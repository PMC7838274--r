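#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test for a 2x2 table (rows = condition, columns =
#' outcome). The two-sided p-value follows the point-probability rule: the
#' sum of probabilities of all tables with the observed margins whose point
#' probability does not exceed the observed table's.
#'
#' @param a,b,c,d Cell counts (non-negative integers), row-wise; or pass a
#'   2x2 matrix as `a`.
#' @return Object of class `"fibsir_comparison"` with `p` (two-sided),
#'   `p_one_sided` (both tails), and the conditional MLE `odds_ratio`.
#' @examples
#' fisher_exact_2x2(20, 78, 0, 57)$p   # silent/active proportions
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_fibsir("counts must be non-negative integers", "fibsir_bad_counts")
  if (sum(tab) == 0)
    stop_fibsir("table total must be > 0", "fibsir_bad_counts")
  two <- stats::fisher.test(tab, alternative = "two.sided")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  comparison_result(
    test = "fisher_exact_2x2",
    statistic = c(odds_ratio = unname(two$estimate)),
    df = NA_real_,
    p = min(two$p.value, 1),
    extra = list(
      table = tab,
      odds_ratio = unname(two$estimate),
      p_one_sided = c(
        less = stats::phyper(a, c1, r1 + r2 - c1, r1),
        greater = stats::phyper(a - 1, c1, r1 + r2 - c1, r1,
                                lower.tail = FALSE)))
  )
}

comparison_result <- function(test, statistic, df, p, post_hoc = NULL,
                              extra = list()) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(c(list(test = test, statistic = statistic, df = df,
                   p = p, post_hoc = post_hoc), extra),
            class = "fibsir_comparison")
}

#' @export
print.fibsir_comparison <- function(x, ...) {
  st <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
              collapse = ", ")
  dfs <- if (all(is.na(x$df))) "" else
    sprintf(", df = %s", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("%s: %s%s, p = %.4g\n", x$test, st, dfs, x$p))
  if (!is.null(x$post_hoc)) {
    cat("post-hoc:\n")
    print(x$post_hoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Omnibus comparison of several groups with the matching post-hoc test
#'
#' Three families, as used throughout dorsal-horn event statistics:
#' Welch's heteroscedastic ANOVA and the Brown-Forsythe F* ANOVA, both
#' followed by the Games-Howell post-hoc test, and the Kruskal-Wallis rank
#' test followed by Dunn's post-hoc test (Bonferroni-adjusted).
#'
#' Games-Howell uses per-pair Welch-Satterthwaite degrees of freedom and
#' the studentized-range distribution over all `k` group means. A
#' zero-variance group is flagged and continued with a small variance guard
#' rather than aborting the battery.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor), >= 2 groups of >= 2.
#' @param family `"welch_anova"`, `"brown_forsythe"` or `"kruskal_wallis"`.
#' @return `"fibsir_comparison"` with `post_hoc` data frame columns
#'   `group1`, `group2`, `statistic`, `p_adjusted`.
#' @export
omnibus_compare <- function(values, groups,
                            family = c("welch_anova", "brown_forsythe",
                                       "kruskal_wallis")) {
  family <- match.arg(family)
  g <- factor(groups)
  ok <- is.finite(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  ns <- tabulate(g)
  if (k < 2L || any(ns < 2L))
    stop_fibsir("need >= 2 groups with >= 2 observations each",
                "fibsir_bad_groups")
  if (family == "kruskal_wallis") {
    ht <- stats::kruskal.test(values, g)
    return(comparison_result("kruskal_wallis",
                             c(KW = unname(ht$statistic)),
                             unname(ht$parameter), ht$p.value,
                             post_hoc = dunn_posthoc(values, g)))
  }
  vs <- tapply(values, g, stats::var)
  flag <- NULL
  if (any(vs == 0)) {
    flag <- "zero-variance group; epsilon variance guard applied"
    scale <- max(1, abs(values))
    for (lv in levels(g)[vs == 0]) {
      i <- which(g == lv)[1]
      values[i] <- values[i] + scale * 1e-9
    }
    vs <- tapply(values, g, stats::var)
  }
  ms <- tapply(values, g, mean)
  if (family == "welch_anova") {
    ht <- stats::oneway.test(values ~ g, var.equal = FALSE)
    res <- comparison_result("welch_anova", c(W = unname(ht$statistic)),
                             unname(ht$parameter), ht$p.value,
                             post_hoc = games_howell_posthoc(ms, vs, ns))
  } else {
    N <- sum(ns)
    gm <- mean(values)
    num <- sum(ns * (ms - gm)^2)
    ci <- (1 - ns / N) * vs
    stat <- num / sum(ci)
    cfrac <- ci / sum(ci)
    df2 <- 1 / sum(cfrac^2 / (ns - 1))
    p <- stats::pf(stat, k - 1, df2, lower.tail = FALSE)
    res <- comparison_result("brown_forsythe", c(F = stat), c(k - 1, df2), p,
                             post_hoc = games_howell_posthoc(ms, vs, ns))
  }
  if (!is.null(flag)) res$flag <- flag
  if (any(ns <= 50))
    res$note <- "Games-Howell is usually advised for group sizes above 50"
  res
}

games_howell_posthoc <- function(ms, vs, ns) {
  k <- length(ms)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    t <- (ms[i] - ms[j]) / sqrt(se2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                   (vs[j] / ns[j])^2 / (ns[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(statistic = unname(t), df = unname(df), p = unname(p))
  })
  data.frame(group1 = names(ms)[pairs[1, ]], group2 = names(ms)[pairs[2, ]],
             statistic = out["statistic", ], df = out["df", ],
             p_adjusted = pmin(out["p", ], 1), row.names = NULL)
}

dunn_posthoc <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ns <- tabulate(g)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  k <- nlevels(g)
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / ns[i] + 1 / ns[j]))
    c(statistic = unname(z), p = min(1, 2 * stats::pnorm(-abs(z)) * m))
  })
  data.frame(group1 = levels(g)[pairs[1, ]], group2 = levels(g)[pairs[2, ]],
             statistic = out["statistic", ], p_adjusted = out["p", ],
             row.names = NULL)
}

#' Paired pre/post comparisons
#'
#' `"paired_t"` and `"wilcoxon_signed_rank"` compare two paired vectors;
#' `"rm_anova_2way_sidak"` fits the two-way repeated-measures ANOVA with a
#' between-cell grouping factor and the within-cell pre/post factor, then
#' runs Sidak-adjusted pre-vs-post paired contrasts within each group
#' (`p_adj = 1 - (1 - p)^m` over the `m` planned contrasts).
#'
#' Degenerate inputs follow the conventions: identical vectors give t = 0,
#' p = 1; all-zero differences give Wilcoxon p = 1 (flagged).
#'
#' @param pre,post Equal-length paired numeric vectors.
#' @param method One of `"paired_t"`, `"wilcoxon_signed_rank"`,
#'   `"rm_anova_2way_sidak"`.
#' @param group For the RM-ANOVA: a factor (one level per pair) such as the
#'   fold-change increase/decrease grouping.
#' @return `"fibsir_comparison"`; for the RM-ANOVA the `statistic`/`p`
#'   report the interaction, with main effects in `effects` and the Sidak
#'   contrasts in `post_hoc`.
#' @export
paired_compare <- function(pre, post,
                           method = c("paired_t", "wilcoxon_signed_rank",
                                      "rm_anova_2way_sidak"),
                           group = NULL) {
  method <- match.arg(method)
  stopifnot(length(pre) == length(post))
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L) stop_fibsir("need >= 2 complete pairs", "fibsir_too_few_pairs")
  d <- post - pre
  if (method == "paired_t") {
    if (all(d == 0))
      return(comparison_result("paired_t", c(t = 0), n - 1, 1,
                               extra = list(flag = "all differences zero")))
    ht <- stats::t.test(post, pre, paired = TRUE)
    return(comparison_result("paired_t", c(t = unname(ht$statistic)),
                             unname(ht$parameter), ht$p.value))
  }
  if (method == "wilcoxon_signed_rank") {
    if (all(d == 0))
      return(comparison_result("wilcoxon_signed_rank", c(V = NA_real_),
                               NA_real_, 1,
                               extra = list(flag = "all differences zero")))
    ## no continuity correction, so perfectly antisymmetric differences give
    ## p = 1 exactly under the normal approximation
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              correct = FALSE))
    return(comparison_result("wilcoxon_signed_rank",
                             c(V = unname(ht$statistic)), NA_real_,
                             ht$p.value))
  }
  ## two-way repeated-measures ANOVA: between = group, within = pre/post
  if (is.null(group))
    stop_fibsir("rm_anova_2way_sidak needs a `group` factor",
                "fibsir_bad_groups")
  group <- factor(group[ok])
  if (nlevels(group) < 2L)
    stop_fibsir("rm_anova_2way_sidak needs >= 2 groups", "fibsir_bad_groups")
  dat <- data.frame(
    value = c(pre, post),
    time = factor(rep(c("pre", "post"), each = n), levels = c("pre", "post")),
    grp = rep(group, 2),
    id = factor(rep(seq_len(n), 2))
  )
  fit <- stats::aov(value ~ grp * time + Error(id), data = dat)
  sm <- summary(fit)
  between <- sm[["Error: id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  grp_eff <- pick(between, "grp")
  time_eff <- pick(within, "time")
  int_eff <- pick(within, "grp:time")
  m <- nlevels(group)
  ph <- do.call(rbind, lapply(levels(group), function(lv) {
    sel <- group == lv
    if (sum(sel) < 2L || all(post[sel] - pre[sel] == 0)) {
      p_raw <- if (sum(sel) < 2L) NA_real_ else 1
      tstat <- if (sum(sel) < 2L) NA_real_ else 0
    } else {
      ht <- stats::t.test(post[sel], pre[sel], paired = TRUE)
      p_raw <- ht$p.value; tstat <- unname(ht$statistic)
    }
    data.frame(group1 = lv, group2 = sprintf("%s (pre vs post)", lv),
               statistic = tstat, p_raw = p_raw,
               p_adjusted = 1 - (1 - p_raw)^m)
  }))
  comparison_result(
    "rm_anova_2way_sidak",
    c(F_interaction = unname(int_eff["F"])),
    unname(int_eff[c("df1", "df2")]),
    unname(int_eff["p"]),
    post_hoc = ph,
    extra = list(effects = data.frame(
      term = c("group", "time", "group:time"),
      F = c(grp_eff["F"], time_eff["F"], int_eff["F"]),
      df1 = c(grp_eff["df1"], time_eff["df1"], int_eff["df1"]),
      df2 = c(grp_eff["df2"], time_eff["df2"], int_eff["df2"]),
      p = c(grp_eff["p"], time_eff["p"], int_eff["p"]),
      row.names = NULL))
  )
}

#' D'Agostino-Pearson omnibus normality check (advisory)
#'
#' Combines the skewness and kurtosis z-scores into the K2 omnibus
#' statistic (chi-square, 2 df). Offered as a gate advisory before choosing
#' parametric vs rank tests; it never switches a test automatically.
#'
#' @param x Numeric vector, n >= 8.
#' @return `"fibsir_comparison"` with `K2` and `p`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop_fibsir("normality check needs n >= 8", "fibsir_too_few")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  ## skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  ## kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  comparison_result("dagostino_pearson", c(K2 = K2), 2,
                    stats::pchisq(K2, 2, lower.tail = FALSE))
}
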
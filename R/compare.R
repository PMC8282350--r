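#' Group comparison with the study's test-dispatch rules
#'
#' Applies the statistical decision rules used throughout the assay suite:
#' two-factor designs (e.g. cell source x timepoint) use a two-way ANOVA
#' (type-II sums of squares) with Tukey's multiple comparisons; one-factor
#' and two-group designs are gated on per-group Shapiro-Wilk normality —
#' normal data use one-way ANOVA + Tukey (or an unpaired t test for two
#' groups), non-normal data use Mann-Whitney tests (pairwise for more than
#' two groups). Significance is declared at p < `alpha`.
#'
#' @param values numeric vector of observations.
#' @param group factor (or coercible) of group labels.
#' @param group2 optional second factor; supplying it selects the two-factor
#'   design.
#' @param design `"auto"` (two-factor when `group2` is given, otherwise by
#'   number of levels) or one of `"two_group"`, `"one_factor"`,
#'   `"two_factor"`.
#' @param alpha significance level.
#' @return object of class `group_comparison`: `test_used` (one of
#'   `two_way_anova_tukey`, `one_way_anova_tukey`, `welch_t`,
#'   `mann_whitney`), `p_values` (named), `normality_p` (per group),
#'   `significant` (logical per comparison), `alpha`, and `reason` when the
#'   comparison is undefined (fewer than 2 observations in a group).
#' @export
compare_groups <- function(values, group, group2 = NULL,
                           design = c("auto", "two_group", "one_factor",
                                      "two_factor"),
                           alpha = 0.05) {
  design <- match.arg(design)
  group <- factor(group)
  undefined <- function(reason)
    structure(list(test_used = NA_character_, p_values = NULL,
                   normality_p = NULL, significant = NULL, alpha = alpha,
                   reason = reason),
              class = "group_comparison")

  if (!is.null(group2) || design == "two_factor") {
    if (is.null(group2)) stop("two_factor design requires group2")
    group2 <- factor(group2)
    tab <- table(group, group2)
    if (any(tab < 2)) return(undefined("fewer than 2 observations in a cell"))
    d <- data.frame(y = values, g1 = group, g2 = group2)
    fit <- aov(y ~ g1 * g2, data = d)
    an <- car::Anova(fit, type = 2)
    p_main <- setNames(an[["Pr(>F)"]][seq_len(3)],
                       c(rownames(an)[1], rownames(an)[2], rownames(an)[3]))
    tk <- TukeyHSD(fit)
    p_pairs <- unlist(lapply(names(tk), function(term)
      setNames(tk[[term]][, "p adj"],
               paste(term, rownames(tk[[term]]), sep = ":"))))
    p <- c(p_main, p_pairs)
    norm_p <- tryCatch(shapiro.test(resid(fit))$p.value, error = function(e) NA)
    return(structure(list(test_used = "two_way_anova_tukey", p_values = p,
                          normality_p = c(residuals = norm_p),
                          significant = p < alpha, alpha = alpha,
                          reason = NULL),
                     class = "group_comparison"))
  }

  split_v <- split(values, group)
  if (any(lengths(split_v) < 2))
    return(undefined("fewer than 2 observations in a group"))
  k <- nlevels(group)
  norm_p <- vapply(split_v, function(v) {
    if (length(v) < 3 || sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(is.na(norm_p) | norm_p >= 0.05)

  if (k == 2 || design == "two_group") {
    if (normal) {
      p <- setNames(t.test(split_v[[1]], split_v[[2]])$p.value, "welch_t")
      test <- "welch_t"
    } else {
      p <- setNames(suppressWarnings(
        wilcox.test(split_v[[1]], split_v[[2]])$p.value), "mann_whitney")
      test <- "mann_whitney"
    }
  } else if (normal) {
    d <- data.frame(y = values, g = group)
    fit <- aov(y ~ g, data = d)
    tk <- TukeyHSD(fit)$g
    p <- setNames(tk[, "p adj"], rownames(tk))
    test <- "one_way_anova_tukey"
  } else {
    pairs <- combn(levels(group), 2)
    p <- apply(pairs, 2, function(pr) suppressWarnings(
      wilcox.test(split_v[[pr[1]]], split_v[[pr[2]]])$p.value))
    names(p) <- apply(pairs, 2, paste, collapse = "-")
    test <- "mann_whitney"
  }
  structure(list(test_used = test, p_values = p, normality_p = norm_p,
                 significant = p < alpha, alpha = alpha, reason = NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<group_comparison> undefined (%s)\n", x$reason))
  } else {
    cat(sprintf("<group_comparison> %s; p: %s\n", x$test_used,
                paste(sprintf("%s=%.3g", names(x$p_values), x$p_values),
                      collapse = ", ")))
  }
  invisible(x)
}
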
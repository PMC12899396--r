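#' Normality gate for a two-group comparison
#'
#' Shapiro-Wilk applied separately to each group; a variable is treated as
#' normal only when both groups' p-values are at or above `alpha`. Groups
#' larger than 5000 are thinned to an evenly spaced deterministic subset
#' (the test is defined for n <= 5000).
#'
#' @param x,y numeric samples for the two groups.
#' @param alpha gate level (default 0.05).
#' @return list with `p_x`, `p_y`, `normal`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  sw <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
    if (length(v) < 3L || sd(v) == 0) return(0) # degenerate: not normal
    shapiro.test(v)$p.value
  }
  p_x <- sw(x)
  p_y <- sw(y)
  list(p_x = p_x, p_y = p_y, normal = p_x >= alpha && p_y >= alpha)
}

#' Choose the between-group test for one variable
#'
#' Categorical variables are compared with the chi-square test. Continuous
#' variables use the independent (Welch) t-test when the normality gate
#' passes in both groups and the Mann-Whitney U test otherwise.
#'
#' @param x,y the two groups' values (numeric, or factor/character/logical
#'   for categorical).
#' @param kind `"continuous"` or `"categorical"`; guessed from the value
#'   type when omitted.
#' @param alpha normality-gate level.
#' @return one of `"t_test"`, `"mann_whitney"`, `"chi_square"`.
#' @export
choose_test <- function(x, y, kind = NULL, alpha = 0.05) {
  if (is.null(kind)) {
    kind <- if (is.numeric(x) && is.numeric(y)) "continuous" else "categorical"
  }
  kind <- match.arg(kind, c("continuous", "categorical"))
  if (kind == "categorical") return("chi_square")
  if (sum(!is.na(x)) < 3L || sum(!is.na(y)) < 3L) {
    stop("need at least 3 observations per group for a continuous comparison")
  }
  if (normality_gate(x, y, alpha)$normal) "t_test" else "mann_whitney"
}

#' Compare one variable between the Stable and Worsening groups
#'
#' Runs the appropriate test ([choose_test()]) and returns a populated
#' comparison row. Degenerate continuous comparisons (zero variance in
#' both groups) are flagged and reported with p = 1.
#'
#' @param x,y values for the stable and worsening groups.
#' @param variable variable name carried into the row.
#' @param kind `"continuous"` or `"categorical"` (guessed when omitted).
#' @param alpha significance and normality-gate level (two-sided 0.05).
#' @param correct Yates continuity correction for chi-square (default
#'   `FALSE`).
#' @return one-row `data.table`: `variable`, per-group `n`, `mean`, `sd`
#'   (for categorical: count and percent of the first level's complement),
#'   `test`, `p_value`, `significant`, `degenerate`.
#' @export
compare_variable <- function(x, y, variable = "variable", kind = NULL,
                             alpha = 0.05, correct = FALSE) {
  if (is.null(kind)) {
    kind <- if (is.numeric(x) && is.numeric(y)) "continuous" else "categorical"
  }
  kind <- match.arg(kind, c("continuous", "categorical"))
  x_ok <- x[!is.na(x)]
  y_ok <- y[!is.na(y)]
  degenerate <- FALSE
  if (kind == "categorical") {
    lv <- union(unique(as.character(x_ok)), unique(as.character(y_ok)))
    tab <- rbind(table(factor(x_ok, levels = lv)),
                 table(factor(y_ok, levels = lv)))
    test <- "chi_square"
    if (ncol(tab) < 2L) {
      degenerate <- TRUE
      p <- 1
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = correct)$p.value)
      if (is.nan(p)) { degenerate <- TRUE; p <- 1 }
    }
    row <- data.table(
      variable = variable,
      n_stable = length(x_ok), n_worsening = length(y_ok),
      mean_stable = NA_real_, sd_stable = NA_real_,
      mean_worsening = NA_real_, sd_worsening = NA_real_,
      test = test, p_value = p
    )
  } else {
    if (sd(x_ok) == 0 && sd(y_ok) == 0) {
      degenerate <- TRUE
      test <- "degenerate"
      p <- 1
    } else {
      test <- choose_test(x_ok, y_ok, "continuous", alpha)
      p <- if (test == "t_test") {
        t.test(x_ok, y_ok, var.equal = FALSE)$p.value
      } else {
        suppressWarnings(wilcox.test(x_ok, y_ok, exact = FALSE)$p.value)
      }
    }
    row <- data.table(
      variable = variable,
      n_stable = length(x_ok), n_worsening = length(y_ok),
      mean_stable = mean(x_ok), sd_stable = sd(x_ok),
      mean_worsening = mean(y_ok), sd_worsening = sd(y_ok),
      test = test, p_value = p
    )
  }
  row[, significant := p_value < alpha]
  set(row, j = "degenerate", value = degenerate)
  row[]
}

#' Percent change from group means
#'
#' Longitudinal percent change as the ratio of group means:
#' `100 * mean_change / mean_baseline`. Defined only for a strictly
#' positive baseline mean.
#'
#' @param mean_baseline group mean at baseline (> 0).
#' @param mean_change group mean of within-person change scores.
#' @return percent change (unrounded; tables print it to one decimal).
#' @export
#' @examples
#' percent_change(22.1, -4.0) # -18.1
percent_change <- function(mean_baseline, mean_change) {
  if (any(is.na(mean_baseline)) || any(mean_baseline <= 0)) {
    stop("percent change requires a positive baseline mean")
  }
  100 * mean_change / mean_baseline
}
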
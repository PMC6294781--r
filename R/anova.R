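#' Two-way repeated-measures ANOVA
#'
#' Within-subject two-way ANOVA for a complete balanced design: both main
#' effects and the interaction are tested against their respective
#' factor-by-subject interaction mean squares (the univariate
#' repeated-measures F tests, uncorrected degrees of freedom). Post-hoc
#' pairwise comparisons of the levels of each factor (collapsing the other)
#' use either Tukey's studentized-range test or Bonferroni-adjusted paired
#' t tests, each with the matching within-subject error stratum.
#'
#' @param data data.frame with columns `subject`, `A`, `B`, `value` (or
#'   supply `subject`, `a`, `b`, `value` as column names via arguments).
#' @param subject,a,b,value Column names in `data`.
#' @param adjustment `"tukey"` or `"bonferroni"` for the post-hoc tables.
#' @param alpha Significance level for the post-hoc flags.
#' @return An object of class `rm_anova`: `effects` (data.frame with F,
#'   df1, df2, p for A, B and A:B), `posthoc` (list of pairwise comparison
#'   tables for A and B), `adjustment`, `alpha`, and the cell means.
#' @export
#' @examples
#' d <- expand.grid(subject = factor(1:6), A = factor(1:2), B = factor(1:3))
#' d$value <- rnorm(nrow(d)) + as.numeric(d$B)
#' rm_anova_two_way(d)$effects
rm_anova_two_way <- function(data, subject = "subject", a = "A", b = "B",
                             value = "value",
                             adjustment = c("tukey", "bonferroni"),
                             alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  need <- c(subject, a, b, value)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(subject = factor(data[[subject]]),
                  A = factor(data[[a]], levels = unique(data[[a]])),
                  B = factor(data[[b]], levels = unique(data[[b]])),
                  value = data[[value]])
  if (anyNA(d)) stop("missing cells: repeated-measures design must be complete")
  tab <- table(d$subject, d$A, d$B)
  if (any(tab != 1))
    stop("design must be balanced and complete: one value per subject x A x B cell")
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2) stop("each factor needs >= 2 levels")
  if (nlevels(d$subject) < 3) stop("at least 3 subjects required")
  if (sd(d$value) == 0) stop("constant data: F statistics undefined")

  fit <- aov(value ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    st <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(st)))
    j <- match("Residuals", trimws(rownames(st)))
    # guard: with zero residual variance F is reported as NA by aov
    data.frame(effect = term, F = st[i, "F value"], df1 = st[i, "Df"],
               df2 = st[j, "Df"], p = st[i, "Pr(>F)"],
               ms_error = st[j, "Mean Sq"], stringsAsFactors = FALSE)
  }
  effects <- rbind(pull("Error: subject:A", "A"),
                   pull("Error: subject:B", "B"),
                   pull("Error: subject:A:B", "A:B"))
  rownames(effects) <- NULL

  posthoc <- list(
    A = .posthoc_factor(d, "A", effects$ms_error[1], effects$df2[1],
                        adjustment, alpha),
    B = .posthoc_factor(d, "B", effects$ms_error[2], effects$df2[2],
                        adjustment, alpha)
  )
  cells <- aggregate(value ~ A + B, data = d, FUN = mean)
  structure(list(effects = effects[, c("effect", "F", "df1", "df2", "p")],
                 posthoc = posthoc, adjustment = adjustment, alpha = alpha,
                 cell_means = cells, n_subjects = nlevels(d$subject)),
            class = "rm_anova")
}

# pairwise comparisons of one within-subject factor's levels, collapsing
# the other factor to subject-level means
.posthoc_factor <- function(d, factor_name, ms_error, df_error,
                            adjustment, alpha) {
  f <- d[[factor_name]]
  lv <- levels(f)
  means_by <- tapply(d$value, list(d$subject, f), mean)
  n_eff <- nrow(means_by) * (if (factor_name == "A") nlevels(d$B) else nlevels(d$A))
  pairs <- utils::combn(lv, 2)
  res <- data.frame(level_1 = pairs[1, ], level_2 = pairs[2, ],
                    diff = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    x1 <- means_by[, pairs[1, i]]
    x2 <- means_by[, pairs[2, i]]
    res$diff[i] <- mean(x1 - x2)
    if (adjustment == "tukey") {
      # studentized range on the raw-observation scale: SE of a level mean
      # from the factor-by-subject error stratum
      se <- sqrt(ms_error / n_eff)
      q <- abs(res$diff[i]) / se
      res$p_adjusted[i] <- ptukey(q, nmeans = length(lv), df = df_error,
                                  lower.tail = FALSE)
    } else {
      dd <- x1 - x2
      p <- if (sd(dd) == 0) {
        if (all(dd == 0)) 1 else 0
      } else {
        2 * pt(-abs(mean(dd) / (sd(dd) / sqrt(length(dd)))), df = length(dd) - 1)
      }
      res$p_adjusted[i] <- min(1, p * ncol(pairs))
    }
  }
  res$significant <- res$p_adjusted < alpha
  res
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %d subjects, %s post-hoc (alpha = %g)\n",
              x$n_subjects, x$adjustment, x$alpha))
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-4s F[%d,%d] = %.3f, p = %.4g\n", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$F[i], eff$p[i]))
  invisible(x)
}

#' Normality check (Shapiro-Wilk and Q-Q summary)
#'
#' Advisory screening of a sample (e.g. one design cell) for normality:
#' Shapiro-Wilk test plus the correlation of the sample quantiles with
#' normal theoretical quantiles (the "Q-Q straightness"). Does not gate
#' any downstream computation.
#'
#' @param values Numeric sample, n >= 3.
#' @return List with `statistic`, `p_value`, `qq_correlation`, `n`, and
#'   `degenerate` (TRUE when the sample is constant, in which case the
#'   test statistics are NA).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("normality check needs at least 3 observations, got ", n)
  if (sd(values) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                qq_correlation = NA_real_, n = n, degenerate = TRUE))
  sw <- shapiro.test(values)
  qq <- cor(sort(values), qnorm(stats::ppoints(n)))
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       qq_correlation = qq, n = n, degenerate = FALSE)
}
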
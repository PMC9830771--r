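# Demographic/clinical summary statistics: two-sample t tests (also from
# published summary statistics), chi-squared tests on 2x2 tables, and
# repeated-measures ANOVA for group x time effects.

#' Two-sample t test from group summaries
#'
#' Computes the t statistic and two-tailed p-value directly from each
#' group's mean, SD and n — the form in which cohort characteristics are
#' usually published. Both the pooled-variance (Student) and
#' unequal-variance (Welch-Satterthwaite) conventions are available;
#' Welch is the default.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param pooled if `TRUE`, Student's pooled-variance test; otherwise
#'   Welch.
#' @return list with `t`, `df`, `p`, `method`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                pooled = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    stop("t statistic undefined: zero variance in both groups with ",
         "equal means")
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Student (pooled variance)"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch (unequal variance)"
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), method = method)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param tab 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @param yates apply Yates continuity correction (default `FALSE`,
#'   plain Pearson).
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0), sum(tab) >= 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: a row or column marginal is zero")
  }
  res <- stats::chisq.test(tab, correct = yates)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-way mixed-design (repeated measures) ANOVA
#'
#' Two-timepoint, two-group mixed design: group is the between-subject
#' factor, time the within-subject factor. Fit via `aov()` with a
#' subject error stratum; the between stratum tests the group effect and
#' the within stratum tests time and the group x time interaction. With
#' only two timepoints sphericity holds trivially.
#'
#' @param data data.frame in long format.
#' @param outcome,subject,group,time column names.
#' @return data.frame with one row per effect (`group`, `time`,
#'   `group:time`): `df1`, `df2`, `SS`, `F`, `p`; plus attributes
#'   `SS_total`, `SS_between_subjects`, `SS_within_subjects`.
#' @export
repeated_anova <- function(data, outcome, subject = "subject_id",
                           group = "group", time = "timepoint") {
  d <- data.frame(y = as.numeric(data[[outcome]]),
                  subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  time = factor(data[[time]]))
  tps <- levels(d$time)
  if (length(tps) != 2L) stop("exactly two timepoints required")
  if (nlevels(d$group) != 2L) stop("exactly two groups required")
  counts <- table(d$subject, d$time)
  bad <- rownames(counts)[rowSums(counts == 1) != 2L]
  if (length(bad)) {
    stop("subject(s) missing a timepoint: ", paste(bad, collapse = ", "))
  }
  fit <- stats::aov(y ~ group * time + Error(subject), data = d)
  s <- summary(fit)
  betw <- s[["Error: subject"]][[1]]
  win <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    resid_i <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = term, df1 = tab$Df[i], df2 = tab$Df[resid_i],
               SS = tab$`Sum Sq`[i], F = tab$`F value`[i],
               p = tab$`Pr(>F)`[i])
  }
  out <- rbind(pick(betw, "group"), pick(win, "time"),
               pick(win, "group:time"))
  rownames(out) <- NULL
  out$effect <- c("group", "time", "group:time")
  ybar <- mean(d$y)
  ss_total <- sum((d$y - ybar)^2)
  subj_means <- tapply(d$y, d$subject, mean)
  ss_between_subj <- 2 * sum((subj_means - ybar)^2)
  attr(out, "SS_total") <- ss_total
  attr(out, "SS_between_subjects") <- ss_between_subj
  attr(out, "SS_within_subjects") <- ss_total - ss_between_subj
  out
}
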
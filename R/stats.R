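#' Aggregate image-level AI scores to one score per subject
#'
#' The subject-level major-depression AI score is the mean (optionally
#' median) of that subject's image scores.
#'
#' @param scores data.frame with `row` (manifest row index) and `score`
#'   columns, e.g. the `scores` element of [evaluate_task()].
#' @param manifest the image manifest the rows refer to.
#' @param fun aggregation, `"mean"` (default) or `"median"`.
#' @return data.frame subject_id, ai_score, n_images.
#' @export
subject_ai_scores <- function(scores, manifest, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  if (any(scores$row < 1 | scores$row > nrow(manifest)))
    stop("score rows outside the manifest (orphan images)")
  sid <- manifest$subject_id[scores$row]
  agg <- tapply(scores$score, sid, if (fun == "mean") mean else stats::median)
  n <- tapply(scores$score, sid, length)
  data.frame(subject_id = names(agg), ai_score = as.numeric(agg),
             n_images = as.integer(n), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with two-sided p value
#'
#' Average ranks for ties; the p value comes from the t approximation
#' (`stats::cor.test`, exact = FALSE).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho` and `p` (`NA` with a warning for a constant
#'   input).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlate subject AI scores against questionnaire scales
#'
#' @param subj data.frame from [subject_ai_scores()].
#' @param roster cohort roster with subject_id and scale columns.
#' @param scales scale column names (default: SDS, SAS, the nine SCL-90
#'   subscales and the four EPQ subscales present in the roster).
#' @return data.frame scale, rho, p, n.
#' @export
correlate_scales <- function(subj, roster, scales = NULL) {
  m <- merge(subj, roster, by = "subject_id")
  if (is.null(scales)) {
    scales <- intersect(
      c("sds", "sas", grep("^scl90_", names(roster), value = TRUE),
        "epq_e", "epq_n", "epq_p", "epq_l"),
      names(roster))
  }
  out <- lapply(scales, function(sc) {
    s <- spearman(m$ai_score, m[[sc]])
    data.frame(scale = sc, rho = s$rho, p = s$p, n = nrow(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-group comparison with a normality-gated test choice
#'
#' Numeric variables: Shapiro-Wilk on each group; when both have p > 0.05
#' an independent-samples t test is used, otherwise the Mann-Whitney U test.
#' Factor/character variables are compared with a chi-squared test on the
#' contingency table.
#'
#' @param data data.frame; @param variable column to compare;
#' @param group column with exactly two levels.
#' @return data.frame variable, test, statistic, p.
#' @export
compare_groups <- function(data, variable, group) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("'group' must have exactly two levels")
  v <- data[[variable]]
  if (any(tapply(seq_along(v), g, length) < 2))
    stop("each group needs at least 2 observations")
  if (is.numeric(v)) {
    sw <- tapply(v, g, function(x) {
      if (length(unique(x)) < 3) return(0)  # degenerate -> non-normal path
      stats::shapiro.test(x)$p.value
    })
    if (all(sw > 0.05)) {
      tt <- stats::t.test(v ~ g)
      data.frame(variable = variable, test = "t", statistic = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v ~ g))
      data.frame(variable = variable, test = "mann-whitney",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }
  } else {
    tab <- table(v, g)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(variable = variable, test = "chi-squared",
               statistic = unname(ct$statistic), p = ct$p.value,
               stringsAsFactors = FALSE)
  }
}
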
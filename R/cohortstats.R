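# Cohort-level aggregation and the statistical battery: densities, the
# 2-SD outlier screen, Student's t-tests, two-way ANOVA with Tukey
# post-hoc, and Pearson correlation. All tests are thin, audited wrappers
# around the base R / car implementations; what is owned here is the
# battery structure, the outlier convention and the reporting.

#' Object density per square millimetre
#'
#' @param count object count (vectorised)
#' @param areaMm2 tissue area in mm^2 (> 0)
#' @return count / area
#' @examples objectDensity(50, 2)
#' @export
objectDensity <- function(count, areaMm2) {
  if (any(!is.finite(areaMm2)) || any(areaMm2 <= 0))
    stop("tissue area must be > 0")
  count / areaMm2
}

#' Screen for outliers more than 2 SD outside the group mean
#'
#' Flags values with `|x - mean| > 2 * SD`, computing mean and SD within
#' each group and including the candidate value itself (single pass, not
#' iterated). Flagging is reporting only: removal is a separate, explicit
#' decision, mirroring an analysis in which flagged cores are inspected
#' for staining artefacts before exclusion. Groups with fewer than 3
#' values are skipped with a warning.
#'
#' @param values numeric vector
#' @param group optional grouping vector (one group if omitted)
#' @param ids optional identifiers reported for flagged values
#' @param nSd flag beyond this many SDs (default 2)
#' @return list: `flagged` data.frame (id, group, value, z), `keep`
#'   logical vector aligned with `values`, `rule` description
#' @export
outlierScreen <- function(values, group = NULL, ids = NULL, nSd = 2) {
  if (is.null(group)) group <- rep("all", length(values))
  if (is.null(ids)) ids <- seq_along(values)
  keep <- rep(TRUE, length(values))
  z <- rep(NA_real_, length(values))
  for (g in unique(group)) {
    sel <- which(group == g & !is.na(values))
    if (length(sel) < 3L) {
      warning("group '", g, "' has fewer than 3 values; outlier screen skipped")
      next
    }
    m <- mean(values[sel]); s <- stats::sd(values[sel])
    if (s == 0) next  # all equal: nothing can be flagged
    z[sel] <- (values[sel] - m) / s
    keep[sel] <- abs(z[sel]) <= nSd
  }
  flagged <- data.frame(id = ids[!keep], group = group[!keep],
                        value = values[!keep], z = z[!keep])
  list(flagged = flagged, keep = keep,
       rule = sprintf("|x - group mean| > %g SD, single pass, candidate included", nSd))
}

# Shapiro-Wilk normality pre-check, reported but never used to switch tests
normalityCheck <- function(values, group) {
  lapply(split(values, group), function(v) {
    if (length(v) >= 3L && length(v) <= 5000L && stats::sd(v) > 0) {
      s <- stats::shapiro.test(v)
      list(W = unname(s$statistic), p = s$p.value)
    } else list(W = NA_real_, p = NA_real_)
  })
}

#' Two-group comparison (Student's t-test)
#'
#' Two-tailed two-sample t-test, pooled-variance Student's by default
#' (Welch by flag). A Shapiro-Wilk normality check per group is reported
#' alongside but does not switch the test.
#'
#' @param values numeric vector
#' @param group grouping vector with exactly two levels, each n >= 2
#' @param varEqual pooled variance (Student's) if TRUE, Welch otherwise
#' @return a [StatReport-class]
#' @examples
#' twoGroupTest(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
twoGroupTest <- function(values, group, varEqual = TRUE) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  sp <- split(values, group)
  if (any(vapply(sp, length, 0L) < 2L)) stop("each group needs n >= 2")
  degenerate <- stats::sd(sp[[1]]) == 0 && stats::sd(sp[[2]]) == 0
  if (degenerate && stats::var(values) == 0) {
    # identical constant groups: t = 0, p = 1 by convention
    est <- c(mean(sp[[1]]), mean(sp[[2]]))
    names(est) <- levels(group)
    return(new("StatReport", test = "Student's t-test (two-tailed)",
               estimate = est, statistic = c(t = 0),
               df = sum(lengths(sp)) - 2, pValue = 1,
               posthoc = NULL, normality = normalityCheck(values, group),
               outliers = list(), details = list(constant = TRUE)))
  }
  if (degenerate)
    stop("both groups have zero variance; the t statistic is undefined")
  tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = varEqual,
                      alternative = "two.sided")
  est <- unname(tt$estimate)
  names(est) <- levels(group)
  new("StatReport",
      test = if (varEqual) "Student's t-test (two-tailed)"
             else "Welch t-test (two-tailed)",
      estimate = est, statistic = c(t = unname(tt$statistic)),
      df = unname(tt$parameter), pValue = tt$p.value, posthoc = NULL,
      normality = normalityCheck(values, group), outliers = list(),
      details = list())
}

#' Two-way ANOVA with Tukey post-hoc
#'
#' Main effects, interaction, F statistics and p-values for a two-factor
#' design; balanced designs use the classical sequential decomposition
#' (which is exact there), unbalanced designs Type II sums of squares via
#' `car::Anova`. Tukey HSD pairwise comparisons are computed on the
#' configured margin (`"cells"` = factor-combination cells, or one
#' factor).
#'
#' @param values numeric response
#' @param factorA,factorB factors (>= 2 levels each, every crossed cell
#'   non-empty)
#' @param tukey margin for the Tukey table: `"cells"`, `"A"` or `"B"`
#' @return a [StatReport-class] with the Tukey table in `@posthoc`
#' @export
twoWayAnova <- function(values, factorA, factorB,
                        tukey = c("cells", "A", "B")) {
  tukey <- match.arg(tukey)
  fA <- droplevels(as.factor(factorA))
  fB <- droplevels(as.factor(factorB))
  if (nlevels(fA) < 2L || nlevels(fB) < 2L)
    stop("both factors need at least 2 levels")
  cells <- table(fA, fB)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", rownames(cells)[bad[1]], " x ",
         colnames(cells)[bad[2]])
  }
  d <- data.frame(y = values, fA = fA, fB = fB)
  fit <- stats::aov(y ~ fA * fB, data = d)
  if (stats::var(values) == 0) {
    return(new("StatReport", test = "two-way ANOVA",
               estimate = c(grand_mean = mean(values)),
               statistic = c(F_A = NA_real_, F_B = NA_real_, F_AB = NA_real_),
               df = rep(NA_real_, 3), pValue = rep(NA_real_, 3),
               posthoc = NULL, normality = list(), outliers = list(),
               details = list(constantResponse = TRUE)))
  }
  balanced <- length(unique(c(cells))) == 1L
  if (balanced) {
    sm <- summary(fit)[[1]]
    Fv <- sm[["F value"]][1:3]
    pv <- sm[["Pr(>F)"]][1:3]
    dfv <- sm[["Df"]]
    ss <- sm[["Sum Sq"]]
    details <- list(type = "classical (balanced)",
                    SS = stats::setNames(ss, rownames(sm)))
  } else {
    a2 <- car::Anova(stats::lm(y ~ fA * fB, data = d), type = 2)
    Fv <- a2[["F value"]][1:3]
    pv <- a2[["Pr(>F)"]][1:3]
    dfv <- a2[["Df"]]
    details <- list(type = "Type II (unbalanced)",
                    SS = stats::setNames(a2[["Sum Sq"]], rownames(a2)))
  }
  which.tk <- switch(tukey, cells = "fA:fB", A = "fA", B = "fB")
  tk <- stats::TukeyHSD(fit, which = which.tk)[[which.tk]]
  posthoc <- data.frame(comparison = rownames(tk), as.data.frame(tk),
                        row.names = NULL)
  names(posthoc) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  new("StatReport", test = "two-way ANOVA + Tukey HSD",
      estimate = c(grand_mean = mean(values)),
      statistic = c(F_A = Fv[1], F_B = Fv[2], F_AB = Fv[3]),
      df = as.numeric(dfv[1:min(4, length(dfv))]),
      pValue = pv, posthoc = posthoc, normality = list(),
      outliers = list(), details = details)
}

#' Pearson correlation between two paired quantities
#'
#' @param x,y paired numeric vectors, n >= 3, non-degenerate
#' @return a [StatReport-class] with r and the two-sided p-value
#' @export
correlateMarkers <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  new("StatReport", test = "Pearson correlation (two-sided)",
      estimate = c(r = unname(ct$estimate)),
      statistic = c(t = unname(ct$statistic)), df = unname(ct$parameter),
      pValue = ct$p.value, posthoc = NULL, normality = list(),
      outliers = list(), details = list(n = length(x)))
}

#' Run the cohort comparison battery
#'
#' Given a per-core results table and a group column, runs two-group
#' Student's t-tests on the requested measures (with the 2-SD outlier
#' screen reported per measure), optional two-way ANOVAs of
#' size-class x group on paired small/large columns, and optional Pearson
#' correlations between measure pairs. With a single group only the
#' descriptive table is returned.
#'
#' @param cores data.frame with one row per core
#' @param measures character vector of numeric columns to compare between
#'   groups
#' @param group name of the group column (default `"group"`)
#' @param anovaMeasures named list; each element `c(smallCol, largeCol)`
#'   is reshaped to long form and tested as size-class x group
#' @param correlations list of `c(xCol, yCol)` pairs
#' @param removeOutliers if TRUE, values flagged by the screen are
#'   excluded from the tests (they are always reported)
#' @return list: `tidy` (one row per test), `reports` (named list of
#'   [StatReport-class]), `descriptives` (per group mean/sd/n)
#' @export
cohortReport <- function(cores, measures, group = "group",
                         anovaMeasures = list(), correlations = list(),
                         removeOutliers = FALSE) {
  missing <- setdiff(c(measures, group, unlist(anovaMeasures),
                       unlist(correlations)), names(cores))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  g <- as.factor(cores[[group]])
  if (any(table(g) < 2L)) stop("need at least 2 cores per group")

  desc <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(levels(g), function(lv) {
      v <- cores[[m]][g == lv]
      data.frame(measure = m, group = lv, n = sum(!is.na(v)),
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
    }))
  }))

  reports <- list()
  tidy <- data.frame()
  if (nlevels(g) == 2L) {
    for (m in measures) {
      v <- cores[[m]]
      scr <- withCallingHandlers(
        outlierScreen(v, group = g, ids = seq_len(nrow(cores))),
        warning = function(w) invokeRestart("muffleWarning"))
      use <- if (removeOutliers) scr$keep else rep(TRUE, length(v))
      use <- use & !is.na(v)
      rep_m <- tryCatch(twoGroupTest(v[use], g[use]), error = function(e) e)
      if (inherits(rep_m, "error")) {
        # e.g. both groups constant at different values: report, don't fail
        tidy <- rbind(tidy, data.frame(
          measure = m, test = paste("skipped:", conditionMessage(rep_m)),
          estimate_1 = NA_real_, estimate_2 = NA_real_,
          statistic = NA_real_, df = NA_real_, p_value = NA_real_,
          n_flagged = nrow(scr$flagged)))
        next
      }
      rep_m@outliers <- scr["flagged"]
      reports[[m]] <- rep_m
      tidy <- rbind(tidy, data.frame(
        measure = m, test = rep_m@test,
        estimate_1 = rep_m@estimate[1], estimate_2 = rep_m@estimate[2],
        statistic = rep_m@statistic[1], df = rep_m@df[1],
        p_value = rep_m@pValue[1], n_flagged = nrow(scr$flagged)))
    }
    for (nm in names(anovaMeasures)) {
      cols <- anovaMeasures[[nm]]
      long <- data.frame(
        y = c(cores[[cols[1]]], cores[[cols[2]]]),
        size_class = rep(c("small", "large"), each = nrow(cores)),
        grp = rep(g, 2))
      ok <- !is.na(long$y)
      rep_a <- twoWayAnova(long$y[ok], long$size_class[ok], long$grp[ok])
      reports[[nm]] <- rep_a
      tidy <- rbind(tidy, data.frame(
        measure = nm, test = rep_a@test,
        estimate_1 = rep_a@estimate[1], estimate_2 = NA,
        statistic = rep_a@statistic[2], df = rep_a@df[1],
        p_value = rep_a@pValue[2], n_flagged = NA))
    }
    for (pair in correlations) {
      nm <- paste(pair, collapse = "_vs_")
      rep_c <- correlateMarkers(cores[[pair[1]]], cores[[pair[2]]])
      reports[[nm]] <- rep_c
      tidy <- rbind(tidy, data.frame(
        measure = nm, test = rep_c@test,
        estimate_1 = rep_c@estimate[1], estimate_2 = NA,
        statistic = rep_c@statistic[1], df = rep_c@df[1],
        p_value = rep_c@pValue[1], n_flagged = NA))
    }
  }
  rownames(tidy) <- NULL
  list(tidy = tidy, reports = reports, descriptives = desc)
}
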
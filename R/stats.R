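# Group x condition analysis layer: split-plot ("mixed") ANOVA with an
# optional gait-speed covariate, Greenhouse-Geisser sphericity correction
# and Bonferroni-corrected post hoc t tests.

#' Mixed (split-plot) ANOVA on a cohort table
#'
#' Fits a between-subject factor `group` and a within-subject factor
#' `condition` for one measure, optionally adjusted for gait speed
#' (grand-mean-centered; entered per subject x condition by default since
#' gait speed varies with condition, or as the subject mean). Subjects with
#' incomplete condition cells are excluded listwise with a warning.
#' Greenhouse-Geisser correction of the within-subject tests is applied
#' when Mauchly's sphericity test is significant at `alpha`
#' (`gg = "auto"`), always (`TRUE`), or never (`FALSE`).
#'
#' @param table a [cohort_table()] (long format).
#' @param measure measure name to analyse.
#' @param covariate `"within"` (per-cell gait speed, default), `"subject_mean"`,
#'   or `"none"`.
#' @param gg `"auto"`, `TRUE` or `FALSE`.
#' @param alpha significance threshold used for the Mauchly decision.
#' @return object of class `anova_result`: `effects` (data.frame with
#'   `effect, df_num, df_den, F, p, gg_applied, epsilon, p_gg`),
#'   `epsilon_gg`, `mauchly_W`, `mauchly_p`, `n_subjects`, `excluded`.
#' @export
mixed_anova <- function(table, measure, covariate = c("within", "subject_mean",
                                                      "none"),
                        gg = "auto", alpha = 0.05) {
  covariate <- match.arg(covariate)
  df <- as.data.frame(table)
  df <- df[df$measure == measure & !is.na(df$value), ]
  if (!nrow(df)) stop("measure '", measure, "' not present in the table")
  conds <- sort(unique(df$condition))
  k <- length(conds)
  if (k < 2L) stop("need at least 2 conditions")
  # listwise exclusion of subjects without a complete condition set
  cnt <- tapply(df$condition, df$subject_id,
                function(cc) length(unique(cc)))
  complete <- names(cnt)[cnt == k]
  excluded <- setdiff(names(cnt), complete)
  if (length(excluded))
    warning("excluding ", length(excluded),
            " subject(s) with incomplete condition cells: ",
            paste(excluded, collapse = ", "))
  df <- df[df$subject_id %in% complete, ]
  df$subject <- factor(df$subject_id)
  df$group <- factor(df$group)
  df$condition <- factor(df$condition, levels = conds)
  g <- nlevels(df$group)
  n <- nlevels(df$subject)
  if (g < 2L) stop("need at least 2 groups")
  if (min(table(unique(df[c("subject", "group")])$group)) < 2L)
    stop("need at least 2 subjects per group")

  has_cov <- covariate != "none" && "gait_speed_mps" %in% names(df) &&
    !anyNA(df$gait_speed_mps)
  if (has_cov) {
    cv <- df$gait_speed_mps
    if (covariate == "subject_mean")
      cv <- stats::ave(cv, df$subject)
    df$speed_c <- cv - mean(cv)
    if (stats::var(df$speed_c) < 1e-12) has_cov <- FALSE
  }
  # all-equal response: every effect is exactly zero; aov would return the
  # ratio of two floating-point zeros
  degenerate <- stats::var(df$value) <= 1e-20 * max(1, mean(df$value)^2)
  form <- if (has_cov)
    value ~ speed_c + group * condition + Error(subject)
  else
    value ~ group * condition + Error(subject)
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    res_i <- match("Residuals", rn)
    df_den <- tab[res_i, "Df"]
    ms_den <- tab[res_i, "Mean Sq"]
    for (i in seq_len(nrow(tab))) {
      if (i == res_i) next
      ssq <- tab[i, "Sum Sq"]
      f <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
      if (degenerate) { f <- 0; p <- 1 }
      else if (!is.finite(f)) {                # 0/0 cells
        if (ssq <= 1e-12) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = sub("speed_c", "gait_speed", rn[i]),
        df_num = tab[i, "Df"], df_den = df_den, F = f, p = p)
    }
  }
  eff <- do.call(rbind, rows)

  sph <- sphericity_tests(df)
  eps <- max(min(sph$epsilon_gg, 1), 1 / (k - 1))
  apply_gg <- if (identical(gg, "auto")) is.finite(sph$mauchly_p) &&
    sph$mauchly_p < alpha else isTRUE(gg)
  within_eff <- eff$effect %in% c("condition", "group:condition")
  eff$gg_applied <- within_eff & apply_gg
  eff$epsilon <- ifelse(within_eff, eps, NA_real_)
  eff$p_gg <- eff$p
  sel <- which(eff$gg_applied & is.finite(eff$F) & eff$F > 0)
  eff$p_gg[sel] <- stats::pf(eff$F[sel], eps * eff$df_num[sel],
                             eps * eff$df_den[sel], lower.tail = FALSE)
  rownames(eff) <- NULL
  structure(list(effects = eff, epsilon_gg = eps, mauchly_W = sph$mauchly_W,
                 mauchly_p = sph$mauchly_p, n_subjects = n,
                 excluded = excluded, measure = measure,
                 conditions = conds),
            class = "anova_result")
}

# Greenhouse-Geisser epsilon and Mauchly's test from the pooled
# within-group covariance of the subject x condition matrix
sphericity_tests <- function(df) {
  Y <- tapply(df$value, list(df$subject, df$condition), mean)
  grp <- tapply(as.character(df$group), df$subject, `[`, 1L)[rownames(Y)]
  k <- ncol(Y); n <- nrow(Y); g <- length(unique(grp))
  if (k < 3L || n - g < k) {   # sphericity trivially holds / not estimable
    return(list(epsilon_gg = 1, mauchly_W = 1, mauchly_p = NA_real_))
  }
  resid <- Y
  for (gg in unique(grp)) {
    i <- grp == gg
    resid[i, ] <- sweep(Y[i, , drop = FALSE], 2,
                        colMeans(Y[i, , drop = FALSE]))
  }
  S <- crossprod(resid) / (n - g)
  C <- qr.Q(qr(stats::contr.helmert(k)))        # orthonormal contrasts
  M <- t(C) %*% S %*% C
  tr <- sum(diag(M))
  eps <- tr^2 / ((k - 1) * sum(M * M))
  detM <- det(M)
  W <- if (detM <= 0) 0 else detM / (tr / (k - 1))^(k - 1)
  dfM <- k * (k - 1) / 2 - 1
  nprime <- n - g
  chi <- -(nprime - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1))) *
    log(max(W, .Machine$double.xmin))
  p <- stats::pchisq(chi, dfM, lower.tail = FALSE)
  list(epsilon_gg = eps, mauchly_W = W, mauchly_p = p)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA for '%s' (%d subjects)\n", x$measure, x$n_subjects))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    gg_note <- if (eff$gg_applied[i])
      sprintf(" [GG eps=%.3f, p=%.4g]", eff$epsilon[i], eff$p_gg[i]) else ""
    cat(sprintf("  %-16s F(%.4g, %.4g) = %.4g, p = %.4g%s\n",
                eff$effect[i], eff$df_num[i], eff$df_den[i], eff$F[i],
                eff$p[i], gg_note))
  }
  if (is.finite(x$mauchly_p))
    cat(sprintf("  Mauchly W = %.4g, p = %.4g\n", x$mauchly_W, x$mauchly_p))
  invisible(x)
}

#' Bonferroni-corrected post hoc pairwise t tests
#'
#' All pairwise comparisons of one factor's levels for one measure, with
#' Bonferroni adjustment `p_adj = min(1, m * p)` over the `m` pairs. For the
#' within-subject factor (`condition`) paired t tests on the subjects'
#' cell values are used; for `group`, two-sample t tests on the subjects'
#' condition means. Following the convention of running post hocs only
#' after a significant omnibus effect, the ANOVA main effect is checked
#' first unless `force = TRUE`.
#'
#' @param table a [cohort_table()].
#' @param measure measure name.
#' @param factor `"group"` or `"condition"`.
#' @param force run the comparisons regardless of the omnibus p value.
#' @param alpha omnibus significance threshold.
#' @param anova optional precomputed [mixed_anova()] result.
#' @return data.frame with `level_1, level_2, mean_diff, t, df, p, p_adj`
#'   (empty when the omnibus test is not significant and `force` is off);
#'   pairs with fewer than 2 observations per level are skipped with a
#'   warning.
#' @export
bonferroni_posthoc <- function(table, measure, factor = c("group", "condition"),
                               force = FALSE, alpha = 0.05, anova = NULL) {
  factor <- match.arg(factor)
  empty <- data.frame(level_1 = character(0), level_2 = character(0),
                      mean_diff = numeric(0), t = numeric(0),
                      df = numeric(0), p = numeric(0), p_adj = numeric(0))
  if (!force) {
    if (is.null(anova)) anova <- mixed_anova(table, measure)
    eff <- anova$effects
    i <- match(factor, eff$effect)
    p_main <- if (eff$gg_applied[i]) eff$p_gg[i] else eff$p[i]
    if (!is.finite(p_main) || p_main >= alpha) {
      message("omnibus ", factor, " effect not significant (p = ",
              signif(p_main, 3), "); no post hoc tests run")
      return(empty)
    }
  }
  df <- as.data.frame(table)
  df <- df[df$measure == measure & !is.na(df$value), ]
  if (factor == "group") {
    vals <- tapply(df$value, df$subject_id, mean)
    grp <- tapply(as.character(df$group), df$subject_id, `[`, 1L)[names(vals)]
    levels_ <- sort(unique(grp))
    get <- function(l) vals[grp == l]
    paired <- FALSE
  } else {
    Y <- tapply(df$value, list(df$subject_id, df$condition), mean)
    levels_ <- colnames(Y)
    get <- function(l) Y[, l]
    paired <- TRUE
  }
  pairs <- utils::combn(levels_, 2, simplify = FALSE)
  m <- length(pairs)
  out <- list()
  for (pr in pairs) {
    a <- get(pr[1]); b <- get(pr[2])
    if (paired) {
      ok <- !is.na(a) & !is.na(b); a <- a[ok]; b <- b[ok]
    } else {
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
    }
    if (length(a) < 2L || length(b) < 2L) {
      warning("skipping pair ", pr[1], " vs ", pr[2],
              ": fewer than 2 observations in a level")
      next
    }
    tt <- if (paired) stats::t.test(a, b, paired = TRUE)
          else stats::t.test(a, b, var.equal = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      level_1 = pr[1], level_2 = pr[2], mean_diff = mean(a) - mean(b),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, p_adj = min(1, m * tt$p.value))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
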
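# Group statistics over morphometry tables, following the workflow used
# for the islet measurements: Shapiro-Wilk normality screening with an
# optional natural-log transform, two-by-two independent-means t tests
# (Welch by default, pooled variance on request), one-way fixed-effects
# ANOVA, and Pearson correlation. Reported group means and SDs always
# describe the untransformed data.

#' Shapiro-Wilk normality check
#'
#' @param values numeric sample, `3 <= n <= 5000`, nonzero variance.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(values) < 3) stop("too few observations (n < 3)")
  if (length(values) > 5000) stop("too many observations (n > 5000)")
  if (var(values) == 0) stop("zero variance sample")
  s <- shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Transform a sample towards normality if needed
#'
#' If the Shapiro-Wilk p-value is at least `alpha` the data are used as
#' is; otherwise, when all values are strictly positive, the natural log
#' is applied (and normality re-checked, informatively). No shift is ever
#' applied silently: a non-normal sample containing nonpositive values is
#' an error. Downstream reports always present untransformed means and
#' SDs regardless of the flag.
#'
#' @param values numeric sample.
#' @param alpha screening level.
#' @return list with `values` (working values), `transform`
#'   (`"none"` or `"log"`), and the pre/post Shapiro p-values.
#' @export
transform_if_needed <- function(values, alpha = 0.05) {
  chk <- normality_check(values)
  if (chk$p >= alpha) {
    return(list(values = values, transform = "none", p_raw = chk$p,
                p_transformed = NA_real_))
  }
  if (any(values <= 0)) {
    stop("sample fails normality and contains nonpositive values; ",
         "log transform not applicable (no shift is applied)")
  }
  lv <- log(values)
  p2 <- if (var(lv) > 0) normality_check(lv)$p else NA_real_
  list(values = lv, transform = "log", p_raw = chk$p, p_transformed = p2)
}

# decide a common transform for several samples: screen the pooled
# within-group residuals, apply log to every sample if indicated
resolve_transform <- function(samples, transform = "auto", alpha = 0.05) {
  if (transform == "none") return("none")
  if (transform == "log") {
    if (any(unlist(samples) <= 0)) stop("log transform on nonpositive values")
    return("log")
  }
  resid <- unlist(lapply(samples, function(s) s - mean(s)))
  if (length(resid) < 3 || length(resid) > 5000 || var(resid) == 0) {
    return("none")
  }
  p <- shapiro.test(resid)$p.value
  if (p >= alpha) return("none")
  if (any(unlist(samples) <= 0)) return("none")  # cannot log; keep raw
  "log"
}

#' Two-by-two independent-means comparison
#'
#' Two-sample t test on working values: Welch (unequal variance) by
#' default, pooled variance on request. With `transform = "auto"` the
#' pooled within-group residuals are screened with Shapiro-Wilk at
#' `alpha` and a natural-log transform is applied to both samples when
#' indicated (and possible). Reported means and SDs are of the
#' untransformed data.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param var_equal pooled-variance t test instead of Welch.
#' @param transform `"auto"`, `"none"` or `"log"`.
#' @param alpha significance level carried into the result.
#' @param names group names for reporting.
#' @return a `group_comparison` list: per-group `n`, `mean`, `sd`
#'   (untransformed), `transform`, `statistic` (t), `df`, `p`, `alpha`,
#'   `method`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE, transform = "auto",
                           alpha = 0.05, names = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  tf <- resolve_transform(list(a, b), transform, alpha)
  wa <- if (tf == "log") log(a) else a
  wb <- if (tf == "log") log(b) else b
  tt <- t.test(wa, wb, var.equal = var_equal)
  structure(list(
    groups = names,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sd = c(sd(a), sd(b)),
    transform = tf,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    alpha = alpha,
    method = if (var_equal) "pooled t" else "Welch t"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s, t = %.3f, p = %.4g (transform: %s)\n",
              x$method, x$groups[1], x$groups[2], x$statistic, x$p,
              x$transform))
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' @param groups list of numeric samples (>= 2 groups, each `n >= 2`).
#' @param transform `"auto"`, `"none"` or `"log"` (applied to all groups).
#' @param alpha screening level for the auto transform.
#' @return list with `F`, `df`, `p`, `transform`, per-group `n`, `mean`,
#'   `sd` of untransformed data.
#' @export
one_way_anova <- function(groups, transform = "auto", alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  allv <- unlist(groups)
  if (var(allv) == 0) stop("all-constant data")
  tf <- resolve_transform(groups, transform, alpha)
  work <- if (tf == "log") lapply(groups, log) else groups
  y <- unlist(work)
  g <- factor(rep(seq_along(work), lengths(work)))
  k <- length(work); n <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(lengths(work) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  list(
    F = f, df = c(df1, df2), p = pf(f, df1, df2, lower.tail = FALSE),
    transform = tf,
    n = lengths(groups),
    mean = vapply(groups, mean, 1),
    sd = vapply(groups, sd, 1)
  )
}

#' Pearson correlation
#'
#' @param x,y equal-length numeric samples, `n >= 3`, both nonconstant.
#' @param names variable names for reporting.
#' @return a `correlation_result`: `r`, `n`, `p`, variable names.
#' @export
pearson_correlation <- function(x, y, names = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("too few observations (n < 3)")
  if (var(x) == 0 || var(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(
    variables = names, n = length(x),
    r = unname(ct$estimate), p = ct$p.value
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson %s ~ %s: r = %.3f, n = %d, p = %.4g\n",
              x$variables[1], x$variables[2], x$r, x$n, x$p))
  invisible(x)
}

#' Normal Q-Q diagnostic plot
#'
#' Purely diagnostic: the numeric Shapiro-Wilk screen, not the plot,
#' decides whether a transform is applied.
#' @param values numeric sample.
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
qq_plot <- function(values, path, main = "normal Q-Q") {
  grDevices::png(path, width = 450, height = 450)
  on.exit(grDevices::dev.off())
  stats::qqnorm(values, main = main, pch = 16, col = "grey30")
  stats::qqline(values, col = "firebrick")
  invisible(path)
}

#' Group statistics report over a morphometry table
#'
#' For each quantified metric, per-condition mean +/- SD and n
#' (untransformed), all pairwise two-by-two comparisons, a one-way ANOVA
#' of islet volume on condition, and the two structural correlations
#' (node count ~ islet volume, hole fraction x volume ~ islet volume).
#' An optional Holm correction over each metric's pairwise p-values is
#' off by default, and its use is recorded in the report.
#'
#' @param records tidy morphometry data frame (one row per islet x
#'   marker) as produced by [measure_islet()] / [run_pipeline()].
#' @param alpha significance level.
#' @param var_equal pooled-variance t tests.
#' @param transform `"auto"`, `"none"` or `"log"`.
#' @param holm apply Holm correction within each metric.
#' @return nested list, JSON-serialisable.
#' @export
group_stats_report <- function(records, alpha = 0.05, var_equal = FALSE,
                               transform = "auto", holm = FALSE) {
  conditions <- unique(records$condition)
  conditions <- conditions[!is.na(conditions)]
  metric_cols <- c(
    volume_fraction_pct = "volume_fraction_pct",
    node_count = "node_count",
    hole_fraction_pct = "hole_fraction_pct",
    mean_intensity_au = "mean_intensity_au"
  )
  report <- list(alpha = alpha, holm = holm, metrics = list())
  for (mk in unique(records$marker)) {
    sub <- records[records$marker == mk, ]
    for (mc in metric_cols) {
      vals <- sub[[mc]]
      if (all(is.na(vals))) next
      per_group <- lapply(conditions, function(cd) {
        v <- vals[sub$condition == cd]
        v[!is.na(v)]
      })
      names(per_group) <- conditions
      entry <- list(
        groups = lapply(per_group, function(v) {
          list(n = length(v), mean = mean(v), sd = sd(v))
        }),
        pairwise = list()
      )
      if (length(conditions) >= 2) {
        pairs <- utils::combn(as.character(conditions), 2, simplify = FALSE)
        cmp <- lapply(pairs, function(pr) {
          ga <- per_group[[pr[1]]]; gb <- per_group[[pr[2]]]
          if (length(ga) < 2 || length(gb) < 2) return(NULL)
          if (var(c(ga - mean(ga), gb - mean(gb))) == 0) return(NULL)
          compare_groups(ga, gb, var_equal = var_equal,
                         transform = transform, alpha = alpha, names = pr)
        })
        cmp <- cmp[!vapply(cmp, is.null, TRUE)]
        if (holm && length(cmp) > 1) {
          padj <- stats::p.adjust(vapply(cmp, function(x) x$p, 1), "holm")
          for (i in seq_along(cmp)) cmp[[i]]$p_holm <- padj[i]
        }
        entry$pairwise <- lapply(cmp, unclass)
      }
      report$metrics[[paste(mk, mc, sep = ".")]] <- entry
    }
  }
  # islet volume: one row per islet (volume repeats across markers)
  one <- records[!duplicated(paste(records$islet_id, records$condition,
                                   records$stack_id)), ]
  vol_groups <- lapply(conditions, function(cd) {
    one$islet_volume_um3[one$condition == cd]
  })
  names(vol_groups) <- conditions
  if (length(vol_groups) >= 2 && all(lengths(vol_groups) >= 2)) {
    an <- one_way_anova(vol_groups, transform = transform, alpha = alpha)
    report$islet_volume_anova <- an
  }
  lam <- records[records$marker == "laminin" & !is.na(records$node_count), ]
  if (nrow(lam) >= 3 && var(lam$node_count) > 0 &&
      var(lam$islet_volume_um3) > 0) {
    report$correlation_nodes_volume <- unclass(pearson_correlation(
      lam$node_count, lam$islet_volume_um3,
      names = c("node_count", "islet_volume_um3")
    ))
  }
  ec <- records[records$marker == "ecadherin" &
                  !is.na(records$hole_fraction_pct), ]
  if (nrow(ec) >= 3) {
    hole_vol <- ec$hole_fraction_pct / 100 * ec$islet_volume_um3
    if (var(hole_vol) > 0 && var(ec$islet_volume_um3) > 0) {
      report$correlation_holes_volume <- unclass(pearson_correlation(
        hole_vol, ec$islet_volume_um3,
        names = c("hole_volume_um3", "islet_volume_um3")
      ))
    }
  }
  report
}
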
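#' Choose the test family by per-group normality
#'
#' Shapiro-Wilk on each group at `alpha`; if any group rejects normality the
#' nonparametric family (Kruskal-Wallis + Dunn) is used, otherwise one-way
#' ANOVA + Tukey.
#'
#' @param groups named list of numeric vectors, each of length >= 3.
#' @param alpha Shapiro-Wilk level, default 0.05.
#' @return `"kruskal_dunn"` or `"anova_tukey"`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  ns <- vapply(groups, length, 0L)
  if (any(ns < 3)) stop("each group needs n >= 3 for the normality gate")
  p <- vapply(groups, function(g) shapiro.test(g)$p.value, 0)
  if (any(p < alpha)) "kruskal_dunn" else "anova_tukey"
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise post hoc
#'
#' Omnibus Kruskal-Wallis H test; pairwise Dunn z statistics on the pooled
#' ranks with tie correction, two-sided p-values adjusted for multiplicity
#' (Holm by default). Group summaries are median +/- IQR/2.
#'
#' @param groups named list of >= 2 numeric vectors.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]:
#'   `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return object of class `group_comparison`: `test_used`, `group_names`,
#'   `n`, `omnibus_p`, `posthoc` (symmetric matrix of adjusted p, unit
#'   diagonal), `stars`, `summaries` (median, iqr_half), `p_adjust_method`,
#'   `dip` (Hartigan-style dip statistic per group, descriptive only).
#' @export
kruskal_dunn <- function(groups, p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  if (length(unique(x)) == 1L) {
    omnibus <- 1
    k <- length(groups)
    post <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  } else {
    omnibus <- kruskal.test(x, g)$p.value
    rk <- rank(x)
    N <- length(x)
    rbar <- tapply(rk, g, mean)
    n <- tapply(rk, g, length)
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    k <- length(groups)
    post <- matrix(NA_real_, k, k,
                   dimnames = list(names(groups), names(groups)))
    diag(post) <- 1
    raw <- c()
    pairs <- which(upper.tri(post), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
      z <- (rbar[i] - rbar[j]) / se
      raw[r] <- 2 * pnorm(-abs(z))
    }
    adj <- p.adjust(raw, method = p_adjust)
    for (r in seq_len(nrow(pairs))) {
      post[pairs[r, 1], pairs[r, 2]] <- adj[r]
      post[pairs[r, 2], pairs[r, 1]] <- adj[r]
    }
  }
  summaries <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    median = vapply(groups, median, 0),
    iqr_half = vapply(groups, function(v) median_iqr2(v)["iqr_half"], 0),
    dip = vapply(groups, function(v)
      if (length(v) >= 4) dip_statistic(v) else NA_real_, 0),
    row.names = NULL)
  new_group_comparison("kruskal_dunn", groups, omnibus, post, summaries,
                       p_adjust)
}

#' One-way ANOVA with Tukey's HSD post hoc
#'
#' Omnibus F test; Tukey honestly-significant-difference pairwise adjusted
#' p-values. Group summaries are mean +/- SD.
#'
#' @param groups named list of >= 2 numeric vectors, each n >= 2.
#' @return a `group_comparison` object (see [kruskal_dunn()]); `summaries`
#'   carries mean and sd.
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  k <- length(groups)
  post <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  if (length(unique(x)) == 1L) {
    omnibus <- 1
  } else {
    fit <- aov(x ~ g)
    tab <- summary(fit)[[1]]
    if (tab["Residuals", "Sum Sq"] <= 0) {
      # zero within-group variance: fall back to the degenerate p = 1 path
      # only if the groups are also identical; otherwise the contrast is
      # infinitely significant
      omnibus <- if (length(unique(vapply(groups, mean, 0))) == 1L) 1 else 0
      post[] <- omnibus
      diag(post) <- 1
    } else {
      omnibus <- tab["g", "Pr(>F)"]
      tk <- TukeyHSD(fit)$g
      for (r in rownames(tk)) {
        ab <- strsplit(r, "-", fixed = TRUE)[[1]]
        post[ab[1], ab[2]] <- tk[r, "p adj"]
        post[ab[2], ab[1]] <- tk[r, "p adj"]
      }
    }
  }
  summaries <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, sd, 0),
    row.names = NULL)
  new_group_comparison("anova_tukey", groups, omnibus, post, summaries,
                       "tukey")
}

new_group_comparison <- function(test, groups, omnibus, post, summaries,
                                 adjust) {
  structure(list(test_used = test, group_names = names(groups),
                 n = vapply(groups, length, 0L), omnibus_p = omnibus,
                 posthoc = post, stars = apply(post, c(1, 2), p_stars),
                 summaries = summaries, p_adjust_method = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  fam <- switch(x$test_used,
                kruskal_dunn = "Kruskal-Wallis + Dunn",
                anova_tukey = "one-way ANOVA + Tukey HSD", x$test_used)
  cat(sprintf("<group_comparison> %s (%d groups; p-adjust: %s)\n",
              fam, length(x$group_names), x$p_adjust_method))
  cat(sprintf("  omnibus p = %.4g\n", x$omnibus_p))
  print(x$summaries, digits = digits)
  cat("  pairwise adjusted p:\n")
  print(signif(x$posthoc, digits))
  invisible(x)
}

#' Map a p-value to significance stars
#'
#' `* <= 0.05`, `** <= 0.01`, `*** <= 0.001`, `**** <= 0.0001`, else `"ns"`.
#'
#' @param p numeric p-value.
#' @return character.
#' @export
p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else
    if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Median and half the interquartile range
#'
#' Quartiles use linear interpolation (type 7); IQR/2 is
#' convention-sensitive, so the convention is part of the contract.
#'
#' @param values numeric, n >= 1.
#' @return named numeric: `median`, `iqr_half`.
#' @export
median_iqr2 <- function(values) {
  if (!length(values)) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr_half = (q[3] - q[1]) / 2)
}

#' Dip-style unimodality statistic (descriptive)
#'
#' Sup-norm distance from the empirical cdf to the nearest unimodal cdf,
#' computed over all mode placements: for a mode at the k-th order
#' statistic, the closest cdf that is convex to the left and concave to the
#' right sits halfway inside the largest convexity violation on each side
#' (greatest convex minorant below the mode, least concave majorant above),
#' and the statistic minimizes the larger of the two half-violations over
#' k. Unimodal samples give values of order n^-1/2; well-separated equal
#' modes approach 0.25. Used only as a descriptive multimodality QC column;
#' no p-value is computed.
#'
#' @param x numeric vector, n >= 4.
#' @return the statistic (between 0 and 0.25).
#' @export
dip_statistic <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (x[1] == x[n]) return(0)
  f <- seq_len(n) / n
  # collapse ties: keep the largest ecdf value at each distinct x
  keep <- c(x[-n] != x[-1], TRUE)
  x <- x[keep]; f <- f[keep]
  m <- length(x)
  # left[k]: largest (F - GCM) over points 1..k; right[k]: largest
  # (LCM - F) over points k..m. Both built incrementally with a monotone
  # hull.
  left <- numeric(m)
  hull <- c(1L)
  dev <- 0
  for (i in seq_len(m)[-1]) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((f[b] - f[a]) * (x[i] - x[b]) >= (f[i] - f[b]) * (x[b] - x[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
    # deviation of interior points above the updated last hull segment
    a <- hull[length(hull) - 1]
    js <- which(x > x[a] & x < x[i])
    if (length(js)) {
      g <- f[a] + (f[i] - f[a]) * (x[js] - x[a]) / (x[i] - x[a])
      dev <- max(dev, max(f[js] - g))
    }
    left[i] <- dev
  }
  right <- numeric(m)
  hull <- c(m)
  dev <- 0
  for (i in rev(seq_len(m))[-1]) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((f[a] - f[b]) * (x[i] - x[b]) <= (f[i] - f[b]) * (x[b] - x[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
    a <- hull[length(hull) - 1]
    js <- which(x > x[i] & x < x[a])
    if (length(js)) {
      g <- f[i] + (f[a] - f[i]) * (x[js] - x[i]) / (x[a] - x[i])
      dev <- max(dev, max(g - f[js]))
    }
    right[i] <- dev
  }
  min(pmax(left, right)) / 2
}
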
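#' @include dvh.R
NULL

#' Between-plan increment percentage
#'
#' 100 x (comparator - reference) / reference: the percent by which the
#' comparator exceeds the reference. Full precision is kept internally;
#' round only at report time (conventionally 2 decimals).
#'
#' @param reference Reference value (nonzero).
#' @param comparator Comparator value.
#' @return Increment in percent.
#' @examples
#' round(incrementPercent(64.42, 77.42), 2)  # 20.18
#' @export
incrementPercent <- function(reference, comparator) {
  if (any(reference == 0)) stop("reference value must be nonzero")
  100 * (comparator - reference) / reference
}

#' One-way ANOVA with LSD pairwise comparisons
#'
#' Classical one-way analysis of variance across plan groups, followed by
#' Fisher's least-significant-difference pairwise tests: each pair is
#' compared with a t statistic built on the pooled within-group mean
#' square, on the within-group degrees of freedom, with no further
#' multiplicity correction. When the between-group sum of squares is
#' (numerically) zero the degenerate branch F = 0, p = 1 is returned.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 values each.
#' @param alpha Significance level for the flags (default 0.05).
#' @return List with elements \code{F}, \code{p}, \code{df} (length 2) and
#'   \code{pairwise}, a data.frame of group pairs with mean difference,
#'   t, p and significance flag.
#' @examples
#' anovaLSD(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))$F
#' @export
anovaLSD <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  n <- tabulate(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  if (any(n < 2L)) stop("each group needs at least two values")
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df <- c(k - 1L, N - k)
  if (ssb < 1e-12 * max(1, sum(values^2))) {
    Fv <- 0; pv <- 1
  } else {
    msw <- ssw / df[2]
    Fv <- if (msw == 0) Inf else (ssb / df[1]) / msw
    pv <- stats::pf(Fv, df[1], df[2], lower.tail = FALSE)
  }
  msw <- ssw / df[2]
  pairs <- utils::combn(levels(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(msw * (1 / n[levels(groups) == i] + 1 / n[levels(groups) == j]))
    diffm <- means[[j]] - means[[i]]
    tv <- if (se == 0) { if (diffm == 0) 0 else Inf * sign(diffm) } else diffm / se
    p <- 2 * stats::pt(abs(tv), df[2], lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, diff = diffm, t = tv, p = p,
               significant = p < alpha)
  })
  list(F = Fv, p = pv, df = df,
       pairwise = do.call(rbind, c(pw, make.row.names = FALSE)))
}

#' Summarize a cohort metric table
#'
#' Aggregates a long-format per-subject metric table (columns subject,
#' plan, structure, metric, value) into the standard cohort report:
#' per-plan mean and sample (n-1) standard deviation for every
#' (structure, metric), the three between-plan increment percentages
#' computed on the plan means (a per-subject mode averaging individual
#' increments is available), and a one-way ANOVA with LSD pairwise p
#' values across plans. Cells with fewer than two subjects are reported
#' with \code{NA} statistics rather than dropped silently.
#'
#' @param table Long-format data.frame with columns \code{subject},
#'   \code{plan}, \code{structure}, \code{metric}, \code{value}; each
#'   (subject, plan, structure, metric) at most once.
#' @param incrementsOnMeans Compute increments on plan means (default,
#'   matching how published cohort tables derive them); \code{FALSE}
#'   averages per-subject increments instead.
#' @return A data.frame with one row per (structure, metric): mean/sd per
#'   plan, increment percentages pct_1_2, pct_1_3, pct_2_3, F, p and the
#'   pairwise p values p_1_2, p_1_3, p_2_3.
#' @export
summarizeCohort <- function(table, incrementsOnMeans = TRUE) {
  need <- c("subject", "plan", "structure", "metric", "value")
  if (!all(need %in% names(table)))
    stop("metric table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(table[c("subject", "plan", "structure", "metric")]))
    stop("duplicate (subject, plan, structure, metric) rows")
  plans <- sort(unique(table$plan))
  cells <- unique(table[c("structure", "metric")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    st <- cells$structure[i]; me <- cells$metric[i]
    sub <- table[table$structure == st & table$metric == me, ]
    out <- data.frame(structure = st, metric = me)
    for (p in plans) {
      v <- sub$value[sub$plan == p]
      out[[paste0("mean_", p)]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0("sd_", p)]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    prs <- if (length(plans) >= 2) utils::combn(seq_along(plans), 2) else NULL
    if (!is.null(prs)) for (cidx in seq_len(ncol(prs))) {
      a <- prs[1, cidx]; b <- prs[2, cidx]
      va <- sub$value[sub$plan == plans[a]]
      vb <- sub$value[sub$plan == plans[b]]
      nm <- paste0("pct_", a, "_", b)
      out[[nm]] <- if (!length(va) || !length(vb) || mean(va) == 0) NA_real_
        else if (incrementsOnMeans) incrementPercent(mean(va), mean(vb))
        else {
          common <- intersect(sub$subject[sub$plan == plans[a]],
                              sub$subject[sub$plan == plans[b]])
          mean(incrementPercent(
            sub$value[sub$plan == plans[a]][match(common, sub$subject[sub$plan == plans[a]])],
            sub$value[sub$plan == plans[b]][match(common, sub$subject[sub$plan == plans[b]])]))
        }
    }
    enough <- all(vapply(plans, function(p)
      sum(sub$plan == p) >= 2, logical(1))) && length(plans) >= 2
    if (enough && stats::var(sub$value) > 0) {
      a <- anovaLSD(sub$value, sub$plan)
      out$F <- a$F; out$p <- a$p
      if (!is.null(prs)) for (cidx in seq_len(ncol(prs))) {
        g1 <- plans[prs[1, cidx]]; g2 <- plans[prs[2, cidx]]
        hit <- a$pairwise$group1 == g1 & a$pairwise$group2 == g2
        out[[paste0("p_", prs[1, cidx], "_", prs[2, cidx])]] <-
          if (any(hit)) a$pairwise$p[hit] else NA_real_
      }
    } else {
      out$F <- if (enough) 0 else NA_real_
      out$p <- if (enough) 1 else NA_real_
    }
    out
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    allcols <- unique(unlist(lapply(rows, names)))
    r[setdiff(allcols, names(r))] <- NA
    r[allcols]
  }))
  rownames(out) <- NULL
  out
}
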
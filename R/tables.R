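# Clinicopathological association tables and exact 2x2 inference for
# pathological complete response. The odds ratio is the conditional maximum
# likelihood estimate under the noncentral hypergeometric distribution (the
# exact-test convention), with exact confidence limits by inverting
# one-sided tests; this convention — not the sample cross-product ratio — is
# what reproduces the printed per-subtype odds ratios.

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be non-negative integers")
  storage.mode(tab) <- "double"
  tab
}

# noncentral hypergeometric log-weights over the support of the a-cell
nchg_support <- function(tab) {
  n1 <- tab[1, 1] + tab[1, 2]   # row-1 total
  n2 <- tab[2, 1] + tab[2, 2]
  m1 <- tab[1, 1] + tab[2, 1]   # column-1 total
  x <- max(0, m1 - n2):min(n1, m1)
  list(x = x, n1 = n1, n2 = n2, m1 = m1,
       lchoose = lchoose(n1, x) + lchoose(n2, m1 - x))
}

nchg_mean <- function(sup, log_psi) {
  lw <- sup$lchoose + sup$x * log_psi
  w <- exp(lw - max(lw))
  sum(sup$x * w) / sum(w)
}

nchg_cdf_tail <- function(sup, log_psi, a, upper = FALSE) {
  lw <- sup$lchoose + sup$x * log_psi
  w <- exp(lw - max(lw))
  sel <- if (upper) sup$x >= a else sup$x <= a
  sum(w[sel]) / sum(w)
}

solve_log_psi <- function(f, target) {
  # f must be monotone increasing in log psi; find f(z) = target
  g <- function(z) f(z) - target
  lo <- -1; hi <- 1
  while (g(lo) > 0 && lo > -745) lo <- lo * 2
  while (g(hi) < 0 && hi < 745) hi <- hi * 2
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by probability-mass ordering: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability (relative slack 1e-7, the
#' standard convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = group,
#'   columns = outcome).
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- check_2x2(tab)
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
      sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0)
    return(1)
  sup <- nchg_support(tab)
  p_all <- stats::dhyper(sup$x, sup$n1, sup$n2, sup$m1)
  p_obs <- stats::dhyper(tab[1, 1], sup$n1, sup$n2, sup$m1)
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
}

#' Conditional maximum-likelihood odds ratio with exact confidence interval
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of the
#' table conditional on both margins, found by solving
#' `E[X | psi] = a` (the observed top-left cell) — the conditional mean is
#' strictly increasing in `psi`. The 95% confidence interval inverts
#' one-sided exact tests at 2.5% on each side; when the observed cell sits
#' at the boundary of its support the corresponding limit is 0 or infinite.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `lower`, `upper`.
#' @export
conditional_mle_or <- function(tab) conditional_mle_or_ci(tab)$or

#' @rdname conditional_mle_or
#' @export
conditional_mle_or_ci <- function(tab, conf_level = 0.95) {
  tab <- check_2x2(tab)
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
      sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0)
    stop("conditional_mle_or: degenerate margin")
  sup <- nchg_support(tab)
  a <- tab[1, 1]
  alpha <- (1 - conf_level) / 2
  or <- if (a == min(sup$x)) 0
        else if (a == max(sup$x)) Inf
        else exp(solve_log_psi(function(z) nchg_mean(sup, z), a))
  # lower limit: P(X >= a | psi) is increasing in psi
  lower <- if (a == min(sup$x)) 0
           else exp(solve_log_psi(function(z)
             nchg_cdf_tail(sup, z, a, upper = TRUE), alpha))
  # upper limit: P(X <= a | psi) is decreasing in psi
  upper <- if (a == max(sup$x)) Inf
           else exp(solve_log_psi(function(z)
             -nchg_cdf_tail(sup, z, a, upper = FALSE), -alpha))
  list(or = or, lower = lower, upper = upper)
}

#' Exact 2x2 contingency analysis
#'
#' Bundles the two-sided Fisher p-value, the conditional-MLE odds ratio and
#' its exact 95% confidence interval, and per-group outcome rates. Tables
#' with an empty margin are flagged not estimable.
#'
#' @param tab 2x2 matrix, rows = group (e.g. no_up / up), columns = outcome
#'   (e.g. residual disease / pCR).
#' @param label optional label carried in the result.
#' @return object of class `contingency_result`.
#' @export
contingency_result <- function(tab, label = NULL) {
  tab <- check_2x2(tab)
  estimable <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  if (estimable) {
    p <- fisher_exact(tab)
    ci <- conditional_mle_or_ci(tab)
  } else {
    p <- NA_real_
    ci <- list(or = NA_real_, lower = NA_real_, upper = NA_real_)
  }
  rates <- tab[, 2] / pmax(1, rowSums(tab))
  structure(list(counts = tab, p = p, or = ci$or, lower = ci$lower,
                 upper = ci$upper, rates = rates, estimable = estimable,
                 label = label),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  if (!is.null(x$label)) cat(x$label, "\n")
  print(x$counts)
  if (x$estimable) {
    cat(sprintf("Fisher exact p = %.3g, OR = %.2f [%.2f-%.2f]\n",
                x$p, x$or, x$lower, x$upper))
  } else {
    cat("not estimable (empty margin)\n")
  }
  invisible(x)
}

#' Clinicopathological association table
#'
#' For each variable, tabulates counts and column percentages by a binary
#' group and tests the association: Fisher's exact test for 2x2 tables, the
#' chi-square test for larger categorical tables, the pooled two-sample
#' t-test for continuous variables (one-way ANOVA if the group had more than
#' two levels). Variables with a single observed level are skipped with a
#' warning.
#'
#' @param clinical data frame of per-sample covariates.
#' @param group_column name of the binary grouping column.
#' @param variables character vector of columns to test.
#' @return object of class `association_table`: a data frame with one row
#'   per variable level (columns: variable, level, per-group `n (pct)`), and
#'   attribute `"p"` — named vector of p-values.
#' @export
association_table <- function(clinical, group_column, variables) {
  g <- clinical[[group_column]]
  glev <- sort(unique(stats::na.omit(as.character(g))))
  if (length(glev) != 2L)
    stop("association_table: group column must be binary")
  rows <- list(); pvals <- c()
  for (v in variables) {
    x <- clinical[[v]]
    keep <- !is.na(x) & !is.na(g)
    xv <- x[keep]; gv <- as.character(g[keep])
    if (is.numeric(xv) && length(unique(xv)) > 8L) {
      if (length(unique(xv)) < 2L) {
        warning("association_table: '", v, "' has a single level; skipped")
        next
      }
      p <- stats::t.test(xv ~ factor(gv), var.equal = TRUE)$p.value
      rows[[v]] <- data.frame(
        variable = v, level = "mean (sd)",
        g1 = sprintf("%.1f (%.1f)", mean(xv[gv == glev[1]]),
                     stats::sd(xv[gv == glev[1]])),
        g2 = sprintf("%.1f (%.1f)", mean(xv[gv == glev[2]]),
                     stats::sd(xv[gv == glev[2]])),
        stringsAsFactors = FALSE)
      pvals[v] <- p
    } else {
      xv <- as.character(xv)
      lev <- sort(unique(xv))
      if (length(lev) < 2L) {
        warning("association_table: '", v, "' has a single level; skipped")
        next
      }
      tab <- table(factor(xv, levels = lev), factor(gv, levels = glev))
      p <- if (all(dim(tab) == c(2L, 2L))) fisher_exact(unclass(tab))
           else suppressWarnings(stats::chisq.test(tab)$p.value)
      pct <- prop.table(tab, 2) * 100
      rows[[v]] <- data.frame(
        variable = v, level = lev,
        g1 = sprintf("%d (%.0f%%)", tab[, 1], pct[, 1]),
        g2 = sprintf("%d (%.0f%%)", tab[, 2], pct[, 2]),
        stringsAsFactors = FALSE)
      pvals[v] <- p
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(variable = character(), level = character(),
                      g1 = character(), g2 = character())
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  names(out)[3:4] <- glev
  structure(out, class = c("association_table", "data.frame"), p = pvals)
}

#' @export
print.association_table <- function(x, ...) {
  df <- as.data.frame(x)
  p <- attr(x, "p")
  df$p <- ifelse(duplicated(df$variable), "",
                 signif(p[df$variable], 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predictive analysis of pathological complete response
#'
#' Tests the association between a binary expression group and pCR in the
#' whole informative population and within each molecular subtype. Samples
#' with missing pCR are excluded (their count is reported). Subtype strata
#' with an empty 2x2 margin are flagged not estimable.
#'
#' @param clinical data frame with the group column, a `pcr` column (0/1,
#'   NA = not informative) and a subtype column.
#' @param group_column binary group column name (default `"pdl1"`); the
#'   level sorted first (e.g. `"no_up"`) forms the first table row.
#' @param subtype_column subtype column name (default `"subtype"`).
#' @return list with `overall` (a `contingency_result`), `by_subtype`
#'   (named list of `contingency_result`), and `n_excluded`.
#' @export
pcr_analysis <- function(clinical, group_column = "pdl1",
                         subtype_column = "subtype") {
  if (!"pcr" %in% names(clinical))
    stop("pcr_analysis: clinical table lacks a 'pcr' column")
  g <- as.character(clinical[[group_column]])
  keep <- !is.na(clinical$pcr) & !is.na(g)
  n_excluded <- sum(!keep & !is.na(g))
  cl <- clinical[keep, , drop = FALSE]
  g <- g[keep]
  glev <- sort(unique(g))
  if (length(glev) != 2L)
    stop("pcr_analysis: group column must have two levels among informative samples")
  make_tab <- function(idx, label) {
    tab <- matrix(0, 2, 2,
                  dimnames = list(glev, c("RD", "pCR")))
    t0 <- table(factor(g[idx], levels = glev),
                factor(cl$pcr[idx], levels = c(0, 1)))
    tab[, ] <- t0
    contingency_result(tab, label = label)
  }
  overall <- make_tab(seq_len(nrow(cl)), "whole cohort")
  st <- as.character(cl[[subtype_column]])
  by_subtype <- lapply(stats::setNames(nm = SUBTYPES), function(s)
    make_tab(which(!is.na(st) & st == s), s))
  list(overall = overall, by_subtype = by_subtype,
       n_excluded = n_excluded)
}
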
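# Nonparametric comparison suite: Friedman with mean ranks, Wilcoxon
# signed-rank (normal approximation, tie-corrected, no continuity
# correction) with Sidak-adjusted p values and the r = |Z|/sqrt(2N) effect
# size, Cochran's Q with pairwise continuity-corrected McNemar tests over
# fit-failure indicators, and Spearman correlation helpers.

#' Friedman rank test with mean ranks
#'
#' Ranks each unit's values across conditions (mid-ranks for ties) and
#' computes the tie-corrected Friedman chi-square with `k - 1` degrees of
#' freedom. Rows containing missing values are dropped listwise.
#'
#' @param m Numeric matrix, units x conditions (>= 2 columns).
#' @return List with `chisq`, `df`, `p`, `mean_ranks` (higher rank = larger
#'   value) and `n` (complete rows used).
#' @export
friedman_ranks <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) {
    stop_effdisc("Friedman test needs at least 2 complete rows",
                 "effdisc_input_error")
  }
  k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  mean_ranks <- colMeans(r)
  names(mean_ranks) <- colnames(m)
  tie_term <- sum(unlist(lapply(seq_len(n), function(i) {
    t <- table(r[i, ])
    t^3 - t
  })))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  chisq <- if (denom <= 0) 0 else
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       mean_ranks = mean_ranks, n = n)
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Classical signed-rank convention: zero differences are dropped, tied
#' absolute differences receive mid-ranks, and the Z statistic uses the
#' tie-corrected normal approximation without continuity correction. The
#' effect size is \eqn{r = |Z|/\sqrt{2N}}, where `N` is the number of pairs
#' including zero differences (both samples observed). Counts of `x > y`,
#' ties and `x < y` are reported alongside.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `z`, `p`, `r`, `n_pairs`, `n_nonzero` and `counts`
#'   (better/tied/worse with percentages).
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n_pairs <- length(x)
  d <- x - y
  counts <- c(better = sum(d > 0), tied = sum(d == 0), worse = sum(d < 0))
  pct <- 100 * counts / n_pairs
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(z = 0, p = 1, r = 0, n_pairs = n_pairs, n_nonzero = 0L,
                counts = counts, percentages = pct))
  }
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 <= 0) 0 else (w_pos - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = min(p, 1), r = abs(z) / sqrt(2 * n_pairs),
       n_pairs = n_pairs, n_nonzero = n, counts = counts, percentages = pct)
}

#' Sidak correction for multiple comparisons
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m}, capped at 1.
#'
#' @param p_raw Raw p value(s) in \[0, 1\].
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p value(s).
#' @examples
#' sidak(0.05, 3)  # 0.142625
#' @export
sidak <- function(p_raw, m) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1), m >= 1)
  pmin(1 - (1 - p_raw)^m, 1)
}

#' Cochran's Q test for related binary outcomes
#'
#' Compares the proportion of 1s (here: fit failures, R-squared = 0) across
#' k related samples. \eqn{Q = k(k-1)\sum_j (C_j - \bar C)^2 /
#' (k \sum_i R_i - \sum_i R_i^2)} with `C` column totals and `R` row totals,
#' df = k - 1.
#'
#' @param m Binary (0/1) matrix, units x conditions.
#' @return List with `q`, `df`, `p` and column totals `failures`.
#' @export
cochran_q <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L, all(m %in% c(0, 1)))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  cj <- colSums(m)
  ri <- rowSums(m)
  denom <- k * sum(ri) - sum(ri^2)
  q <- if (denom == 0) 0 else k * (k - 1) * sum((cj - mean(cj))^2) / denom
  df <- k - 1
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       failures = cj)
}

#' Continuity-corrected McNemar test from discordant counts
#'
#' \eqn{\chi^2 = (|b - c| - 1)^2/(b + c)} on 1 df, where `b` and `c` are the
#' two discordant cell counts of the paired 2x2 table.
#'
#' @param b,c Non-negative discordant counts.
#' @return List with `chisq`, `df`, `p` and `defined` (FALSE when
#'   `b + c = 0`, in which case the statistic is `NA`).
#' @examples
#' mcnemar_cc(0, 25)$chisq  # 23.04
#' @export
mcnemar_cc <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    return(list(chisq = NA_real_, df = 1L, p = NA_real_, defined = FALSE))
  }
  chisq <- (abs(b - c) - 1)^2 / (b + c)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE), defined = TRUE)
}

#' Spearman rank correlation
#'
#' Mid-ranked Spearman rho with the asymptotic p value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- !is.na(x) & !is.na(y)
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

# units x models matrix of one fit-level column, from a long fits table.
fits_matrix <- function(tab, col, models) {
  units <- unique(tab$unit)
  m <- matrix(NA_real_, length(units), length(models),
              dimnames = list(units, models))
  for (i in seq_len(nrow(tab))) {
    if (tab$model[i] %in% models) m[tab$unit[i], tab$model[i]] <- tab[[col]][i]
  }
  m
}

# units x magnitudes matrix of one parameter for one model.
param_matrix <- function(df, model, par, amounts) {
  sub <- df[df$model == model, ]
  units <- unique(sub$unit)
  m <- matrix(NA_real_, length(units), length(amounts),
              dimnames = list(units, paste0(par, "_", amounts)))
  for (i in seq_len(nrow(sub))) {
    j <- match(sub$magnitude[i], amounts)
    if (!is.na(j)) m[sub$unit[i], j] <- sub[[par]][i]
  }
  m
}

# All pairwise Wilcoxon comparisons over the columns of a matrix, with
# Sidak-adjusted p values.
pairwise_wilcoxon <- function(m) {
  k <- ncol(m)
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  out <- lapply(seq_len(n_comp), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ok <- stats::complete.cases(m[, c(a, b)])
    w <- wilcoxon_paired(m[ok, a], m[ok, b])
    w$comparison <- paste(colnames(m)[a], "vs", colnames(m)[b])
    w$p_adjusted <- sidak(w$p, n_comp)
    w
  })
  names(out) <- vapply(out, `[[`, "", "comparison")
  out
}

# Pairwise McNemar over binary failure indicators, Sidak-adjusted.
pairwise_mcnemar <- function(m) {
  k <- ncol(m)
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  out <- lapply(seq_len(n_comp), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ok <- stats::complete.cases(m[, c(a, b)])
    bb <- sum(m[ok, a] == 1 & m[ok, b] == 0)
    cc <- sum(m[ok, a] == 0 & m[ok, b] == 1)
    r <- mcnemar_cc(bb, cc)
    r$comparison <- paste(colnames(m)[a], "vs", colnames(m)[b])
    r$b <- bb; r$c <- cc
    r$p_adjusted <- if (is.na(r$p)) NA_real_ else sidak(r$p, n_comp)
    r
  })
  names(out) <- vapply(out, `[[`, "", "comparison")
  out
}

#' Run the full nonparametric comparison suite
#'
#' Reproduces the structure of the model-comparison analyses on a batch of
#' individual-level fits: per effort domain, (1) Friedman tests plus pairwise
#' Wilcoxon comparisons (Sidak-corrected, with better/tied/worse
#' percentages) of R-squared across models, within the one-parameter and
#' two-parameter model families; (2) Friedman and pairwise Wilcoxon
#' comparisons of the `l` (and `s`) estimates of a reference model across
#' reward magnitudes, with mean ranks; (3) Cochran's Q and pairwise McNemar
#' tests over the R-squared = 0 failure indicators; (4) Spearman correlation
#' matrices of `l` (and `s`) across magnitudes and between domains.
#'
#' @param fits A `disc_fitset` of individual-level fits.
#' @param spec The [edq_design()] used.
#' @param reference_model Model whose parameters are compared across
#'   magnitudes and domains (default `"power"`).
#' @return A nested list (class `disc_stats`) keyed by domain and analysis.
#' @export
run_stats_suite <- function(fits, spec = edq_design(),
                            reference_model = "power") {
  stopifnot(inherits(fits, "disc_fitset"))
  df <- as.data.frame(fits)
  df <- df[df$unit != "MEDIAN", ]
  reg <- disc_models()
  fitted_models <- intersect(reg$model, unique(df$model))
  one_par <- intersect(reg$model[reg$n_par == 1L], fitted_models)
  two_par <- intersect(reg$model[reg$n_par == 2L], fitted_models)
  amounts <- spec$amounts
  fit_level <- df[!duplicated(paste(df$unit, df$domain, df$model)), ]

  out <- list()
  for (dom in unique(df$domain)) {
    dd <- fit_level[fit_level$domain == dom, ]
    ddp <- df[df$domain == dom, ]
    res <- list()
    for (grp_name in c("one_parameter", "two_parameter")) {
      grp <- if (grp_name == "one_parameter") one_par else two_par
      if (length(grp) < 2L) next
      r2m <- fits_matrix(dd, "r2", grp)
      res[[paste0("r2_", grp_name)]] <- list(
        friedman = friedman_ranks(r2m),
        pairwise = pairwise_wilcoxon(r2m))
      failm <- fits_matrix(dd, "clamped", grp)
      res[[paste0("nonfit_", grp_name)]] <- list(
        cochran = cochran_q(failm[stats::complete.cases(failm), , drop = FALSE]),
        pairwise = pairwise_mcnemar(failm))
    }
    if (reference_model %in% fitted_models) {
      lm_ <- param_matrix(ddp, reference_model, "l", amounts)
      res$l_magnitude <- list(friedman = friedman_ranks(lm_),
                              pairwise = pairwise_wilcoxon(lm_))
      if (reference_model %in% two_par) {
        sm_ <- param_matrix(ddp, reference_model, "s", amounts)
        res$s_magnitude <- list(friedman = friedman_ranks(sm_),
                                pairwise = pairwise_wilcoxon(sm_))
      }
      res$l_correlations <- cor_matrix_list(lm_)
      if (reference_model %in% two_par) {
        res$s_correlations <- cor_matrix_list(
          param_matrix(ddp, reference_model, "s", amounts))
      }
    }
    out[[dom]] <- res
  }
  # Cross-domain parameter correlations for the reference model.
  domains <- unique(df$domain)
  if (length(domains) == 2L && reference_model %in% fitted_models) {
    cross <- list()
    for (par in c("l", if (reference_model %in% two_par) "s")) {
      m1 <- param_matrix(df[df$domain == domains[1L], ], reference_model, par,
                         amounts)
      m2 <- param_matrix(df[df$domain == domains[2L], ], reference_model, par,
                         amounts)
      shared <- intersect(rownames(m1), rownames(m2))
      cross[[par]] <- lapply(seq_along(amounts), function(j) {
        sr <- spearman_rho(m1[shared, j], m2[shared, j])
        sr$amount <- amounts[j]
        sr
      })
      names(cross[[par]]) <- paste0(par, "_", amounts)
    }
    out$cross_domain <- cross
  }
  structure(out, class = "disc_stats")
}

# Pairwise Spearman correlations between the columns of a matrix.
cor_matrix_list <- function(m) {
  k <- ncol(m)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sr <- spearman_rho(m[, a], m[, b])
    sr$comparison <- paste(colnames(m)[a], "vs", colnames(m)[b])
    sr
  })
  names(out) <- vapply(out, `[[`, "", "comparison")
  out
}

#' @export
print.disc_stats <- function(x, ...) {
  for (dom in setdiff(names(x), "cross_domain")) {
    cat(sprintf("== %s effort ==\n", dom))
    for (an in names(x[[dom]])) {
      el <- x[[dom]][[an]]
      if (!is.null(el$friedman)) {
        cat(sprintf("  %s: Friedman chi^2 = %.3f (df = %d, p = %.3g)\n",
                    an, el$friedman$chisq, el$friedman$df, el$friedman$p))
      } else if (!is.null(el$cochran)) {
        cat(sprintf("  %s: Cochran Q = %.3f (df = %d, p = %.3g)\n",
                    an, el$cochran$q, el$cochran$df, el$cochran$p))
      }
    }
  }
  if (!is.null(x$cross_domain)) {
    cat("== cross-domain Spearman correlations ==\n")
    for (par in names(x$cross_domain)) {
      for (nm in names(x$cross_domain[[par]])) {
        el <- x$cross_domain[[par]][[nm]]
        cat(sprintf("  %s: rho = %.3f (p = %.3g, n = %d)\n",
                    nm, el$rho, el$p, el$n))
      }
    }
  }
  invisible(x)
}
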
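# SSE-based information criteria, deltas, group aggregation and best-model
# frequency tables for comparing the seven discounting models.

#' SSE-based Akaike Information Criterion
#'
#' \eqn{AIC = n \ln(SSe/n) + 2p}, the least-squares form appropriate when
#' model fit is summarised by a residual sum of squares. A perfect fit
#' (`sse = 0`) returns `-Inf` with a warning, preserving the ordering.
#'
#' @param n Number of data points (indifference points in the joint fit).
#' @param p Number of free regression parameters (3 for one-parameter models
#'   across three magnitudes, 6 for two-parameter models).
#' @param sse Residual sum of squares.
#' @return The criterion value (unitless).
#' @examples
#' aic_sse(15, 3, 15)  # 6
#' @export
aic_sse <- function(n, p, sse) {
  stopifnot(n > 0, p >= 0, sse >= 0)
  if (sse == 0) {
    warning("sse = 0 (perfect fit): criterion reported as -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * p
}

#' Second-order (small-sample corrected) AIC
#'
#' \eqn{AICc = AIC + 2p(p+1)/(n-p-1)}; defined only for `n > p + 1`.
#'
#' @inheritParams aic_sse
#' @return The criterion value.
#' @examples
#' aicc_sse(15, 3, 15)  # 6 + 24/11
#' @export
aicc_sse <- function(n, p, sse) {
  if (n - p - 1 <= 0) {
    stop_effdisc("AICc undefined: n must exceed p + 1",
                 "effdisc_undefined_criterion")
  }
  aic_sse(n, p, sse) + 2 * p * (p + 1) / (n - p - 1)
}

#' SSE-based Bayesian Information Criterion
#'
#' \eqn{BIC = n \ln(SSe/n) + p \ln(n)}.
#'
#' @inheritParams aic_sse
#' @return The criterion value.
#' @examples
#' bic_sse(15, 3, 15)  # 3 * log(15)
#' @export
bic_sse <- function(n, p, sse) {
  stopifnot(n > 0, p >= 0, sse >= 0)
  if (sse == 0) {
    warning("sse = 0 (perfect fit): criterion reported as -Inf")
    return(-Inf)
  }
  n * log(sse / n) + log(n) * p
}

#' Delta criterion values
#'
#' Differences from the best (lowest) model; the best model gets delta 0.
#' `-Inf` sentinels (perfect fits) are supported: the sentinel model gets 0
#' and every finite model `Inf`.
#'
#' @param values Named numeric vector of criterion values, one per model.
#' @return Named vector of deltas (>= 0, minimum exactly 0).
#' @export
ic_deltas <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L, !anyNA(values))
  if (any(values == -Inf)) {
    out <- ifelse(values == -Inf, 0, Inf)
    names(out) <- names(values)
    return(out)
  }
  values - min(values)
}

#' Sum criterion values across subjects, then take deltas
#'
#' Fixed-effects group aggregation: per-model column sums of per-subject
#' criterion values, converted to deltas. Subjects lacking a finite value for
#' any model (clamped, non-converged or perfect fits) are dropped listwise
#' and reported via the `dropped` attribute.
#'
#' @param ic_matrix Numeric matrix, subjects x models (named columns).
#' @return Named list with `sums`, `deltas` and `n_subjects` (after listwise
#'   deletion); attribute `dropped` holds the excluded row indices.
#' @export
aggregate_ic <- function(ic_matrix) {
  stopifnot(is.matrix(ic_matrix), ncol(ic_matrix) >= 2L)
  keep <- apply(is.finite(ic_matrix), 1L, all)
  dropped <- which(!keep)
  m <- ic_matrix[keep, , drop = FALSE]
  if (!nrow(m)) {
    stop_effdisc("no subject has finite criterion values for every model",
                 "effdisc_input_error")
  }
  sums <- colSums(m)
  out <- list(sums = sums, deltas = ic_deltas(sums), n_subjects = nrow(m))
  attr(out, "dropped") <- dropped
  out
}

#' Best-model frequencies across subjects
#'
#' Counts, per model, the subjects for which it attains the minimum criterion
#' value. Ties credit every tied model (so counts can sum to more than the
#' number of subjects); tie occurrences are reported.
#'
#' @param ic_matrix Numeric matrix, subjects x models (named columns);
#'   subjects with any non-finite value are dropped listwise.
#' @return List with `counts`, `ratios` (count / subjects retained),
#'   `n_subjects` and `n_ties`.
#' @export
best_model_frequencies <- function(ic_matrix) {
  stopifnot(is.matrix(ic_matrix), ncol(ic_matrix) >= 2L)
  keep <- apply(is.finite(ic_matrix), 1L, all)
  m <- ic_matrix[keep, , drop = FALSE]
  if (!nrow(m)) {
    stop_effdisc("no subject has finite criterion values for every model",
                 "effdisc_input_error")
  }
  is_best <- t(apply(m, 1L, function(row) row == min(row)))
  counts <- colSums(is_best)
  names(counts) <- colnames(m)
  list(counts = counts, ratios = counts / nrow(m), n_subjects = nrow(m),
       n_ties = sum(rowSums(is_best) > 1L))
}

#' Model-selection table for a batch of fits
#'
#' Computes AIC, AICc and BIC for every fit in a `disc_fitset`, plus, per
#' domain, summed-criterion deltas and best-model frequencies across
#' individual subjects.
#'
#' @param fits A `disc_fitset` from [disc_fit_all()].
#' @return An object of class `disc_selection`: list with `table` (long
#'   data.frame `unit,domain,model,sse,n,p,r2,clamped,aic,aicc,bic`),
#'   `summed` (per domain: deltas of summed AICc and BIC) and `frequencies`
#'   (per domain and criterion: best-model counts and ratios). Units whose
#'   fit is clamped or non-converged for a model carry `NA` criteria and are
#'   excluded listwise from the group summaries.
#' @export
model_selection <- function(fits) {
  stopifnot(inherits(fits, "disc_fitset"))
  rows <- lapply(unclass(fits), function(f) {
    usable <- !f$clamped && f$converged && f$sse > 0
    data.frame(unit = f$unit, domain = f$domain, model = f$model,
               sse = f$sse, n = f$n, p = f$p, r2 = f$r2,
               clamped = f$clamped, converged = f$converged,
               aic = if (usable) aic_sse(f$n, f$p, f$sse) else NA_real_,
               aicc = if (usable) aicc_sse(f$n, f$p, f$sse) else NA_real_,
               bic = if (usable) bic_sse(f$n, f$p, f$sse) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  models <- unique(tab$model)
  summed <- list()
  freqs <- list()
  for (dom in unique(tab$domain)) {
    dt <- tab[tab$domain == dom & tab$unit != "MEDIAN", ]
    if (!nrow(dt)) next
    mk_matrix <- function(col) {
      units <- unique(dt$unit)
      m <- matrix(NA_real_, nrow = length(units), ncol = length(models),
                  dimnames = list(units, models))
      for (i in seq_len(nrow(dt))) m[dt$unit[i], dt$model[i]] <- dt[[col]][i]
      m
    }
    m_aicc <- mk_matrix("aicc")
    m_bic <- mk_matrix("bic")
    summed[[dom]] <- list(aicc = aggregate_ic(m_aicc),
                          bic = aggregate_ic(m_bic))
    freqs[[dom]] <- list(aicc = best_model_frequencies(m_aicc),
                         bic = best_model_frequencies(m_bic))
  }
  structure(list(table = tab, summed = summed, frequencies = freqs,
                 models = models),
            class = "disc_selection")
}

#' @export
print.disc_selection <- function(x, ...) {
  cat("Discounting model selection\n")
  for (dom in names(x$summed)) {
    cat(sprintf("\n%s effort: summed-criterion deltas (n = %d subjects)\n",
                dom, x$summed[[dom]]$aicc$n_subjects))
    m <- rbind(dAICc = x$summed[[dom]]$aicc$deltas,
               dBIC = x$summed[[dom]]$bic$deltas)
    print(round(m, 2))
    cat(sprintf("%s effort: best-model counts (BIC)\n", dom))
    print(x$frequencies[[dom]]$bic$counts)
  }
  invisible(x)
}
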
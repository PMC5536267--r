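# Nonlinear least-squares estimation of discounting models, jointly across
# reward magnitudes, for one analysis unit (a participant or the group
# median) within one effort domain.
#
# The joint ("dummy-variable") fit estimates magnitude-specific parameters
# (l, and s for two-parameter models) while minimising a single pooled sum
# of squared errors over every indifference point, so one goodness-of-fit
# value covers all magnitudes. The objective is block-separable because each
# parameter touches only its own magnitude's points; the implementation
# exploits that structure directly, and an independent per-magnitude fitting
# route (fit_magnitude) serves as a decomposition cross-check in the tests.
#
# Two of the models are conditionally linear and are estimated by variable
# projection: the power function is linear in l given s, and the
# two-parameter exponential is linear in its asymptote s given l, so the
# linear parameter is profiled out in closed form and only the nonlinear
# parameter is iterated. This removes the flattest direction of their l-s
# ridges from the search.

# Number of ranked grid starts polished by local optimisation (both in the
# joint fit and the per-magnitude decomposition route). One-parameter and
# profiled models have at most 7 grid points; the two hyperboloids get the
# full 35-point grid, which their multimodal SSE surfaces need.
N_POLISH <- 35L

# nlminb termination states that represent a stationary point. Iteration or
# evaluation limits are genuine non-convergence; "singular" and "false"
# convergence arise routinely on the flat l-s ridges of two-parameter
# discounting fits and are accepted as converged stationary points.
nlminb_converged <- function(res) {
  if (res$convergence == 0L) return(TRUE)
  msg <- res$message %||% ""
  grepl("convergence", msg) && !grepl("limit reached", msg)
}

# Reduced estimation problem for one model on one magnitude's points:
# the iterated parameter vector (dim 1 or 2), its start grid and bounds, the
# profiled SSE, and the mapping back to the full (l, s) pair.
reduced_block <- function(model, def, A, E, ip) {
  fn <- def$fn
  l_grid <- matrix(10^seq(-6, 0), ncol = 1L)
  if (model == "power") {
    # SV = A - l E^s is linear in l given s; profile l (non-negative).
    prof_l <- function(s) {
      Es <- E^s
      max(sum(Es * (A - ip)) / sum(Es * Es), 0)
    }
    list(dim = 1L, grid = matrix(c(0.25, 0.5, 1, 2, 4), ncol = 1L),
         lower = 1e-8, upper = 10,
         sse = function(th) {
           l <- prof_l(th[1L])
           sum((ip - (A - l * E^th[1L]))^2)
         },
         full = function(th) c(prof_l(th[1L]), th[1L]))
  } else if (model == "exp2") {
    # SV = (A - s) e^{-lE} + s is linear in s given l; profile s (< A).
    # l is kept strictly positive: as l -> 0 the family closes on linear
    # curves via s -> -Inf, and the profile is discontinuous at exactly 0.
    prof_s <- function(l) {
      w <- 1 - exp(-l * E)
      if (all(w == 0)) return(0)
      min(sum(w * (ip - A * exp(-l * E))) / sum(w * w), A)
    }
    list(dim = 1L, grid = l_grid, lower = 1e-12, upper = Inf,
         sse = function(th) {
           s <- prof_s(th[1L])
           sum((ip - ((A - s) * exp(-th[1L] * E) + s))^2)
         },
         full = function(th) c(th[1L], prof_s(th[1L])))
  } else if (def$n_par == 1L) {
    list(dim = 1L, grid = l_grid, lower = 0, upper = Inf,
         sse = function(th) sum((ip - fn(A, E, th[1L]))^2),
         full = function(th) c(th[1L], NA_real_))
  } else {
    # Myerson-Green and Rachlin hyperboloids: genuinely nonlinear in (l, s).
    list(dim = 2L,
         grid = as.matrix(expand.grid(l = 10^seq(-6, 0),
                                      s = c(0.25, 0.5, 1, 2, 4),
                                      KEEP.OUT.ATTRS = FALSE)),
         lower = c(0, 1e-8), upper = c(Inf, 10),
         sse = function(th) sum((ip - fn(A, E, th[1L], th[2L]))^2),
         full = function(th) th)
  }
}

# Start vectors ranked by their raw (pre-polish) SSE.
ranked_starts <- function(rb) {
  sse0 <- apply(rb$grid, 1L, rb$sse)
  rb$grid[order(sse0), , drop = FALSE]
}

run_nlminb <- function(obj, start, lower, upper) {
  res <- tryCatch(
    stats::nlminb(start, obj, lower = lower, upper = upper,
                  scale = 1 / pmax(abs(start), 1e-6),
                  control = list(iter.max = 500, eval.max = 2000,
                                 abs.tol = 1e-20, rel.tol = 1e-12)),
    error = function(e) NULL)
  if (is.null(res)) {
    res <- list(par = start, objective = obj(start), convergence = 1L,
                message = "error")
  }
  res$ok <- nlminb_converged(res)
  res
}

# Repeatedly restart nlminb from the incumbent until the objective stops
# improving; PORT sometimes halts early on flat valleys and a cold restart
# makes further progress.
polish_until_stable <- function(obj, res, lower, upper, max_restarts = 4L) {
  for (i in seq_len(max_restarts)) {
    nxt <- run_nlminb(obj, res$par, lower, upper)
    if (nxt$objective < res$objective * (1 - 1e-12) - 1e-300) {
      res <- nxt
    } else {
      if (nxt$objective <= res$objective) res <- nxt
      break
    }
  }
  res
}

#' Independent per-magnitude least-squares fit
#'
#' Fits one discounting model to the indifference points of a single reward
#' magnitude by bounded multi-start nonlinear least squares. This is the
#' decomposition route: because the joint fit's objective separates by
#' magnitude, its pooled SSE must equal the sum of these independent fits'
#' SSEs, which the test suite verifies for every model.
#'
#' @param model Model name (see [disc_models()]).
#' @param A Reward amount (PLN).
#' @param E Numeric vector of effort intensities.
#' @param ip Numeric vector of indifference points, same length as `E`.
#' @return A list with `par` (named `l`, and `s` for two-parameter models),
#'   `sse` and `converged`.
#' @export
fit_magnitude <- function(model, A, E, ip) {
  def <- match_model(model)
  stopifnot(length(E) == length(ip), length(E) >= 1L)
  rb <- reduced_block(model, def, A, E, ip)
  starts <- ranked_starts(rb)
  best <- NULL
  best_conv <- FALSE
  for (k in seq_len(min(nrow(starts), N_POLISH))) {
    res <- run_nlminb(rb$sse, starts[k, ], rb$lower, rb$upper)
    if (is.null(best) || res$objective < best$objective) {
      best <- res
      best_conv <- res$ok
    }
  }
  best <- polish_until_stable(rb$sse, best, rb$lower, rb$upper)
  best_conv <- best_conv || best$ok
  full <- rb$full(best$par)
  par <- if (def$n_par == 1L) c(l = full[1L]) else c(l = full[1L], s = full[2L])
  list(par = par, sse = rb$sse(best$par), converged = best_conv)
}

# Validate that ip rows cover each (amount, effort level) cell exactly once.
check_cell_coverage <- function(ip_rows, spec) {
  cells <- expand.grid(effort_level = spec$effort_levels,
                       amount = spec$amounts, KEEP.OUT.ATTRS = FALSE)
  have <- paste(ip_rows$amount, ip_rows$effort_level)
  want <- paste(cells$amount, cells$effort_level)
  if (length(have) != length(want) || !setequal(have, want) ||
      anyDuplicated(have)) {
    stop_effdisc("indifference points must cover every amount x effort level cell exactly once",
                 "effdisc_input_error")
  }
  invisible(TRUE)
}

#' Fit a discounting model jointly across reward magnitudes
#'
#' The central fitting function. Takes the indifference points of one
#' analysis unit (one participant, or the group median) in one effort domain
#' and estimates the chosen model's parameters separately per reward
#' magnitude while minimising a single pooled sum of squared errors -- the
#' dummy-variable simultaneous fit, yielding one goodness-of-fit measure
#' across all magnitudes.
#'
#' The coefficient of determination follows the convention that a model
#' beaten by the grand mean is reported as \eqn{R^2 = 0} with its parameter
#' estimates set to missing (`clamped = TRUE`); the total sum of squares is
#' taken around the grand mean of all points entering the joint fit.
#'
#' @param ip_data Indifference-point data.frame for exactly one unit and one
#'   domain (columns `amount`, `effort_level`, `ip`; optionally
#'   `participant_id` and `domain`, which must then be single-valued).
#' @param model Model name (see [disc_models()]).
#' @param spec An [edq_design()] giving the amounts and effort levels the
#'   data must cover.
#' @return An object of class `disc_fit` with components `model`, `unit`,
#'   `domain`, `params` (per-magnitude estimates, `NA` when clamped),
#'   `params_raw` (unclamped least-squares estimates), `sse`, `n`, `p`,
#'   `r2`, `clamped`, `converged`, and the data fitted.
#' @examples
#' spec <- edq_design(effort_domains = "physical", amounts = c(80, 400),
#'                    effort_levels = c(30, 60, 90))
#' ips <- expand.grid(effort_level = c(30, 60, 90), amount = c(80, 400))
#' ips$ip <- ips$amount / (1 + 0.01 * ips$effort_level)
#' fit <- disc_fit(ips, "hyperbolic", spec)
#' coef(fit)
#' @export
disc_fit <- function(ip_data, model = "power", spec = edq_design()) {
  def <- match_model(model)
  check_columns(ip_data, c("amount", "effort_level", "ip"), "ip data")
  unit <- if ("participant_id" %in% names(ip_data)) {
    u <- unique(ip_data$participant_id)
    if (length(u) != 1L) {
      stop_effdisc("disc_fit expects a single unit; use disc_fit_all for batches",
                   "effdisc_input_error")
    }
    u
  } else "unit"
  domain <- if ("domain" %in% names(ip_data)) {
    d <- unique(ip_data$domain)
    if (length(d) != 1L) {
      stop_effdisc("disc_fit expects a single effort domain",
                   "effdisc_input_error")
    }
    d
  } else "domain"
  if (any(ip_data$effort_level == 0)) {
    stop_effdisc("zero-effort rows must be excluded before fitting (apply_exclusions)",
                 "effdisc_input_error")
  }
  check_cell_coverage(ip_data, spec)

  amounts <- spec$amounts
  n_mag <- length(amounts)
  blocks <- lapply(amounts, function(a) {
    rows <- ip_data[ip_data$amount == a, ]
    rows <- rows[order(rows$effort_level), ]
    rb <- reduced_block(model, def, a, rows$effort_level, rows$ip)
    c(rb, list(A = a, E = rows$effort_level, ip = rows$ip))
  })
  dim_b <- blocks[[1L]]$dim
  slice <- function(m) ((m - 1L) * dim_b + 1L):(m * dim_b)

  joint_obj <- function(theta) {
    total <- 0
    for (m in seq_len(n_mag)) total <- total + blocks[[m]]$sse(theta[slice(m)])
    total
  }
  # Block-structured joint estimation: because every parameter touches only
  # its own magnitude's points (the dummy variables zero out all others),
  # minimising each slice of the pooled objective over its block's ranked
  # starts and composing the coordinates minimises the pooled objective
  # itself -- one goodness-of-fit value, magnitude-specific estimates.
  block_best <- lapply(blocks, function(b) {
    starts <- ranked_starts(b)
    best_b <- NULL
    for (k in seq_len(min(nrow(starts), N_POLISH))) {
      res <- run_nlminb(b$sse, starts[k, ], b$lower, b$upper)
      if (is.null(best_b) || res$objective < best_b$objective) best_b <- res
    }
    polish_until_stable(b$sse, best_b, b$lower, b$upper)
  })
  best <- list(par = unlist(lapply(block_best, `[[`, "par")),
               ok = all(vapply(block_best, `[[`, TRUE, "ok")))

  theta <- best$par
  # the pooled objective re-evaluated at the composed vector is the
  # authoritative SSe (never the optimizer's last reported value)
  sse <- joint_obj(theta)
  converged <- best$ok

  full_pars <- t(vapply(seq_len(n_mag), function(m)
    blocks[[m]]$full(theta[slice(m)]), numeric(2L)))
  all_ip <- unlist(lapply(blocks, `[[`, "ip"))
  n <- length(all_ip)
  p <- def$n_par * n_mag
  rs <- r_squared(sse, all_ip)
  r2 <- rs$r2
  clamped <- rs$clamped
  if (!converged) r2 <- 0

  params_raw <- data.frame(amount = amounts, l = full_pars[, 1L],
                           s = full_pars[, 2L])
  params <- params_raw
  if (clamped || !converged) {
    params$l <- NA_real_
    params$s <- NA_real_
  }

  fitted_vals <- unlist(lapply(seq_len(n_mag), function(m) {
    th <- full_pars[m, if (def$n_par == 1L) 1L else 1:2]
    sv_eval(def$fn, blocks[[m]]$A, blocks[[m]]$E, th, def$n_par)
  }))
  data_out <- do.call(rbind, lapply(blocks, function(b)
    data.frame(amount = b$A, effort_level = b$E, ip = b$ip)))

  structure(list(model = model, unit = unit, domain = domain,
                 params = params, params_raw = params_raw,
                 sse = sse, n = n, p = p, r2 = r2,
                 clamped = clamped, converged = converged,
                 data = data_out, fitted = fitted_vals,
                 n_par = def$n_par, amounts = amounts),
            class = "disc_fit")
}

#' Coefficient of determination with the mean-beats-model convention
#'
#' \eqn{R^2 = 1 - SSe/SST} with SST taken around the grand mean of all
#' points entering the joint fit. When the mean explains more variance than
#' the model (\eqn{R^2 < 0}), or the points have no variance at all, the fit
#' is reported as \eqn{R^2 = 0} and flagged `clamped`, the signal to set
#' parameter estimates to missing.
#'
#' @param sse Residual sum of squares (>= 0).
#' @param ip_values All indifference points entering the fit (length >= 2).
#' @return A list with `r2` in \[0, 1\] and logical `clamped`.
#' @export
r_squared <- function(sse, ip_values) {
  stopifnot(is.numeric(sse), length(sse) == 1L, sse >= 0,
            length(ip_values) >= 2L)
  sst <- sum((ip_values - mean(ip_values))^2)
  if (sst == 0) return(list(r2 = 0, clamped = TRUE))
  r2 <- 1 - sse / sst
  if (r2 < 0) return(list(r2 = 0, clamped = TRUE))
  list(r2 = r2, clamped = FALSE)
}

#' @export
print.disc_fit <- function(x, ...) {
  cat(sprintf("Joint discounting fit: %s (%s, %s)\n",
              match_model(x$model)$label, x$unit, x$domain))
  cat(sprintf("  n = %d points, p = %d free parameters\n", x$n, x$p))
  cat(sprintf("  SSe = %.6g, R^2 = %.4f%s%s\n", x$sse, x$r2,
              if (x$clamped) " [clamped: mean beat the model]" else "",
              if (!x$converged) " [did not converge]" else ""))
  pr <- x$params
  for (i in seq_len(nrow(pr))) {
    cat(sprintf("  A = %-6g l = %-12.6g%s\n", pr$amount[i], pr$l[i],
                if (x$n_par == 2L) sprintf(" s = %-12.6g", pr$s[i]) else ""))
  }
  invisible(x)
}

#' @export
coef.disc_fit <- function(object, ...) {
  pr <- object$params
  out <- pr$l
  names(out) <- paste0("l_", pr$amount)
  if (object$n_par == 2L) {
    s <- pr$s
    names(s) <- paste0("s_", pr$amount)
    out <- c(out, s)
  }
  out
}

#' @export
fitted.disc_fit <- function(object, ...) object$fitted

#' @export
residuals.disc_fit <- function(object, ...) object$data$ip - object$fitted

#' Predict subjective values from a fitted discounting model
#'
#' Uses the raw least-squares estimates (even when the fit is clamped for
#' reporting, in which case a warning is issued). Amounts must be among the
#' fitted reward magnitudes, since parameters are magnitude-specific.
#'
#' @param object A `disc_fit` object.
#' @param newdata Data.frame with columns `amount` and `effort_level`;
#'   defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted subjective values (PLN).
#' @export
predict.disc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  check_columns(newdata, c("amount", "effort_level"), "newdata")
  if (object$clamped) {
    warning("fit is clamped (mean beat the model); predictions use raw estimates")
  }
  def <- match_model(object$model)
  vapply(seq_len(nrow(newdata)), function(i) {
    a <- newdata$amount[i]
    m <- match(a, object$params_raw$amount)
    if (is.na(m)) {
      stop_effdisc(sprintf("amount %g was not among the fitted magnitudes", a),
                   "effdisc_input_error")
    }
    th <- c(object$params_raw$l[m],
            if (object$n_par == 2L) object$params_raw$s[m])
    sv_eval(def$fn, a, newdata$effort_level[i], th, object$n_par)
  }, 0)
}

#' Simulate indifference-point tables from a fitted model
#'
#' Draws new indifference points from the fitted discounting curves plus
#' Gaussian residual noise with standard deviation
#' \eqn{\hat\sigma = \sqrt{SSe/(n - p)}}, truncated to \[0, A\].
#'
#' @param object A `disc_fit` object.
#' @param nsim Number of simulated tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data.frames shaped like `object$data`.
#' @export
simulate.disc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / max(object$n - object$p, 1L))
  lapply(seq_len(nsim), function(i) {
    out <- object$data
    out$ip <- pmin(pmax(object$fitted + stats::rnorm(object$n, 0, sigma), 0),
                   out$amount)
    out
  })
}

#' Plot a fitted discounting curve
#'
#' Draws the indifference points and the fitted subjective-value curve for
#' each reward magnitude, with subjective value expressed as a proportion of
#' the nominal amount so magnitudes share one panel.
#'
#' @param x A `disc_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.disc_fit <- function(x, ...) {
  def <- match_model(x$model)
  dat <- x$data
  graphics::plot(NA, xlim = range(c(0, dat$effort_level)), ylim = c(0, 1.05),
                 xlab = "Effort intensity (task units)",
                 ylab = "Subjective value (proportion of amount)",
                 main = sprintf("%s: %s, %s", match_model(x$model)$label,
                                x$unit, x$domain), ...)
  cols <- grDevices::hcl.colors(length(x$amounts), "Dark 3")
  for (m in seq_along(x$amounts)) {
    a <- x$amounts[m]
    rows <- dat[dat$amount == a, ]
    graphics::points(rows$effort_level, rows$ip / a, col = cols[m], pch = 16)
    th <- c(x$params_raw$l[m], if (x$n_par == 2L) x$params_raw$s[m])
    ee <- seq(0, max(dat$effort_level), length.out = 200)
    graphics::lines(ee, sv_eval(def$fn, a, ee, th, x$n_par) / a, col = cols[m])
  }
  graphics::legend("bottomleft", legend = paste("PLN", x$amounts),
                   col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' @export
summary.disc_fit <- function(object, ...) {
  out <- list(fit = object,
              aic = aic_sse(object$n, object$p, object$sse),
              aicc = aicc_sse(object$n, object$p, object$sse),
              bic = bic_sse(object$n, object$p, object$sse),
              residual_sd = sqrt(object$sse / max(object$n - object$p, 1L)))
  class(out) <- "summary.disc_fit"
  out
}

#' @export
print.summary.disc_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC = %.3f, AICc = %.3f, BIC = %.3f, residual SD = %.3f\n",
              x$aic, x$aicc, x$bic, x$residual_sd))
  invisible(x)
}

#' Fit several models to every unit and domain
#'
#' Applies [disc_fit()] per (unit, domain, model). Per-unit failures are
#' caught, logged and skipped rather than aborting the batch.
#'
#' @param ip_table Indifference-point data.frame (individual level, zero-effort
#'   rows already excluded or excluded here via [apply_exclusions()]).
#' @param models Character vector of model names (default: all seven).
#' @param spec An [edq_design()].
#' @param units `"individual"`, `"median"` (group medians via
#'   [group_median_ips()]) or `"both"`.
#' @return An object of class `disc_fitset`: a list of `disc_fit` objects
#'   with attributes `failures` (data.frame of unit/domain/model that
#'   errored).
#' @export
disc_fit_all <- function(ip_table, models = disc_models()$model,
                         spec = edq_design(), units = "individual") {
  units <- match.arg(units, c("individual", "median", "both"))
  for (m in models) match_model(m)   # fail fast on unknown model tokens
  ip_table <- apply_exclusions(ip_table)
  tabs <- list()
  if (units %in% c("individual", "both")) tabs$individual <- ip_table
  if (units %in% c("median", "both")) tabs$median <- group_median_ips(ip_table)
  fits <- list()
  failures <- data.frame(unit = character(), domain = character(),
                         model = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (tab in tabs) {
    for (id in unique(tab$participant_id)) {
      for (dom in unique(tab$domain)) {
        rows <- tab[tab$participant_id == id & tab$domain == dom, ]
        if (!nrow(rows)) next
        for (mod in models) {
          f <- tryCatch(disc_fit(rows, mod, spec), error = function(e) e)
          if (inherits(f, "error")) {
            failures <- rbind(failures,
                              data.frame(unit = id, domain = dom, model = mod,
                                         error = conditionMessage(f),
                                         stringsAsFactors = FALSE))
          } else {
            fits[[length(fits) + 1L]] <- f
          }
        }
      }
    }
  }
  if (nrow(failures)) {
    warning(sprintf("%d fit(s) failed and were skipped", nrow(failures)))
  }
  structure(fits, failures = failures, class = "disc_fitset")
}

#' @export
print.disc_fitset <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("disc_fitset: %d fits (%d units, %d domains, %d models)\n",
              length(x), length(unique(df$unit)),
              length(unique(df$domain)), length(unique(df$model))))
  fails <- attr(x, "failures")
  if (!is.null(fails) && nrow(fails)) {
    cat(sprintf("  %d failure(s) skipped\n", nrow(fails)))
  }
  invisible(x)
}

#' Long-format table of a batch of fits
#'
#' @param x A `disc_fitset`.
#' @param ... Unused.
#' @return Data.frame with one row per unit x domain x model x magnitude:
#'   `unit,domain,model,magnitude,l,s,sse,n,p,r2,clamped,converged`
#'   (fit-level columns repeated per magnitude row).
#' @export
as.data.frame.disc_fitset <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(f) {
    data.frame(unit = f$unit, domain = f$domain, model = f$model,
               magnitude = f$params$amount, l = f$params$l, s = f$params$s,
               sse = f$sse, n = f$n, p = f$p, r2 = f$r2,
               clamped = f$clamped, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
}
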
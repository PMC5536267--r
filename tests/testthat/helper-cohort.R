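# Shared fixtures built in code. The full-scale cohort fit is expensive, so
# it is computed once per test run and cached for every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-design cohort at the study's scale (114 agents, sigma = 0.03 A),
# fitted with all seven models on individual units.
full_cohort_fits <- function() {
  with_cache("full_cohort", {
    spec <- edq_design()
    cfg <- cohort_config(n_agents = 114, seed = 883271)
    cohort <- generate_cohort(cfg, spec)
    ips <- apply_exclusions(extract_ips(cohort$choices, spec))
    fits <- disc_fit_all(ips, spec = spec, units = "individual")
    list(spec = spec, config = cfg, cohort = cohort, ips = ips, fits = fits,
         selection = model_selection(fits))
  })
}

# A small cohort for cheap smoke/consistency checks.
small_cohort <- function(n = 6, seed = 4711, ...) {
  with_cache(paste0("small_", n, "_", seed, "_", paste(c(...), collapse = "_")), {
    spec <- edq_design()
    cfg <- cohort_config(n_agents = n, seed = seed, ...)
    cohort <- generate_cohort(cfg, spec)
    ips <- apply_exclusions(extract_ips(cohort$choices, spec))
    list(spec = spec, config = cfg, cohort = cohort, ips = ips)
  })
}

# Fast independent least-squares fit of the power model to one magnitude:
# l is profiled in closed form given s, and s is found by golden-section
# search over bracketing intervals. Used as the test-side oracle for the
# quantization-bound brute force, where tens of thousands of fits are needed.
power_profile_fit <- function(A, E, ip) {
  prof_l <- function(s) {
    Es <- E^s
    max(sum(Es * (A - ip)) / sum(Es * Es), 0)
  }
  obj <- function(s) {
    l <- prof_l(s)
    sum((ip - (A - l * E^s))^2)
  }
  best <- NULL
  for (iv in list(c(0.25, 1.5), c(1, 3), c(2.5, 6), c(5, 10))) {
    o <- stats::optimize(obj, iv, tol = 1e-9)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  s <- best$minimum
  c(l = prof_l(s), s = s)
}

# Exact indifference points from a parameter table (no ladder, no noise).
exact_ips <- function(model, spec, params) {
  rows <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
    data.frame(amount = params$amount[i], effort_level = spec$effort_levels,
               ip = sv(model, params$amount[i], spec$effort_levels,
                       params$l[i],
                       if ("s" %in% names(params)) params$s[i] else NULL))
  }))
  rows
}
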
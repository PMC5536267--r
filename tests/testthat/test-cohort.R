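# Synthetic cohort generator.

test_that("zero spread makes every agent the median agent", {
  spec <- edq_design()
  cfg <- cohort_config(n_agents = 3, sdlog_l = 0, sdlog_s = 0, noise_sd = 0,
                       seed = 1)
  agents <- generate_cohort(cfg, spec)$agents
  for (a in seq_along(spec$amounts)) {
    rows <- agents[agents$amount == spec$amounts[a], ]
    expect_true(all(rows$l_true == rows$l_true[1]))
    expect_equal(rows$s_true[1], cfg$s_medians[a])
    expect_equal(rows$l_true[1], cfg$l_medians[a])
  }
})

test_that("every agent shows the magnitude effect by construction", {
  spec <- edq_design()
  agents <- generate_cohort(cohort_config(n_agents = 40, seed = 12), spec)$agents
  for (key in split(agents, paste(agents$participant_id, agents$domain))) {
    key <- key[order(key$amount), ]
    expect_true(all(diff(key$l_true) < 0))
    expect_true(all(diff(key$s_true) > 0))
    expect_true(all(key$l_true > 0 & key$s_true > 0))
  }
})

test_that("the latent mixing scheme induces the requested cross-domain correlation", {
  spec <- edq_design()
  set.seed(314)
  cfg_hi <- cohort_config(n_agents = 500, model = "hyperbolic",
                          l_medians = c(6e-3, 3e-3, 1e-3), sdlog_l = 0.5,
                          rho_l = 0.99, seed = 314)
  ag <- sample_agents(cfg_hi, spec)
  l_phys <- ag$l_true[ag$domain == "physical" & ag$amount == 80]
  l_cog <- ag$l_true[ag$domain == "cognitive" & ag$amount == 80]
  expect_gt(stats::cor(l_phys, l_cog, method = "spearman"), 0.8)
  set.seed(314)
  cfg_lo <- cohort_config(n_agents = 500, model = "hyperbolic",
                          l_medians = c(6e-3, 3e-3, 1e-3), sdlog_l = 0.5,
                          rho_l = 0, seed = 314)
  ag0 <- sample_agents(cfg_lo, spec)
  r0 <- stats::cor(ag0$l_true[ag0$domain == "physical" & ag0$amount == 80],
                   ag0$l_true[ag0$domain == "cognitive" & ag0$amount == 80],
                   method = "spearman")
  expect_lt(abs(r0), 0.12)   # inside the null band at n = 500
})

test_that("deterministic valuations quantize to the ladder floor", {
  spec <- edq_design(effort_domains = "physical")
  # power agent with V = 80 - 0.2622222 * 90 = 56.4 at (A = 80, E = 90)
  cfg <- cohort_config(n_agents = 1, noise_sd = 0, sdlog_l = 0, sdlog_s = 0,
                       l_medians = c(0.2622222, 0.1, 0.01),
                       s_medians = c(1, 1.5, 2), seed = 3)
  cohort <- generate_cohort(cfg, spec)
  ips <- extract_ips(cohort$choices, spec)
  got <- ips$ip[ips$amount == 80 & ips$effort_level == 90]
  lad <- build_ladder(80)
  expect_equal(got, max(lad[lad <= 56.4]))  # brute-force scan: 56
  expect_equal(got, 56)
})

test_that("valuation extremes hit the no-discounting and full-discounting limits", {
  spec <- edq_design(effort_domains = "physical")
  tiny <- cohort_config(n_agents = 1, noise_sd = 0, sdlog_l = 0, sdlog_s = 0,
                        l_medians = c(3e-9, 2e-9, 1e-9), s_medians = c(1, 1.1, 1.2),
                        seed = 5)
  ips_tiny <- extract_ips(generate_cohort(tiny, spec)$choices, spec)
  # valuations sit a hair below A, so the floor convention yields at most one
  # ladder step of discounting; zero-effort pages value at exactly A
  expect_true(all(ips_tiny$ip >= 0.97 * ips_tiny$amount))
  expect_true(all(ips_tiny$ip[ips_tiny$effort_level == 0] == ips_tiny$amount[ips_tiny$effort_level == 0]))
  huge <- cohort_config(n_agents = 1, noise_sd = 0, sdlog_l = 0, sdlog_s = 0,
                        l_medians = c(1e6, 1e5, 1e4), s_medians = c(1, 1.1, 1.2),
                        seed = 6)
  ips_huge <- apply_exclusions(extract_ips(generate_cohort(huge, spec)$choices, spec))
  expect_true(all(ips_huge$ip == 0))
})

test_that("cohort generation is deterministic in the seed", {
  spec <- edq_design()
  a <- generate_cohort(cohort_config(n_agents = 3, seed = 123), spec)
  b <- generate_cohort(cohort_config(n_agents = 3, seed = 123), spec)
  expect_identical(a$agents, b$agents)
  expect_identical(a$choices, b$choices)
  c <- generate_cohort(cohort_config(n_agents = 3, seed = 124), spec)
  expect_false(identical(a$choices, c$choices))
})

test_that("cohort shape follows the design and the empty cohort is legal", {
  spec <- edq_design()
  cohort <- generate_cohort(cohort_config(n_agents = 4, seed = 9), spec)
  # 36 pages (30 conditions + 6 zero-effort) x 30 rows per participant
  expect_equal(nrow(cohort$choices), 4 * 36 * 30)
  expect_true(all(table(cohort$choices$participant_id) == 36 * 30))
  none <- generate_cohort(cohort_config(n_agents = 0, seed = 9), spec)
  expect_equal(nrow(none$choices), 0L)
  expect_equal(nrow(none$agents), 0L)
})

test_that("simulated choices always satisfy the single-switch rule", {
  spec <- edq_design()
  cohort <- generate_cohort(cohort_config(n_agents = 5, seed = 77), spec)
  expect_equal(nrow(find_switch_violations(cohort$choices)), 0L)
})

test_that("a seed is mandatory and invalid configurations are rejected", {
  expect_error(cohort_config(n_agents = 3), class = "effdisc_invalid_spec")
  expect_error(cohort_config(l_medians = c(1, 2, 3), seed = 1),
               class = "effdisc_invalid_spec")   # must decrease
  expect_error(cohort_config(s_medians = c(3, 2, 1), seed = 1),
               class = "effdisc_invalid_spec")   # must increase
})
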
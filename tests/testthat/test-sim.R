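test_that("lattice initialization satisfies Sir conservation and boundaries", {
  cfg <- sim_config(L = 4, N_sir_total = 2, distal_pinned_E = FALSE)
  st <- init_lattice(cfg, "all_active")
  expect_equal(st$sites, rep("E", 4))
  expect_equal(st$free_sir, 2L)

  cfg4 <- sim_config(L = 4, N_sir_total = 4, distal_pinned_E = FALSE)
  st4 <- init_lattice(cfg4, "all_silenced")
  expect_equal(st4$sites, rep("S", 4))
  expect_equal(st4$free_sir, 0L)

  # with the default pinned-active distal boundary the last site stays E
  cfg4p <- sim_config(L = 4, N_sir_total = 4)
  st4p <- init_lattice(cfg4p, "all_silenced")
  expect_equal(st4p$sites, c("S", "S", "S", "E"))
  expect_equal(st4p$free_sir, 1L)

  expect_error(init_lattice(sim_config(L = 200, N_sir_total = 100),
                            "all_silenced"),
               "infeasible")
  expect_error(init_lattice(cfg, "explicit", sites = c("S", "S", "S", "S")),
               "conservation")
  expect_error(init_lattice(cfg, "explicit",
                            sites = c("S", "U", "U", "U"), free_sir = 0),
               "conservation")
})

test_that("reaction enumeration matches the hand-computed propensities", {
  # lone A site flanked by two S, nearest-neighbour kernel:
  # deacetylation propensity = 2 * f(I) * k_deac
  cfg <- sim_config(L = 5, N_sir_total = 3, I = 1, locus_window = c(1, 3),
                    rates = sparse_rates(k_sir_deacetyl = 4),
                    telomere_nucleation = FALSE)
  st <- explicit_state(cfg, c("U", "S", "A", "S", "E"))
  rx <- enumerate_reactions(st, cfg)
  deac <- rx[rx$site == 3 & rx$to == "U", ]
  expect_equal(deac$propensity, 2 * 0.5 * 4)

  # with no free Sir every binding propensity is zero
  cfgb <- sim_config(L = 4, N_sir_total = 2, locus_window = c(1, 2),
                     rates = sparse_rates(k_sir_bind = 10))
  stb <- explicit_state(cfgb, c("S", "S", "U", "E"))
  expect_equal(stb$free_sir, 0L)
  rxb <- enumerate_reactions(stb, cfgb)
  expect_false(any(rxb$to == "S"))

  # interior without S: Sir-mediated reactions only via the nucleation term
  cfgn <- sim_config(L = 3, N_sir_total = 3, locus_window = c(1, 2),
                     rates = sparse_rates(k_sir_bind = 10,
                                          k_sir_deacetyl = 5))
  stn <- explicit_state(cfgn, c("U", "U", "E"))
  rxn <- enumerate_reactions(stn, cfgn)
  expect_true(all(rxn$to == "S"))
  expect_true(all(rxn$site == 1))  # nearest-neighbour kernel reaches site 1

  # pinned distal site never reacts
  cfgp <- sim_config(L = 4, N_sir_total = 4, locus_window = c(1, 2))
  stp <- init_lattice(cfgp, "all_active")
  expect_false(4 %in% enumerate_reactions(stp, cfgp)$site)
})

test_that("compiled propensities agree with the pure-R enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    cfg <- sim_config(
      L = 25L, N_sir_total = 12L, locus_window = c(2, 10),
      I = runif(1, 0, 4),
      nucleation_strength = runif(1, 0, 1),
      rates = rate_set(runif(1, 0, 5), runif(1, 0, 10), runif(1, 0, 10),
                       runif(1, 0, 20), runif(1, 0, 3), runif(1, 0, 0.5),
                       kernel = kernel_exponential(2, 3)))
    labels <- sample(c("U", "A", "M", "E", "S"), 25, replace = TRUE,
                     prob = c(.3, .2, .15, .15, .2))
    labels[25] <- "E"
    n_s <- sum(labels == "S")
    if (n_s > 12) labels[labels == "S"][seq_len(n_s - 12)] <- "U"
    st <- init_lattice(cfg, "explicit", sites = labels)
    rx <- enumerate_reactions(st, cfg)
    pm <- sirswitch:::.cpp_propensity_matrix(
      unname(sirswitch:::SIR_STATES[st$sites]), st$free_sir,
      sirswitch:::cpp_pars(cfg))
    # total and per-site propensities must agree between the two routes
    expect_equal(sum(rx$propensity), sum(pm), tolerance = 1e-12)
    by_site <- tapply(rx$propensity, factor(rx$site, levels = 1:25), sum)
    by_site[is.na(by_site)] <- 0
    expect_equal(as.numeric(by_site), as.numeric(colSums(pm)),
                 tolerance = 1e-12)
  }
})

test_that("a single step fires the right reaction at the right time", {
  # single possible reaction with propensity a: waiting times exponential
  cfg <- sim_config(L = 3, N_sir_total = 3, locus_window = c(1, 2),
                    rates = sparse_rates(k_sir_unbind = 2.5),
                    telomere_nucleation = FALSE)
  st <- explicit_state(cfg, c("S", "M", "E"))
  rx <- enumerate_reactions(st, cfg)
  expect_equal(nrow(rx), 1)
  expect_equal(rx$propensity, 2.5)

  set.seed(7)
  dts <- replicate(1e5, gillespie_step(st, rx, cfg)$dt)
  expect_equal(mean(dts), 1 / 2.5, tolerance = 0.02)

  # two reactions with propensities 1 and 3: selection frequency 3/4
  cfg2 <- sim_config(L = 3, N_sir_total = 3, locus_window = c(1, 2),
                     rates = sparse_rates(k_sir_unbind = 1,
                                          k_activation = 3),
                     telomere_nucleation = FALSE)
  st2 <- explicit_state(cfg2, c("S", "A", "E"))
  rx2 <- enumerate_reactions(st2, cfg2)
  expect_equal(sort(rx2$propensity), c(1, 3))
  set.seed(8)
  picks <- replicate(1e5, gillespie_step(st2, rx2, cfg2)$reaction$to)
  expect_equal(mean(picks == "E"), 0.75, tolerance = 0.02)

  # absorbing state signalled, not silently looped
  cfg0 <- sim_config(L = 3, N_sir_total = 3, locus_window = c(1, 2),
                     rates = sparse_rates(), telomere_nucleation = FALSE)
  st0 <- explicit_state(cfg0, c("U", "U", "E"))
  rx0 <- enumerate_reactions(st0, cfg0)
  out <- gillespie_step(st0, rx0, cfg0)
  expect_true(out$absorbed)
  expect_equal(out$dt, Inf)
})

test_that("single compiled steps replay the pure-R sampler exactly", {
  cfg <- tiny_config(rates = default_rate_set(), I = 0.5)
  st <- init_lattice(cfg, "telomere_silenced")
  for (seed in c(3, 14, 159)) {
    set.seed(seed)
    rx <- enumerate_reactions(st, cfg)
    r_step <- gillespie_step(st, rx, cfg)
    cfg1 <- cfg
    cfg1$seed <- seed
    cfg1$t_record <- 1e5  # stop on the event cap, not the clock
    cfg1$record_dt <- 1e5
    cpp <- simulate_lattice(cfg1, st, max_events = 1)
    expect_equal(cpp$final_state$sites, r_step$state$sites)
    expect_equal(cpp$final_state$free_sir, r_step$state$free_sir)
  }
})

test_that("mark-loss-only dynamics decays monotonically to all-U", {
  cfg <- tiny_config(rates = sparse_rates(k_mark_loss = 1), t_record = 30)
  st <- init_lattice(cfg, "telomere_silenced")
  tr <- simulate_lattice(cfg, st)
  non_u <- tr$n_S  # S count is non-increasing when only decay exists
  expect_true(all(diff(non_u) <= 0))
  expect_true(all(tr$final_state$sites[-cfg$L] == "U"))
  expect_equal(tail(tr$occupancy, 1), 0)
  expect_true(tr$absorbed)
})

test_that("identical seed, config and initial state give identical runs", {
  cfg <- tiny_config(seed = 7L, rates = default_rate_set())
  st <- init_lattice(cfg, "telomere_silenced")
  t1 <- simulate_lattice(cfg, st)
  t2 <- simulate_lattice(cfg, st)
  expect_identical(t1$occupancy, t2$occupancy)
  expect_identical(t1$final_state, t2$final_state)
  expect_identical(t1$n_events, t2$n_events)
})

test_that("the shipped rate set is bistable at I = 0 on the study lattice", {
  mean_occ <- function(mode, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- sim_config(seed = s)
      sir_occupancy(simulate_lattice(cfg, init_lattice(cfg, mode)))
    }, numeric(1)))
  }
  occ_sil <- mean_occ("telomere_silenced", 101:108)
  occ_act <- mean_occ("all_active", 201:208)
  expect_gt(occ_sil, 0.5)
  expect_lt(occ_act, 0.5)
  expect_gt(occ_sil - occ_act, 0.4)  # the hysteresis gap the search demands
})

test_that("occupancy readout averages the post-burn-in window fraction", {
  cfg <- tiny_config(rates = default_rate_set())
  tr <- simulate_lattice(cfg, init_lattice(cfg, "telomere_silenced"))
  keep <- tr$times >= cfg$t_burn
  expect_equal(sir_occupancy(tr), mean(tr$occupancy[keep]))
  expect_true(sir_occupancy(tr) >= 0 && sir_occupancy(tr) <= 1)
  expect_error(sir_occupancy(tr, window = c(1, 5)), "window")
  expect_error(sir_occupancy(tr, t_burn = 1e9), "insufficient")
  # hand-checkable average
  fake <- tr
  fake$times <- c(0, 10, 20)
  fake$occupancy <- c(0.9, 0.2, 0.6)
  expect_equal(sir_occupancy(fake), 0.4)
})

test_that("ensemble-mean occupancy is non-increasing in inhibitor level", {
  occ_at <- function(I) {
    mean(vapply(1:30, function(s) {
      cfg <- sim_config(I = I, seed = 7000L + s, t_record = 30)
      sir_occupancy(simulate_lattice(cfg,
                                     init_lattice(cfg, "telomere_silenced")))
    }, numeric(1)))
  }
  occs <- vapply(c(0, 1, 4), occ_at, numeric(1))
  expect_true(all(diff(occs) <= 0))
})

test_that("Sir conservation holds exactly over a long default run", {
  cfg <- sim_config(seed = 11L, t_record = 1e4, record_dt = 10)
  tr <- simulate_lattice(cfg, init_lattice(cfg, "telomere_silenced"),
                         max_events = 120000)
  expect_gte(tr$n_events, 1e5)
  expect_true(tr$conserved)
  expect_equal(sum(tr$final_state$sites == "S") + tr$final_state$free_sir,
               100)
  expect_true(all(tr$n_S + tr$free_sir_series == 100))
})

test_that("the bistability search accepts, rejects and fails as specified", {
  cfg <- tiny_config(t_record = 5, rates = default_rate_set())
  # vacuous criterion: the first sampled set is accepted
  r <- find_bistable_rates(config = cfg, min_gap = -1,
                           require_closure = FALSE, n_rep = 1,
                           max_tries = 10, seed = 2)
  expect_s3_class(r, "sir_rates")
  expect_equal(attr(r, "search")$tries, 1)

  # binding forced to zero: the silenced branch cannot persist
  bounds0 <- list(k_basal_acetyl = c(1, 2), k_sir_deacetyl = c(1, 2),
                  k_txn_feedback = c(1, 2), k_sir_bind = c(0, 0),
                  k_activation = c(0.5, 1), k_sir_unbind = c(0.1, 0.2))
  expect_error(
    find_bistable_rates(bounds = bounds0, config = cfg, min_gap = 0.3,
                        require_closure = FALSE, n_rep = 1, max_tries = 6,
                        seed = 3),
    "search failure")
})
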
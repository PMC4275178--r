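#' @useDynLib sirswitch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
NULL

# Nucleosome state alphabet. Codes are fixed by the C++ core.
SIR_STATES <- c(U = 0L, A = 1L, M = 2L, E = 3L, S = 4L)

#' Interaction kernels
#'
#' Kernel weights give the interaction strength between two lattice sites as a
#' function of their genomic separation in nucleosomes. The nearest-neighbour
#' kernel (range 1, weight 1) encodes the classic polymerization/oozing
#' picture in which a Sir-bound nucleosome acts only on its immediate
#' neighbours; the exponential kernel is the hook for looping-like variants
#' that let silencing act over a few nucleosomes.
#'
#' @param xi decay length in nucleosomes.
#' @param range maximum separation with non-zero weight.
#' @return numeric vector of weights for separations `1:range`.
#' @export
kernel_nearest <- function() 1.0

#' @rdname kernel_nearest
#' @export
kernel_exponential <- function(xi = 2, range = 3) {
  stopifnot(xi > 0, range >= 1)
  exp(-(seq_len(range)) / xi)
}

#' Non-cooperative inhibitor response
#'
#' Fraction of Sir activity remaining at scaled inhibitor concentration
#' `I` = \[inhibitor\]/K_D, the standard competitive-inhibition factor
#' 1/(1 + I). Multiplies all Sir-mediated rates (deacetylation and binding).
#'
#' @param I scaled inhibitor concentration (dimensionless, >= 0).
#' @export
inhibitor_linear <- function(I) 1 / (1 + I)

#' Reaction rate set for the silencing lattice model
#'
#' All rates are measured in units of the uniform mark-loss rate
#' (`k_mark_loss`), which stands in for cell-cycle dilution of chromatin
#' marks and is fixed at 1 to set the time scale.
#'
#' The transition graph: U -> A at `k_basal_acetyl` (basal, Sas-mediated);
#' A -> E at `k_activation` (establishment of the active state); A -> U at
#' `f(I) * k_sir_deacetyl * Ssum` (cooperative Sir-mediated deacetylation next
#' to Sir-bound sites); U/A -> M at `k_txn_feedback * Esum` (transcriptional
#' feedback from active neighbours); U -> S at
#' `f(I) * k_sir_bind * (free_sir/N_sir) * Ssum` (cooperative Sir binding,
#' titrated by the free pool); S -> U at `k_sir_unbind`; and every non-U state
#' -> U at `k_mark_loss`. M carries no outgoing edge other than mark loss and
#' blocks Sir binding. `Ssum`/`Esum` are kernel-weighted neighbour counts.
#'
#' @param k_basal_acetyl,k_sir_deacetyl,k_txn_feedback,k_sir_bind,k_activation,k_sir_unbind
#'   non-negative rates, in mark-loss units.
#' @param k_mark_loss uniform mark-loss rate; 1 defines the time unit.
#' @param kernel numeric vector of kernel weights for separations
#'   `1:length(kernel)`; non-negative and non-increasing.
#' @param inhibitor_response function of `I` in (0, 1] with `f(0) = 1`,
#'   strictly decreasing.
#' @return object of class `sir_rates`.
#' @export
rate_set <- function(k_basal_acetyl, k_sir_deacetyl, k_txn_feedback,
                     k_sir_bind, k_activation, k_sir_unbind,
                     k_mark_loss = 1, kernel = kernel_nearest(),
                     inhibitor_response = inhibitor_linear) {
  rates <- list(
    k_basal_acetyl = k_basal_acetyl, k_sir_deacetyl = k_sir_deacetyl,
    k_txn_feedback = k_txn_feedback, k_sir_bind = k_sir_bind,
    k_activation = k_activation, k_sir_unbind = k_sir_unbind,
    k_mark_loss = k_mark_loss, kernel = as.numeric(kernel),
    inhibitor_response = inhibitor_response
  )
  num <- rates[1:7]
  if (any(vapply(num, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1)))) {
    stop("all rates must be single non-negative numbers")
  }
  if (any(rates$kernel < 0) || is.unsorted(rev(rates$kernel))) {
    stop("kernel weights must be non-negative and non-increasing in distance")
  }
  f0 <- inhibitor_response(0)
  if (abs(f0 - 1) > 1e-12) stop("inhibitor_response must satisfy f(0) = 1")
  structure(rates, class = "sir_rates")
}

#' Default ('wild type') rate set
#'
#' A searched rate set for which the 200-site lattice with Sir capacity 100
#' (at the default nucleation strength 0.002, see [sim_config()]) shows
#' robust bistability at I = 0: started from a silenced telomeric domain the
#' locus window stays majority-silenced over intermediate times (occupancy
#' about 0.7), started from the all-active state it stays essentially
#' Sir-free, and the silenced state is lost by I = 4. The values come from a
#' seeded Latin-hypercube screen of the rate space refined on a local grid,
#' with every candidate judged by replicate ensembles of the full
#' pregrow/continue hysteresis protocol; [find_bistable_rates()] replays the
#' acceptance criterion. High basal acetylation plus strong transcriptional
#' feedback keep unmodified substrate rare in the active state, so de-novo
#' Sir nucleation needs the slow two-step (deacetylate-then-bind) path,
#' while strong binding and deacetylation keep an established domain
#' self-healing; that asymmetry is what makes the history dependence robust
#' at intermediate times.
#'
#' @export
default_rate_set <- function() {
  rate_set(
    k_basal_acetyl = 18,
    k_sir_deacetyl = 16,
    k_txn_feedback = 28,
    k_sir_bind = 30,
    k_activation = 0.5,
    k_sir_unbind = 0.1,
    kernel = kernel_exponential(xi = 2, range = 3)
  )
}

#' Simulation configuration
#'
#' @param L lattice length in nucleosomes; site 1 is the telomere-proximal
#'   end, site `L` the distal end.
#' @param N_sir_total fixed total Sir supply, in sites' worth; bound plus
#'   free Sir always sums to this (titration).
#' @param rates a [rate_set()].
#' @param I scaled inhibitor concentration.
#' @param locus_window inclusive site range whose S-fraction is the occupancy
#'   readout (default sites 5--50 from the telomere, clipped to the lattice).
#' @param t_burn burn-in horizon discarded from occupancy averages
#'   (mark-loss time units).
#' @param t_record total simulated horizon.
#' @param record_dt fixed recording cadence.
#' @param seed RNG seed for the run.
#' @param telomere_nucleation if `TRUE`, a permanent virtual Sir-bound site
#'   sits just off the telomere end and seeds Sir binding at sites within
#'   kernel range.
#' @param nucleation_strength silencer strength of the nucleation site
#'   relative to an interior Sir-bound nucleosome (its kernel contribution is
#'   multiplied by this factor). A weak nucleation centre (default 0.002,
#'   searched together with [default_rate_set()]) lets an established domain
#'   re-anchor while keeping de-novo establishment from the active state
#'   slow, which is what makes the history dependence observable at
#'   intermediate times.
#' @param distal_pinned_E if `TRUE`, site `L` is pinned in the active state
#'   E (transcriptionally active distal boundary) and never reacts.
#' @return object of class `sir_config`.
#' @export
sim_config <- function(L = 200L, N_sir_total = 100L, rates = default_rate_set(),
                       I = 0, locus_window = NULL, t_burn = 5,
                       t_record = 50, record_dt = 0.1, seed = 1L,
                       telomere_nucleation = TRUE, nucleation_strength = 0.002,
                       distal_pinned_E = TRUE) {
  if (is.null(locus_window)) locus_window <- pmin(c(5L, 50L), L)
  stopifnot(L >= 2, N_sir_total >= 0, inherits(rates, "sir_rates"), I >= 0,
            length(locus_window) == 2,
            locus_window[1] >= 1, locus_window[1] <= locus_window[2],
            locus_window[2] <= L, t_burn < t_record, record_dt > 0,
            nucleation_strength >= 0)
  structure(list(
    L = as.integer(L), N_sir_total = as.integer(N_sir_total), rates = rates,
    I = I, locus_window = as.integer(locus_window), t_burn = t_burn,
    t_record = t_record, record_dt = record_dt, seed = as.integer(seed),
    telomere_nucleation = isTRUE(telomere_nucleation),
    nucleation_strength = nucleation_strength,
    distal_pinned_E = isTRUE(distal_pinned_E)
  ), class = "sir_config")
}

new_lattice_state <- function(sites, free_sir, time = 0) {
  structure(list(sites = sites, free_sir = as.integer(free_sir), time = time),
            class = "lattice_state")
}

#' Validate a lattice state against its configuration
#'
#' Checks the state alphabet, Sir conservation (bound S sites plus the free
#' pool equal the configured capacity) and boundary pinning.
#'
#' @param state a `lattice_state`.
#' @param config a [sim_config()].
#' @export
validate_lattice_state <- function(state, config) {
  stopifnot(inherits(state, "lattice_state"))
  if (length(state$sites) != config$L) stop("lattice length mismatch")
  if (!all(state$sites %in% names(SIR_STATES))) {
    stop("invalid site label; must be one of U, A, M, E, S")
  }
  nS <- sum(state$sites == "S")
  if (state$free_sir < 0 || nS + state$free_sir != config$N_sir_total) {
    stop("Sir conservation violated: count(S) + free_sir != N_sir_total")
  }
  if (config$distal_pinned_E && state$sites[config$L] != "E") {
    stop("distal boundary site must be pinned in state E")
  }
  invisible(state)
}

#' Initialize a lattice state
#'
#' @param config a [sim_config()].
#' @param mode one of `"all_active"` (all E), `"all_silenced"` (every
#'   non-pinned site S; requires enough Sir capacity), `"telomere_silenced"`
#'   (a compact S domain of size `min(N_sir_total, L-1)` at the telomere end,
#'   active elsewhere), `"random"` (uniform over U/A/M/E; all Sir free), or
#'   `"explicit"` (take `sites` as given).
#' @param sites explicit label vector for `mode = "explicit"`.
#' @param free_sir optional explicit free-Sir count; if omitted it is derived
#'   from Sir conservation. Supplying a value inconsistent with conservation
#'   is an error.
#' @return a `lattice_state` satisfying all invariants.
#' @export
init_lattice <- function(config, mode = c("all_active", "all_silenced",
                                          "telomere_silenced", "random",
                                          "explicit"),
                         sites = NULL, free_sir = NULL) {
  mode <- match.arg(mode)
  L <- config$L
  N <- config$N_sir_total
  n_free_sites <- if (config$distal_pinned_E) L - 1L else L
  s <- switch(mode,
    all_active = rep("E", L),
    all_silenced = {
      if (n_free_sites > N) {
        stop(sprintf(
          "infeasible state: %d sites to silence but Sir capacity is %d",
          n_free_sites, N))
      }
      c(rep("S", n_free_sites), rep("E", L - n_free_sites))
    },
    telomere_silenced = {
      k <- min(N, n_free_sites)
      c(rep("S", k), rep("E", L - k))
    },
    random = sample(c("U", "A", "M", "E"), L, replace = TRUE),
    explicit = {
      if (is.null(sites)) stop("mode 'explicit' requires `sites`")
      as.character(sites)
    }
  )
  if (config$distal_pinned_E) s[L] <- "E"
  if (!all(s %in% names(SIR_STATES))) stop("invalid site label in `sites`")
  nS <- sum(s == "S")
  if (nS > N) {
    stop(sprintf("conservation error: %d S sites exceed Sir capacity %d",
                 nS, N))
  }
  fs <- if (is.null(free_sir)) N - nS else as.integer(free_sir)
  st <- new_lattice_state(s, fs)
  validate_lattice_state(st, config)
  st
}

# Flatten the pieces the C++ core needs, with f(I) pre-evaluated.
cpp_pars <- function(config) {
  r <- config$rates
  fI <- r$inhibitor_response(config$I)
  if (!is.finite(fI) || fI <= 0 || fI > 1) {
    stop("inhibitor_response(I) must lie in (0, 1]")
  }
  list(k_basal_acetyl = r$k_basal_acetyl, k_activation = r$k_activation,
       k_sir_deacetyl = r$k_sir_deacetyl, k_txn_feedback = r$k_txn_feedback,
       k_sir_bind = r$k_sir_bind, k_sir_unbind = r$k_sir_unbind,
       k_mark_loss = r$k_mark_loss, fI = fI,
       N_sir_total = as.numeric(config$N_sir_total),
       kernel_weights = r$kernel, pin_distal = config$distal_pinned_E,
       nucleation = if (config$telomere_nucleation)
         config$nucleation_strength else 0)
}

# Kernel-weighted neighbour sums, pure R (independent of the C++ core).
kernel_sum_r <- function(sites, target, kern, virtual_telomere_S = 1) {
  L <- length(sites)
  R <- length(kern)
  is_t <- sites == target
  out <- numeric(L)
  for (d in seq_len(R)) {
    w <- kern[d]
    if (d < L) {
      left <- c(rep(FALSE, d), is_t[seq_len(L - d)])   # neighbour at i - d
      right <- c(is_t[(1 + d):L], rep(FALSE, d))       # neighbour at i + d
      out <- out + w * (left + right)
    }
    if (target == "S" && virtual_telomere_S > 0 && d <= L) {
      # virtual S at position 0, separation d from site d
      out[d] <- out[d] + virtual_telomere_S * w
    }
  }
  out
}

#' Enumerate all possible reactions and their propensities
#'
#' Pure-R reference enumeration of the reaction set for a lattice state, in
#' the canonical site-major, channel-minor order used by the simulator's
#' event selection. Serves both as the single-step engine of
#' [gillespie_step()] and as an independent cross-check of the compiled core.
#'
#' @param state a `lattice_state`.
#' @param config a [sim_config()] supplying rates, inhibitor level, Sir
#'   capacity and boundary conditions.
#' @return data.frame with columns `site`, `channel`, `from`, `to`,
#'   `propensity`, containing only reactions with positive propensity.
#' @export
enumerate_reactions <- function(state, config) {
  validate_lattice_state(state, config)
  r <- config$rates
  fI <- r$inhibitor_response(config$I)
  s <- state$sites
  L <- config$L
  kern <- r$kernel
  ssum <- kernel_sum_r(s, "S", kern,
                       virtual_telomere_S = if (config$telomere_nucleation)
                         config$nucleation_strength else 0)
  esum <- kernel_sum_r(s, "E", kern, virtual_telomere_S = 0)
  free_frac <- state$free_sir / config$N_sir_total

  channels <- list(
    list(ch = 1L, name = "loss", from = c("A", "M", "E", "S"), to = "U",
         rate = function(i) r$k_mark_loss),
    list(ch = 2L, name = "acetyl", from = "U", to = "A",
         rate = function(i) r$k_basal_acetyl),
    list(ch = 3L, name = "activate", from = "A", to = "E",
         rate = function(i) r$k_activation),
    list(ch = 4L, name = "deacetyl", from = "A", to = "U",
         rate = function(i) fI * r$k_sir_deacetyl * ssum[i]),
    list(ch = 5L, name = "methylate", from = c("U", "A"), to = "M",
         rate = function(i) r$k_txn_feedback * esum[i]),
    list(ch = 6L, name = "bind", from = "U", to = "S",
         rate = function(i) fI * r$k_sir_bind * free_frac * ssum[i]),
    list(ch = 7L, name = "unbind", from = "S", to = "U",
         rate = function(i) r$k_sir_unbind)
  )
  reactive_sites <- if (config$distal_pinned_E) seq_len(L - 1L) else seq_len(L)
  rows <- vector("list", length(reactive_sites))
  for (i in reactive_sites) {
    props <- vapply(channels, function(chn) {
      if (s[i] %in% chn$from) chn$rate(i) else 0
    }, numeric(1))
    if (any(props < 0)) stop("internal invariant error: negative propensity")
    keep <- which(props > 0)
    if (length(keep)) {
      rows[[i]] <- data.frame(
        site = i, channel = keep,
        from = s[i],
        to = vapply(channels[keep], `[[`, character(1), "to"),
        propensity = props[keep]
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(site = integer(), channel = integer(),
                      from = character(), to = character(),
                      propensity = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Execute one Gillespie step
#'
#' Draws an exponential waiting time from the total propensity and fires one
#' reaction chosen with probability proportional to its propensity (two
#' uniform draws from R's RNG, waiting time first, matching the compiled
#' core's draw order).
#'
#' @param state a `lattice_state`.
#' @param reactions output of [enumerate_reactions()] on `state`.
#' @param config the matching [sim_config()].
#' @return list with `state` (updated), `dt`, `reaction` (the fired row), and
#'   `absorbed` (`TRUE` with `dt = Inf` when no reaction is possible).
#' @export
gillespie_step <- function(state, reactions, config) {
  total <- sum(reactions$propensity)
  if (nrow(reactions) == 0 || total <= 0) {
    return(list(state = state, dt = Inf, reaction = NULL, absorbed = TRUE))
  }
  dt <- -log(runif(1)) / total
  target <- runif(1) * total
  idx <- findInterval(target, cumsum(reactions$propensity),
                      left.open = TRUE) + 1L
  idx <- min(idx, nrow(reactions))
  rx <- reactions[idx, ]
  s <- state$sites
  fs <- state$free_sir
  if (s[rx$site] == "S" && rx$to != "S") fs <- fs + 1L
  if (rx$to == "S") fs <- fs - 1L
  s[rx$site] <- rx$to
  list(state = new_lattice_state(s, fs, state$time + dt), dt = dt,
       reaction = rx, absorbed = FALSE)
}

#' Run a full lattice simulation
#'
#' Gillespie simulation of the silencing lattice from a given initial state
#' to `config$t_record`, recording the S-fraction of the locus window at the
#' fixed cadence `config$record_dt`. Identical `(config, initial, seed)`
#' give bit-identical trajectories.
#'
#' @param config a [sim_config()].
#' @param initial a `lattice_state`, e.g. from [init_lattice()].
#' @param max_events optional cap on the number of reaction events
#'   (`NULL` = no cap); used for long invariant-checking runs.
#' @param check_conservation verify integer Sir conservation after every
#'   event (cheap; on by default).
#' @return object of class `sir_trajectory`: `times`, `occupancy`, `n_S`,
#'   `free_sir_series`, `final_state`, `n_events`, `conserved`, `absorbed`,
#'   `sir_total`, plus the config.
#' @export
simulate_lattice <- function(config, initial = init_lattice(config, "all_active"),
                             max_events = NULL, check_conservation = TRUE) {
  validate_lattice_state(initial, config)
  if (config$t_record / config$record_dt > 1e7) {
    stop("recording cadence would produce more than 1e7 samples; ",
         "increase record_dt")
  }
  set.seed(config$seed)
  codes <- unname(SIR_STATES[initial$sites])
  res <- .cpp_simulate(codes, initial$free_sir, cpp_pars(config),
                       config$t_record, config$record_dt,
                       config$locus_window[1], config$locus_window[2],
                       if (is.null(max_events)) -1L else as.integer(max_events),
                       isTRUE(check_conservation))
  if (check_conservation && !res$conserved) {
    stop("internal invariant error: Sir conservation violated during run")
  }
  labels <- names(SIR_STATES)[res$final_state + 1L]
  structure(list(
    times = res$times, occupancy = res$occupancy, n_S = res$n_S,
    free_sir_series = res$free_sir_series,
    final_state = new_lattice_state(labels, res$final_free_sir,
                                    res$final_time),
    n_events = res$n_events, conserved = res$conserved,
    absorbed = res$absorbed, sir_total = res$sir_total,
    config = config
  ), class = "sir_trajectory")
}

#' Time-averaged Sir occupancy of a locus
#'
#' Mean post-burn-in S-fraction of the locus window over the recorded
#' samples of a trajectory.
#'
#' @param traj a `sir_trajectory`.
#' @param window site range; must equal the window recorded in the
#'   trajectory's configuration (occupancy is recorded for that window only).
#' @param t_burn burn-in horizon; samples at `times < t_burn` are discarded.
#'   Defaults to the trajectory's configured value.
#' @return occupancy in \[0, 1\].
#' @export
sir_occupancy <- function(traj, window = traj$config$locus_window,
                          t_burn = traj$config$t_burn) {
  stopifnot(inherits(traj, "sir_trajectory"))
  if (!identical(as.integer(window), traj$config$locus_window)) {
    stop("occupancy was recorded for window [",
         traj$config$locus_window[1], ", ", traj$config$locus_window[2],
         "]; re-run the simulation to read out a different window")
  }
  keep <- traj$times >= t_burn
  if (!any(keep)) stop("insufficient data: no recorded samples after burn-in")
  mean(traj$occupancy[keep])
}

#' Search for a bistable ('wild type') rate set
#'
#' Samples rate sets log-uniformly within bounds and accepts the first one
#' whose lattice shows history-dependent occupancy: started from a silenced
#' telomeric domain versus from the all-active state at `I = I_low`, the
#' intermediate-time occupancy gap must exceed `min_gap`; optionally the two
#' histories must also agree (silencing lost) at `I = I_high`, so that the
#' bistable region closes within the scanned inhibitor range.
#'
#' @param bounds named list of `c(lo, hi)` bounds for the six searched rates
#'   (`k_basal_acetyl`, `k_sir_deacetyl`, `k_txn_feedback`, `k_sir_bind`,
#'   `k_activation`, `k_sir_unbind`).
#' @param config template [sim_config()]; its rates are replaced by each
#'   candidate.
#' @param min_gap acceptance criterion on the occupancy gap at `I_low`.
#' @param I_low,I_high inhibitor levels for the bistability and closure
#'   checks.
#' @param require_closure if `TRUE` a candidate must also lose the gap
#'   (both occupancies below `closure_occ`) at `I_high`.
#' @param closure_occ occupancy ceiling defining loss of silencing.
#' @param n_rep replicate runs per history per candidate (occupancies are
#'   averaged).
#' @param max_tries sampling budget; exhausting it is an error, not a silent
#'   fallback.
#' @param seed search RNG seed (recorded in the result).
#' @return the accepted `sir_rates`, with attributes `search` (seed,
#'   criterion, tries, measured gaps).
#' @export
find_bistable_rates <- function(bounds = list(
                                  k_basal_acetyl = c(8, 25),
                                  k_sir_deacetyl = c(6, 20),
                                  k_txn_feedback = c(15, 35),
                                  k_sir_bind = c(15, 40),
                                  k_activation = c(0.2, 1.2),
                                  k_sir_unbind = c(0.05, 0.3)),
                                config = sim_config(),
                                min_gap = 0.5, I_low = 0, I_high = 4,
                                require_closure = TRUE, closure_occ = 0.25,
                                n_rep = 3, max_tries = 200, seed = 1) {
  set.seed(seed)
  draw <- function(b) {
    if (b[1] == b[2]) return(b[1])
    if (b[1] <= 0) stop("log-uniform bounds must be positive (or equal)")
    exp(runif(1, log(b[1]), log(b[2])))
  }
  mean_occ <- function(cfg, mode, seeds) {
    mean(vapply(seeds, function(s) {
      cfg$seed <- s
      sir_occupancy(simulate_lattice(cfg, init_lattice(cfg, mode)))
    }, numeric(1)))
  }
  for (try in seq_len(max_tries)) {
    cand <- rate_set(
      k_basal_acetyl = draw(bounds$k_basal_acetyl),
      k_sir_deacetyl = draw(bounds$k_sir_deacetyl),
      k_txn_feedback = draw(bounds$k_txn_feedback),
      k_sir_bind = draw(bounds$k_sir_bind),
      k_activation = draw(bounds$k_activation),
      k_sir_unbind = draw(bounds$k_sir_unbind),
      kernel = config$rates$kernel,
      inhibitor_response = config$rates$inhibitor_response
    )
    cfg <- config
    cfg$rates <- cand
    seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_rep)
    cfg$I <- I_low
    occ_sil <- mean_occ(cfg, "telomere_silenced", seeds[seq_len(n_rep)])
    occ_act <- mean_occ(cfg, "all_active", seeds[n_rep + seq_len(n_rep)])
    gap <- occ_sil - occ_act
    if (gap < min_gap) next
    if (require_closure) {
      cfg$I <- I_high
      seeds_hi <- sample.int(.Machine$integer.max - 1L, 2 * n_rep)
      hi_sil <- mean_occ(cfg, "telomere_silenced", seeds_hi[seq_len(n_rep)])
      hi_act <- mean_occ(cfg, "all_active", seeds_hi[n_rep + seq_len(n_rep)])
      if (hi_sil > closure_occ || hi_act > closure_occ) next
    }
    attr(cand, "search") <- list(seed = seed, min_gap = min_gap,
                                 tries = try, gap_at_I_low = gap,
                                 occ_silenced = occ_sil,
                                 occ_active = occ_act)
    return(cand)
  }
  stop("search failure: no rate set met the bistability criterion within ",
       max_tries, " tries")
}

#' @export
print.sir_trajectory <- function(x, ...) {
  cat("Silencing-lattice trajectory\n",
      "  L = ", x$config$L, ", Sir capacity = ", x$config$N_sir_total,
      ", I = ", x$config$I, ", seed = ", x$config$seed, "\n",
      "  events: ", format(x$n_events, big.mark = ","),
      ", horizon: ", x$config$t_record, " mark-loss units\n",
      "  post-burn-in occupancy of sites [",
      x$config$locus_window[1], ", ", x$config$locus_window[2], "]: ",
      round(sir_occupancy(x), 3), "\n", sep = "")
  invisible(x)
}
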
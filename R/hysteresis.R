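# In-silico hysteresis protocol: pre-grow replicate lattices to their
# history-conditioned states at HIGH and LOW inhibitor, expose every replicate
# to each intermediate level, read out intermediate-time occupancy, and
# classify how the two branches meet.

#' Pre-grow replicate ensembles at the HIGH and LOW inhibitor levels
#'
#' Mimics growing two yeast populations for many generations with and
#' without the drug: independent long simulations at `I_high` (from the
#' all-active state) and `I_low` (from a compact silenced telomeric domain)
#' whose final lattices become the initial conditions of the scan.
#'
#' @param config a [sim_config()] template; `t_record` is the pre-growth
#'   horizon.
#' @param I_high,I_low pre-growth inhibitor levels (defaults 4 and 0).
#' @param n_rep replicates per history (>= 1).
#' @param seed master seed; per-replicate seeds are derived with
#'   [derive_seed()] and recorded.
#' @return list of class `pregrown_ensembles`: `high`, `low` (lists of
#'   `lattice_state`), `seeds`, `I_high`, `I_low`.
#' @export
pregrow_ensembles <- function(config, I_high = 4, I_low = 0, n_rep = 50,
                              seed = 1) {
  stopifnot(n_rep >= 1)
  grow <- function(I, mode, tag) {
    lapply(seq_len(n_rep), function(j) {
      cfg <- config
      cfg$I <- I
      cfg$seed <- derive_seed(seed, paste0("pregrow_", tag, "_", j))
      fin <- simulate_lattice(cfg, init_lattice(cfg, mode))$final_state
      fin$time <- 0
      fin
    })
  }
  structure(list(
    high = grow(I_high, "all_active", "high"),
    low = grow(I_low, "telomere_silenced", "low"),
    I_high = I_high, I_low = I_low, n_rep = n_rep, seed = seed
  ), class = "pregrown_ensembles")
}

#' Expose pre-grown ensembles to a grid of intermediate inhibitor levels
#'
#' Every ensemble member is continued at each grid level for the config's
#' `t_record`; short-time dynamics (before `t_burn`) is discarded and the
#' intermediate-time mean occupancy of the locus window recorded.
#'
#' @param config a [sim_config()] template.
#' @param I_grid increasing inhibitor levels.
#' @param ensembles a [pregrow_ensembles()] result.
#' @param seed master seed for the continuation runs.
#' @return object of class `hysteresis_scan`: data.frame `occupancies`
#'   (`I`, `history`, `replicate`, `occupancy`) plus `I_grid`, `n_rep`,
#'   `seed`.
#' @export
hysteresis_scan <- function(config, I_grid, ensembles, seed = 1) {
  stopifnot(length(I_grid) >= 1, !is.unsorted(I_grid),
            inherits(ensembles, "pregrown_ensembles"))
  rows <- list()
  for (I in I_grid) {
    for (hist in c("HIGH_pregrown", "LOW_pregrown")) {
      members <- if (hist == "HIGH_pregrown") ensembles$high else
        ensembles$low
      occ <- vapply(seq_along(members), function(j) {
        cfg <- config
        cfg$I <- I
        cfg$seed <- derive_seed(seed, paste0("scan_", hist, "_", I, "_", j))
        sir_occupancy(simulate_lattice(cfg, members[[j]]))
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        I = I, history = hist, replicate = seq_along(members),
        occupancy = occ)
    }
  }
  new_hysteresis_scan(do.call(rbind, rows), sort(I_grid), ensembles$n_rep,
                      seed)
}

new_hysteresis_scan <- function(occupancies, I_grid, n_rep, seed = NA) {
  stopifnot(all(c("I", "history", "replicate", "occupancy") %in%
                  names(occupancies)),
            all(occupancies$occupancy >= 0 & occupancies$occupancy <= 1))
  for (I in I_grid) {
    h <- unique(occupancies$history[occupancies$I == I])
    if (!all(c("HIGH_pregrown", "LOW_pregrown") %in% h)) {
      stop("both histories must be present at every grid point")
    }
  }
  structure(list(occupancies = occupancies, I_grid = I_grid, n_rep = n_rep,
                 seed = seed),
            class = "hysteresis_scan")
}

#' Classify the bistable-to-monostable transition of a hysteresis scan
#'
#' Summarizes the scan into per-level branch means, the occupancy gap
#' (LOW-history minus HIGH-history) with its pooled standard error, a
#' threshold estimate (smallest inhibitor level where the absolute gap is
#' within `gap_tol` pooled standard errors of zero and stays so), and a
#' scenario label: `continuous_merge` when the gap shrinks gradually into
#' the noise (supercritical-pitchfork-like), `discontinuous_jump` when a
#' single grid step drops the gap by more than `jump_tol` of its maximum
#' while the branches were still clearly separated just below the threshold
#' (saddle-node-like), `monostable_everywhere`/`bistable_everywhere` when
#' the gap is inside/outside tolerance across the whole grid. A jump-sized
#' drop without clear separation below the threshold is flagged `ambiguous`
#' rather than guessed.
#'
#' @param scan a `hysteresis_scan` (>= 4 grid points; >= 2 replicates per
#'   history for standard errors).
#' @param gap_tol tolerance in pooled standard errors (default 2).
#' @param jump_tol fraction of the maximum gap that a single-step drop must
#'   exceed to count as a jump (default 0.5).
#' @return object of class `bifurcation_report`: `branches` data.frame
#'   (`I`, `mean_low`, `mean_high`, `gap`, `se`), `threshold`,
#'   `threshold_uncertainty`, `classification`, `ambiguous`,
#'   `out_of_range`.
#' @export
classify_bifurcation <- function(scan, gap_tol = 2, jump_tol = 0.5) {
  stopifnot(inherits(scan, "hysteresis_scan"), length(scan$I_grid) >= 4)
  occ <- scan$occupancies
  agg <- function(I, hist) {
    x <- occ$occupancy[occ$I == I & occ$history == hist]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
  }
  br <- do.call(rbind, lapply(scan$I_grid, function(I) {
    lo <- agg(I, "LOW_pregrown")
    hi <- agg(I, "HIGH_pregrown")
    data.frame(I = I, mean_low = lo["mean"], mean_high = hi["mean"],
               gap = lo["mean"] - hi["mean"],
               se = sqrt(lo["se"]^2 + hi["se"]^2))
  }))
  rownames(br) <- NULL
  if (any(!is.finite(br$se))) {
    stop("ensemble size must be >= 2 per history for uncertainty estimates")
  }
  closed <- abs(br$gap) <= gap_tol * br$se
  n <- nrow(br)

  out_of_range <- FALSE
  if (all(closed)) {
    classification <- "monostable_everywhere"
    threshold <- br$I[1]
    thr_idx <- 1L
  } else if (!any(closed)) {
    classification <- "bistable_everywhere"
    threshold <- NA_real_
    thr_idx <- NA_integer_
    out_of_range <- TRUE
  } else {
    thr_idx <- which(closed)[1]
    threshold <- br$I[thr_idx]
    classification <- NA_character_
  }

  ambiguous <- FALSE
  if (is.na(classification)) {
    g <- abs(br$gap)
    max_gap <- max(g)
    drops <- -diff(g)
    jump_detected <- any(drops > jump_tol * max_gap)
    separated_below <- thr_idx > 1 &&
      g[thr_idx - 1] > gap_tol * br$se[thr_idx - 1] &&
      g[thr_idx - 1] > jump_tol * max_gap
    if (jump_detected && separated_below) {
      classification <- "discontinuous_jump"
    } else if (!jump_detected) {
      classification <- "continuous_merge"
    } else {
      classification <- "continuous_merge"
      ambiguous <- TRUE
    }
  }

  thr_unc <- if (!is.na(thr_idx) && thr_idx > 1) {
    br$I[thr_idx] - br$I[thr_idx - 1]
  } else if (length(br$I) > 1) {
    br$I[2] - br$I[1]
  } else {
    NA_real_
  }

  structure(list(branches = br, threshold = threshold,
                 threshold_uncertainty = thr_unc,
                 classification = classification, ambiguous = ambiguous,
                 out_of_range = out_of_range,
                 gap_tol = gap_tol, jump_tol = jump_tol),
            class = "bifurcation_report")
}

#' @export
print.bifurcation_report <- function(x, ...) {
  cat("Bifurcation report\n")
  print(transform(x$branches, gap = signif(gap, 3), se = signif(se, 3)),
        row.names = FALSE)
  cat("classification:", x$classification,
      if (x$ambiguous) "(ambiguous: grid too coarse to rule out a jump)",
      "\nthreshold:", x$threshold, "+/-", x$threshold_uncertainty, "\n")
  invisible(x)
}
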
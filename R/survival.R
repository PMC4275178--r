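#' Dilution-corrected 5-FOA survival fractions
#'
#' In the 5-FOA assay, cells with the telomeric *URA3* reporter silenced
#' survive on 5-FOA plates while expressing cells die, so the dilution-scaled
#' colony-count ratio between a 5-FOA plate and a YPD (total viable count)
#' plate estimates the silenced fraction of the population:
#' `S = (N_FOA / d_FOA) / (N_YPD / d_YPD)`.
#'
#' Relative error follows Poisson counting statistics,
#' `sqrt(1/max(N_FOA, 1) + 1/N_YPD)`. A zero 5-FOA count yields an upper
#' bound (as if one colony had been seen) with `is_upper_bound` set.
#'
#' @param counts data.frame with columns `concentration_uM`, `history`,
#'   `N_YPD`, `d_YPD`, `N_FOA`, `d_FOA` (one row per plate pair). Dilution
#'   factors must lie in (0, 1]; counts must be non-negative integers and
#'   `N_YPD >= 1`.
#' @return the input data.frame with columns `S_hat`, `rel_err`,
#'   `is_upper_bound` appended.
#' @export
survival_fraction <- function(counts) {
  required <- c("concentration_uM", "history", "N_YPD", "d_YPD",
                "N_FOA", "d_FOA")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  with(counts, {
    if (any(N_YPD %% 1 != 0 | N_FOA %% 1 != 0 | N_YPD < 0 | N_FOA < 0)) {
      stop("colony counts must be non-negative integers")
    }
    if (any(d_YPD <= 0 | d_YPD > 1 | d_FOA <= 0 | d_FOA > 1)) {
      stop("dilution factors must lie in (0, 1]")
    }
    if (any(N_YPD == 0)) {
      stop("undefined denominator: N_YPD = 0 (no viable-count estimate)")
    }
  })
  ub <- counts$N_FOA == 0
  n_foa <- ifelse(ub, 1, counts$N_FOA)  # zero counts become 1-colony bounds
  counts$S_hat <- (n_foa / counts$d_FOA) / (counts$N_YPD / counts$d_YPD)
  counts$rel_err <- sqrt(1 / pmax(counts$N_FOA, 1) + 1 / counts$N_YPD)
  counts$is_upper_bound <- ub
  counts
}

#' Assemble a per-history survival curve
#'
#' @param estimates output of [survival_fraction()].
#' @param history which pre-growth history to extract (`"LOW_pregrown"` grown
#'   without inhibitor, `"HIGH_pregrown"` grown at the high inhibitor level).
#' @param mutation_floor apparent survival contributed by 5-FOA-resistant
#'   mutants; carried as an attribute for [floor_subtract()].
#' @return object of class `survival_curve`: a data.frame ordered by strictly
#'   increasing concentration with attributes `history` and `mutation_floor`.
#' @export
survival_curve <- function(estimates, history, mutation_floor = 1e-6) {
  stopifnot(mutation_floor >= 0)
  cur <- estimates[estimates$history == history, , drop = FALSE]
  if (!nrow(cur)) stop("no rows for history ", history)
  cur <- cur[order(cur$concentration_uM), , drop = FALSE]
  if (any(diff(cur$concentration_uM) <= 0)) {
    stop("concentrations must be strictly increasing (one plate pair each)")
  }
  rownames(cur) <- NULL
  structure(cur, class = c("survival_curve", "data.frame"),
            history = history, mutation_floor = mutation_floor)
}

#' Subtract the mutational escape floor
#'
#' 5-FOA survivors at saturating inhibitor are mutants that grow regardless
#' of silencing; their apparent survival (default 1e-6) is subtracted, with
#' values clipped at zero flagged in a `floored` column. The pre-subtraction
#' value is kept in `S_raw` so downstream log-scale statistics can fall back
#' to it as an upper bound.
#'
#' @param curve a [survival_curve()].
#' @return the curve with `S_hat` floored, plus `S_raw` and `floored`.
#' @export
floor_subtract <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  floor_ <- attr(curve, "mutation_floor")
  curve$S_raw <- curve$S_hat
  curve$S_hat <- pmax(curve$S_hat - floor_, 0)
  curve$floored <- curve$S_raw <= floor_
  curve
}

#' Concentration at which two history-conditioned curves converge
#'
#' The operational signature of the bistable-to-monostable transition in the
#' 5-FOA assay: below it, survival depends on pre-growth history; past it the
#' two curves agree. Convergence is declared at the smallest concentration
#' where the log10 survival difference is within `k_se` combined log-scale
#' standard errors, and remains so at all larger concentrations.
#'
#' @param curve_low,curve_high [survival_curve()]s on the same concentration
#'   grid (LOW- and HIGH-pregrowth histories).
#' @param k_se convergence tolerance in combined standard errors (default 2).
#' @return list with `threshold` (µM; `NA` if the curves never converge),
#'   `uncertainty` (spacing to the previous grid point), `no_threshold` flag
#'   and the per-concentration comparison table.
#' @export
convergence_threshold <- function(curve_low, curve_high, k_se = 2) {
  stopifnot(inherits(curve_low, "survival_curve"),
            inherits(curve_high, "survival_curve"))
  if (!isTRUE(all.equal(curve_low$concentration_uM,
                        curve_high$concentration_uM))) {
    stop("curves must share the same concentration grid")
  }
  conc <- curve_low$concentration_uM
  # Poisson relative error approximates the SD of log_e S; convert to log10
  dlog <- abs(log10(curve_low$S_hat) - log10(curve_high$S_hat))
  se <- sqrt(curve_low$rel_err^2 + curve_high$rel_err^2) / log(10)
  ok <- dlog <= k_se * se
  ok[is.na(ok)] <- FALSE
  # smallest concentration from which convergence persists
  persist <- rev(cumprod(rev(ok))) == 1
  tab <- data.frame(concentration_uM = conc, dlog10 = dlog,
                    se_log10 = se, converged = ok)
  if (!any(persist)) {
    return(list(threshold = NA_real_, uncertainty = NA_real_,
                no_threshold = TRUE, table = tab))
  }
  idx <- which(persist)[1]
  unc <- if (idx == 1) NA_real_ else conc[idx] - conc[idx - 1]
  list(threshold = conc[idx], uncertainty = unc, no_threshold = FALSE,
       table = tab)
}

#' Log-survival drop per decade of concentration
#'
#' Steepness statistic for the approach to the threshold:
#' `(log10 S(c_lo) - log10 S(c_hi)) / (log10 c_hi - log10 c_lo)`. A value of
#' 5 over one concentration decade is a five-orders-of-magnitude drop.
#'
#' @param curve a [survival_curve()], possibly after [floor_subtract()].
#' @param c_lo,c_hi concentrations on the curve's grid, `c_lo < c_hi`, both
#'   positive (log scale).
#' @return the drop statistic, with attribute `used_upper_bound` set when a
#'   floored zero forced the pre-subtraction value to stand in as an upper
#'   bound.
#' @export
log_drop_per_decade <- function(curve, c_lo, c_hi) {
  stopifnot(inherits(curve, "survival_curve"), c_lo < c_hi, c_lo > 0)
  conc <- curve$concentration_uM
  i_lo <- match(c_lo, conc)
  i_hi <- match(c_hi, conc)
  if (is.na(i_lo) || is.na(i_hi)) stop("c_lo and c_hi must be on the grid")
  s <- curve$S_hat[c(i_lo, i_hi)]
  used_ub <- FALSE
  if (any(s <= 0)) {
    if (is.null(curve$S_raw)) stop("zero survival and no raw value to bound")
    s[s <= 0] <- curve$S_raw[c(i_lo, i_hi)][s <= 0]
    used_ub <- TRUE
    if (any(s <= 0)) stop("survival is zero with no usable upper bound")
  }
  drop <- (log10(s[1]) - log10(s[2])) / (log10(c_hi) - log10(c_lo))
  structure(drop, used_upper_bound = used_ub)
}

#' Hill model of inhibitor action on Sir2
#'
#' The single-molecule-cooperativity straw man: if the sharp survival drop
#' were explained at the level of the enzyme alone, the fraction of active
#' Sir2 would have to fall as `A_0 / (1 + (c/K_d)^n)` with a large Hill
#' coefficient. In-vitro inhibition of Sir2 is consistent with `n = 1` and an
#' IC50 (identified with `K_d`) near 60 µM, which is what
#' [cooperativity_contrast()] puts side by side with the cooperative variant.
#'
#' @param K_d dissociation constant, µM (> 0).
#' @param n Hill coefficient (> 0).
#' @param A_0 active-Sir2 level at zero inhibitor.
#' @return object of class `hill_model`.
#' @export
hill_model <- function(K_d, n, A_0 = 1) {
  stopifnot(K_d > 0, n > 0, A_0 > 0)
  structure(list(K_d = K_d, n = n, A_0 = A_0), class = "hill_model")
}

#' @rdname hill_model
#' @param c inhibitor concentration(s), µM (>= 0).
#' @param model a [hill_model()].
#' @return active-Sir2 fraction(s) in (0, `A_0`].
#' @export
hill_active_fraction <- function(c, model) {
  stopifnot(inherits(model, "hill_model"), all(c >= 0))
  model$A_0 / (1 + (c / model$K_d)^model$n)
}

#' Contrast cooperative and non-cooperative inhibition
#'
#' Evaluates two Hill models over a concentration range and reports their
#' fold-drops across it, quantifying how much steeper a cooperative
#' (`n` of 5--6) response is than the measured non-cooperative one.
#'
#' @param model_coop,model_flat [hill_model()]s.
#' @param c_range concentrations to evaluate (µM).
#' @return data.frame with columns `concentration_uM`, `active_coop`,
#'   `active_flat`; attribute `fold_drop` holds each model's ratio of active
#'   fraction between the smallest and largest concentration.
#' @export
cooperativity_contrast <- function(model_coop, model_flat,
                                   c_range = seq(2.5, 25, by = 2.5)) {
  a_coop <- hill_active_fraction(c_range, model_coop)
  a_flat <- hill_active_fraction(c_range, model_flat)
  out <- data.frame(concentration_uM = c_range, active_coop = a_coop,
                    active_flat = a_flat)
  attr(out, "fold_drop") <- c(coop = a_coop[1] / a_coop[length(a_coop)],
                              flat = a_flat[1] / a_flat[length(a_flat)])
  out
}
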
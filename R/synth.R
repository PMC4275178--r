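# Synthetic-data generators emulating the statistical structure of the two
# population assays: 5-FOA plate counts from a bistable two-state population
# with concentration-dependent switching and a mutational escape floor, and
# per-colony RGB intensities from per-plate Gaussian mixtures whose
# components either merge continuously (pitchfork scenario) or lose the
# 'off' weight at constant separation (saddle scenario). Every generator is
# seed-deterministic and returns its ground truth alongside the data.

#' Two-state population model for the 5-FOA assay
#'
#' Each cell is silenced ('off', survives 5-FOA) or expressing ('on', dies),
#' with per-generation switching probabilities that are logistic in log
#' concentration around the bistability threshold `c_star`: derepression
#' (off to on) rises from 0 to `p_derepress_max` as `c` crosses `c_star`
#' with sharpness `s`; re-silencing (on to off) is rare and fades above the
#' threshold. A fraction `mu` of cells are 5-FOA-resistant mutants that
#' survive regardless.
#'
#' @param c_grid assay concentrations, µM (default the 18-point design).
#' @param c_star bistable-to-monostable threshold, µM.
#' @param g generations of growth at the intermediate concentration
#'   (12--15 in the assay; default 14, enough to dilute pre-existing
#'   protein by 2^14 > 1e4).
#' @param s logistic sharpness in log concentration.
#' @param p_derepress_max per-generation off-to-on probability far above
#'   threshold.
#' @param p_silence_max per-generation on-to-off probability far below
#'   threshold.
#' @param f_off_init named initial silenced fractions per pre-growth
#'   history.
#' @param mu mutational 5-FOA escape rate.
#' @param N_plated cells plated per plate before dilution.
#' @param target_count dilutions are chosen (as in the assay, where serial
#'   dilutions were adjusted for reliable counts) so expected colony counts
#'   are near this value.
#' @return object of class `population_model`.
#' @export
population_model <- function(c_grid = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12,
                                        14, 16, 20, 30, 40, 50, 60),
                             c_star = 25, g = 14L, s = 8,
                             p_derepress_max = 0.9, p_silence_max = 1e-5,
                             f_off_init = c(LOW_pregrown = 0.999,
                                            HIGH_pregrown = 1e-3),
                             mu = 1e-6, N_plated = 2e7, target_count = 200) {
  stopifnot(!is.unsorted(c_grid, strictly = TRUE), c_star > 0, g >= 1,
            s > 0, p_derepress_max >= 0, p_derepress_max <= 1,
            p_silence_max >= 0, p_silence_max <= 1, mu >= 0,
            all(f_off_init >= 0 & f_off_init <= 1),
            all(c("LOW_pregrown", "HIGH_pregrown") %in% names(f_off_init)))
  structure(list(c_grid = c_grid, c_star = c_star, g = as.integer(g), s = s,
                 p_derepress_max = p_derepress_max,
                 p_silence_max = p_silence_max, f_off_init = f_off_init,
                 mu = mu, N_plated = N_plated, target_count = target_count),
            class = "population_model")
}

#' @rdname population_model
#' @param c concentration(s), µM.
#' @param model a [population_model()].
#' @return `k_off_on` and `k_on_off` give the per-generation off-to-on
#'   (derepression) and on-to-off (silencing) switching probabilities.
#' @export
k_off_on <- function(c, model) {
  model$p_derepress_max *
    ifelse(c <= 0, 0, stats::plogis(model$s * log(c / model$c_star)))
}

#' @rdname population_model
#' @export
k_on_off <- function(c, model) {
  model$p_silence_max *
    ifelse(c <= 0, 1, 1 - stats::plogis(model$s * log(c / model$c_star)))
}

#' Evolve the silenced fraction over generations
#'
#' Iterates the two-state Markov chain
#' `f' = f (1 - k_off_on) + (1 - f) k_on_off` for `g` generations.
#'
#' @param f0 initial silenced fraction.
#' @param c concentration, µM.
#' @param model a [population_model()].
#' @param g generations (default the model's).
#' @return silenced fraction after `g` generations.
#' @export
evolve_off_fraction <- function(f0, c, model, g = model$g) {
  a <- k_off_on(c, model)  # off -> on
  b <- k_on_off(c, model)  # on -> off
  f <- f0
  for (i in seq_len(g)) f <- f * (1 - a) + (1 - f) * b
  f
}

# smallest power-of-ten dilution bringing the expectation near the target
choose_dilution <- function(expected_full, target) {
  if (expected_full <= target) return(1)
  10^(-ceiling(log10(expected_full / target)))
}

#' Generate synthetic 5-FOA/YPD plate counts
#'
#' For every concentration and history the silenced fraction is evolved over
#' `g` generations, the true survival is `f_off (1 - mu) + mu`, power-of-ten
#' dilutions are chosen to put expected counts near `target_count`, and
#' colony counts are drawn as Poisson. The output table is the survival
#' pipeline's input dialect; the ground truth travels alongside.
#'
#' @param model a [population_model()].
#' @param seed RNG seed.
#' @return list with `counts` (data.frame `concentration_uM`, `history`,
#'   `N_YPD`, `d_YPD`, `N_FOA`, `d_FOA`), `truth` (true `f_off` and
#'   `survival` per row, plus `c_star`, `mu`, `seed` as attributes) and
#'   `model`.
#' @export
generate_plate_counts <- function(model = population_model(), seed = 1) {
  set.seed(seed)
  rows <- truth <- list()
  for (hist in c("LOW_pregrown", "HIGH_pregrown")) {
    for (cc in model$c_grid) {
      f_off <- evolve_off_fraction(model$f_off_init[[hist]], cc, model)
      surv <- f_off * (1 - model$mu) + model$mu
      d_ypd <- choose_dilution(model$N_plated, model$target_count)
      d_foa <- choose_dilution(model$N_plated * surv, model$target_count)
      lam_ypd <- model$N_plated * d_ypd
      lam_foa <- model$N_plated * surv * d_foa
      if (lam_ypd > 1e6 || lam_foa > 1e6) {
        stop("expected counts exceed 1e6 per plate; use a larger dilution")
      }
      rows[[length(rows) + 1]] <- data.frame(
        concentration_uM = cc, history = hist,
        N_YPD = stats::rpois(1, lam_ypd), d_YPD = d_ypd,
        N_FOA = stats::rpois(1, lam_foa), d_FOA = d_foa)
      truth[[length(truth) + 1]] <- data.frame(
        concentration_uM = cc, history = hist, f_off = f_off,
        survival = surv)
    }
  }
  truth <- do.call(rbind, truth)
  attr(truth, "c_star") <- model$c_star
  attr(truth, "mu") <- model$mu
  attr(truth, "seed") <- seed
  list(counts = do.call(rbind, rows), truth = truth, model = model)
}

#' Colony-colour model for the ADE2 pigmentation assay
#'
#' Each plate is a (possibly degenerate) two-component Gaussian mixture in
#' RGB space. In the `pitchfork` scenario the 'on' and 'off' component means
#' approach each other as `separation0 * max(0, 1 - c/c_merge)^beta` and
#' merge at `c_merge` with the 'off' weight held fixed; in the `saddle`
#' scenario the separation stays constant while the 'off' weight falls
#' linearly to zero at `c_merge`. Whole plates are scaled by a random
#' illumination factor, which the per-plate normalization must undo.
#'
#' @param scenario `"pitchfork"` or `"saddle"`.
#' @param c_grid plate concentrations, µM.
#' @param c_merge merge concentration, µM.
#' @param m_on,m_off base component means (R, G, B) at `c = 0`; 'off'
#'   (pigmented) must have the larger red channel.
#' @param beta merge exponent (0.5 = square-root closing, the normal-form
#'   scaling of a supercritical pitchfork).
#' @param noise_sd per-channel within-component SD.
#' @param w_off0 'off' weight at `c = 0`.
#' @param n_colonies colonies per plate.
#' @param illumination_sd SD of the log-normal per-plate illumination
#'   scalar.
#' @return object of class `color_model`.
#' @export
color_model <- function(scenario = c("pitchfork", "saddle"),
                        c_grid = c(0, 2.5, 5, 7.5, 10, 12.5, 15),
                        c_merge = 10,
                        m_on = c(0.90, 1.06, 1.08),
                        m_off = c(1.18, 0.94, 0.88),
                        beta = 0.5, noise_sd = 0.04, w_off0 = 0.5,
                        n_colonies = 120L, illumination_sd = 0.15) {
  scenario <- match.arg(scenario)
  stopifnot(m_off[1] > m_on[1], beta > 0, noise_sd >= 0,
            w_off0 >= 0, w_off0 <= 1, n_colonies >= 1, c_merge > 0)
  structure(list(scenario = scenario, c_grid = c_grid, c_merge = c_merge,
                 m_on = m_on, m_off = m_off, beta = beta,
                 noise_sd = noise_sd, w_off0 = w_off0,
                 n_colonies = as.integer(n_colonies),
                 illumination_sd = illumination_sd),
            class = "color_model")
}

#' @rdname color_model
#' @param c concentration, µM.
#' @param model a `color_model`.
#' @return `color_truth_means` gives the scenario's true 'on'/'off' means
#'   and 'off' weight at `c` (before illumination scaling).
#' @export
color_truth_means <- function(c, model) {
  centre <- (model$m_on + model$m_off) / 2
  delta0 <- model$m_off - model$m_on
  if (model$scenario == "pitchfork") {
    shrink <- max(0, 1 - c / model$c_merge)^model$beta
    w_off <- model$w_off0
  } else {
    shrink <- 1
    w_off <- model$w_off0 * max(0, 1 - c / model$c_merge)
  }
  list(m_on = centre - delta0 * shrink / 2,
       m_off = centre + delta0 * shrink / 2,
       w_off = w_off, separation = sqrt(sum(delta0^2)) * shrink)
}

#' Generate synthetic colony-colour plates
#'
#' @param model a [color_model()].
#' @param seed RNG seed.
#' @return list with `colors` (data.frame `plate_id`, `concentration_uM`,
#'   `colony_id`, `R`, `G`, `B`), `truth` (per-colony true labels and the
#'   per-plate means/weights/illumination) and `model`.
#' @export
generate_colony_colors <- function(model = color_model(), seed = 1) {
  set.seed(seed)
  rows <- lab <- plates <- list()
  for (pi in seq_along(model$c_grid)) {
    cc <- model$c_grid[pi]
    tm <- color_truth_means(cc, model)
    illum <- exp(stats::rnorm(1, 0, model$illumination_sd))
    is_off <- stats::runif(model$n_colonies) < tm$w_off
    means <- ifelse(matrix(is_off, model$n_colonies, 3),
                    matrix(tm$m_off, model$n_colonies, 3, byrow = TRUE),
                    matrix(tm$m_on, model$n_colonies, 3, byrow = TRUE))
    rgb <- illum * (means + matrix(stats::rnorm(model$n_colonies * 3, 0,
                                                model$noise_sd),
                                   model$n_colonies, 3))
    rgb[rgb < 0] <- 0
    rows[[pi]] <- data.frame(
      plate_id = sprintf("plate_%02d", pi), concentration_uM = cc,
      colony_id = seq_len(model$n_colonies),
      R = rgb[, 1], G = rgb[, 2], B = rgb[, 3])
    lab[[pi]] <- data.frame(
      plate_id = sprintf("plate_%02d", pi), concentration_uM = cc,
      colony_id = seq_len(model$n_colonies),
      label = ifelse(is_off, "off", "on"))
    plates[[pi]] <- data.frame(
      plate_id = sprintf("plate_%02d", pi), concentration_uM = cc,
      w_off = tm$w_off, separation = tm$separation,
      illumination = illum)
  }
  truth <- list(labels = do.call(rbind, lab),
                plates = do.call(rbind, plates),
                scenario = model$scenario, c_merge = model$c_merge,
                seed = seed)
  list(colors = do.call(rbind, rows), truth = truth, model = model)
}

#' Generate a synthetic hysteresis scan with known scenario
#'
#' Replicate occupancies for both histories drawn around branch means whose
#' gap follows the chosen ground-truth profile: `merge` closes linearly to
#' zero at `I_star`, `jump` stays at the full gap below `I_star` and
#' collapses to zero there.
#'
#' @param truth `"merge"` or `"jump"`.
#' @param I_grid inhibitor levels.
#' @param I_star transition level.
#' @param gap_max branch gap far below threshold.
#' @param centre midpoint occupancy of the two branches.
#' @param noise_sd replicate-to-replicate occupancy SD.
#' @param n_rep replicates per history per level.
#' @param seed RNG seed.
#' @return a `hysteresis_scan` with attribute `truth`.
#' @export
generate_hysteresis_scan <- function(truth = c("merge", "jump"),
                                     I_grid = seq(0, 4, by = 0.5),
                                     I_star = 2, gap_max = 0.8,
                                     centre = 0.5, noise_sd = 0.1,
                                     n_rep = 50, seed = 1) {
  truth <- match.arg(truth)
  set.seed(seed)
  gap_of <- function(I) {
    if (truth == "merge") gap_max * max(0, 1 - I / I_star)
    else gap_max * (I < I_star)
  }
  rows <- list()
  for (I in I_grid) {
    gp <- gap_of(I)
    for (hist in c("HIGH_pregrown", "LOW_pregrown")) {
      mu <- centre + if (hist == "LOW_pregrown") gp / 2 else -gp / 2
      occ <- pmin(1, pmax(0, stats::rnorm(n_rep, mu, noise_sd)))
      rows[[length(rows) + 1]] <- data.frame(
        I = I, history = hist, replicate = seq_len(n_rep), occupancy = occ)
    }
  }
  scan <- new_hysteresis_scan(do.call(rbind, rows), I_grid, n_rep, seed)
  attr(scan, "truth") <- list(scenario = truth, I_star = I_star,
                              gap_max = gap_max)
  scan
}
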
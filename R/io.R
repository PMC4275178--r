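# Tabular text I/O ('#'-commented TSV dialects), the seed-derivation rule,
# and the two end-to-end synthetic reproductions.

#' Derive a stage seed from the global seed
#'
#' Documented, stable rule: the stage name's bytes are folded into the
#' global seed by repeated multiply-and-add modulo 2^31 - 1 (a Lehmer-style
#' mix), so every pipeline stage gets a distinct, reproducible seed below
#' 2^31.
#'
#' @param global_seed integer master seed.
#' @param stage character stage label.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(global_seed, stage) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(global_seed) %% m
  for (b in utf8ToInt(as.character(stage))) {
    h <- (h * 48271 + b) %% m
  }
  as.integer(max(1, h %% (m - 1)))
}

write_commented_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_commented_tsv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (!length(lineno)) stop("no data rows in ", path)
  df <- utils::read.table(text = raw[keep], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("header mismatch in ", path, ": missing ",
         paste(missing_cols, collapse = ", "))
  }
  for (cl in numeric_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad)) {
      stop("non-numeric value in column '", cl, "' at line ",
           lineno[bad[1] + 1], " of ", path)
    }
    df[[cl]] <- as.numeric(df[[cl]])
  }
  attr(df, "line_numbers") <- lineno[-1]
  df
}

#' Read and write 5-FOA plate-count tables
#'
#' Tab-separated with a header row and '#' comment lines; columns
#' `concentration_uM`, `history`, `N_YPD`, `d_YPD`, `N_FOA`, `d_FOA`.
#' Validation failures name the offending line.
#'
#' @param path file path.
#' @return data.frame of validated plate counts.
#' @export
read_counts_tsv <- function(path) {
  req <- c("concentration_uM", "history", "N_YPD", "d_YPD", "N_FOA", "d_FOA")
  df <- read_commented_tsv(path, req, setdiff(req, "history"))
  ln <- attr(df, "line_numbers")
  bad <- which(df$N_YPD %% 1 != 0 | df$N_FOA %% 1 != 0 |
                 df$N_YPD < 0 | df$N_FOA < 0)
  if (length(bad)) {
    stop("non-integer or negative colony count at line ", ln[bad[1]],
         " of ", path)
  }
  bad <- which(df$d_YPD <= 0 | df$d_YPD > 1 | df$d_FOA <= 0 | df$d_FOA > 1)
  if (length(bad)) {
    stop("dilution factor outside (0, 1] at line ", ln[bad[1]], " of ", path)
  }
  df$N_YPD <- as.integer(df$N_YPD)
  df$N_FOA <- as.integer(df$N_FOA)
  df[setdiff(names(df), "")]
}

#' @rdname read_counts_tsv
#' @param counts data.frame in the plate-count dialect.
#' @param comments character vector of '#' comment lines (metadata).
#' @export
write_counts_tsv <- function(counts, path, comments = character(0)) {
  req <- c("concentration_uM", "history", "N_YPD", "d_YPD", "N_FOA", "d_FOA")
  write_commented_tsv(counts[req], path, comments)
}

#' Read and write colony-colour tables
#'
#' Tab-separated with '#' comments; columns `plate_id`, `concentration_uM`,
#' `colony_id`, `R`, `G`, `B` (non-negative channel means).
#'
#' @param path file path.
#' @return data.frame of validated colony intensities.
#' @export
read_colors_tsv <- function(path) {
  req <- c("plate_id", "concentration_uM", "colony_id", "R", "G", "B")
  df <- read_commented_tsv(path, req, c("concentration_uM", "R", "G", "B"))
  ln <- attr(df, "line_numbers")
  bad <- which(df$R < 0 | df$G < 0 | df$B < 0)
  if (length(bad)) {
    stop("negative channel value at line ", ln[bad[1]], " of ", path)
  }
  df
}

#' @rdname read_colors_tsv
#' @param colors data.frame in the colony-colour dialect.
#' @param comments character vector of '#' comment lines (metadata).
#' @export
write_colors_tsv <- function(colors, path, comments = character(0)) {
  req <- c("plate_id", "concentration_uM", "colony_id", "R", "G", "B")
  write_commented_tsv(colors[req], path, comments)
}

#' Write a simulated trajectory as commented TSV
#'
#' Columns `time`, `occupancy`, `n_S`, `free_sir`; run metadata (seed,
#' inhibitor level, lattice size) in '#' comment lines.
#'
#' @param traj a `sir_trajectory`.
#' @param path file path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "sir_trajectory"))
  cfg <- traj$config
  write_commented_tsv(
    data.frame(time = traj$times, occupancy = traj$occupancy,
               n_S = traj$n_S, free_sir = traj$free_sir_series),
    path,
    comments = c(
      sprintf("seed=%d I=%g L=%d N_sir_total=%d", cfg$seed, cfg$I, cfg$L,
              cfg$N_sir_total),
      sprintf("window=[%d,%d] t_burn=%g t_record=%g",
              cfg$locus_window[1], cfg$locus_window[2], cfg$t_burn,
              cfg$t_record)))
}

#' End-to-end synthetic 5-FOA reproduction
#'
#' Generates synthetic plate counts under the default population model,
#' runs the survival pipeline (fractions, curves, convergence threshold,
#' floor subtraction, steepness) and reports recovery against the
#' generator's ground truth.
#'
#' @param seed global seed (stage seeds derived via [derive_seed()]).
#' @param model a [population_model()].
#' @param k_se convergence tolerance, see [convergence_threshold()].
#' @return list: `curves` (per-history), `threshold` (estimate and truth),
#'   `floor_estimate` (median apparent survival at the top concentration),
#'   `drop_per_decade`, `counts`, `truth`.
#' @export
pipeline_survival_demo <- function(seed = 1, model = population_model(),
                                   k_se = 2) {
  gen <- generate_plate_counts(model, seed = derive_seed(seed, "counts"))
  est <- survival_fraction(gen$counts)
  cur_low <- survival_curve(est, "LOW_pregrown", mutation_floor = model$mu)
  cur_high <- survival_curve(est, "HIGH_pregrown", mutation_floor = model$mu)
  thr <- convergence_threshold(cur_low, cur_high, k_se = k_se)
  cmax <- max(model$c_grid)
  floor_est <- stats::median(est$S_hat[est$concentration_uM == cmax])
  # steepness over the decade just below the estimated threshold
  c_hi <- if (!is.na(thr$threshold)) thr$threshold else cmax
  c_lo_target <- c_hi / 10
  grid <- model$c_grid[model$c_grid > 0]
  c_lo <- grid[which.min(abs(log10(grid) - log10(c_lo_target)))]
  drop <- if (c_lo < c_hi) {
    log_drop_per_decade(floor_subtract(cur_low), c_lo, c_hi)
  } else {
    NA_real_
  }
  list(curves = list(LOW_pregrown = cur_low, HIGH_pregrown = cur_high),
       threshold = list(estimate = thr$threshold,
                        uncertainty = thr$uncertainty,
                        truth = model$c_star, no_threshold = thr$no_threshold),
       floor_estimate = floor_est, floor_truth = model$mu,
       drop_per_decade = as.numeric(drop),
       drop_range = c(c_lo, c_hi),
       counts = gen$counts, truth = gen$truth)
}

#' End-to-end synthetic pigmentation reproduction
#'
#' Generates synthetic colony colours under the chosen scenario, traces the
#' projected 'on'/'off' branches and reports merge recovery against ground
#' truth.
#'
#' @param seed global seed.
#' @param scenario `"pitchfork"` or `"saddle"`.
#' @param model a [color_model()].
#' @return list: `trace` (a `branch_trace`), `merge` (estimate, truth,
#'   uncertainty), `merge_type`, `colors`, `truth`.
#' @export
pipeline_pigment_demo <- function(seed = 1, scenario = "pitchfork",
                                  model = color_model(scenario = scenario)) {
  gen <- generate_colony_colors(model, seed = derive_seed(seed, "colors"))
  tr <- trace_branches(gen$colors, seed = derive_seed(seed, "gmm"))
  list(trace = tr,
       merge = list(estimate = tr$merge_concentration,
                    uncertainty = tr$merge_uncertainty,
                    truth = model$c_merge),
       merge_type = tr$merge_type,
       colors = gen$colors, truth = gen$truth)
}
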
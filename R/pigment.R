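# ADE2 colony-pigmentation analysis: per-plate illumination normalization,
# 1- vs 2-component full-covariance Gaussian mixtures on the 3 RGB channel
# means, colony classification, and projection of branch means on the leading
# principal direction of on/off differences.

#' Normalize colony intensities to the plate's grand mean
#'
#' Divides every channel of every colony by the mean intensity over all
#' channels and colonies of the plate, compensating for plate-to-plate
#' illumination differences. After normalization the grand mean is exactly 1.
#'
#' @param rgb numeric matrix (colonies x 3 channels, order R, G, B) of
#'   non-negative mean intensities for one plate.
#' @return normalized matrix of the same shape.
#' @export
normalize_plate <- function(rgb) {
  rgb <- as.matrix(rgb)
  if (nrow(rgb) < 1 || ncol(rgb) != 3) {
    stop("rgb must be a (colonies x 3) matrix")
  }
  if (any(!is.finite(rgb)) || any(rgb < 0)) {
    stop("channel intensities must be finite and non-negative")
  }
  gm <- mean(rgb)
  if (gm <= 0) stop("validation error: zero grand mean")
  rgb / gm
}

# log multivariate-normal density via Cholesky; sigma must be symmetric PD
log_dmvnorm <- function(x, mean, sigma) {
  ch <- chol(sigma)
  d <- ncol(x)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

mixture_loglik <- function(x, means, covs, weights) {
  k <- length(weights)
  ll <- vapply(seq_len(k), function(j) {
    log(weights[j]) + log_dmvnorm(x, means[j, ], covs[[j]])
  }, numeric(nrow(x)))
  if (!is.matrix(ll)) ll <- matrix(ll, nrow = nrow(x))
  m <- apply(ll, 1, max)
  list(loglik = sum(m + log(rowSums(exp(ll - m)))),
       log_resp = ll - (m + log(rowSums(exp(ll - m)))))
}

# M-step from responsibilities, with ridge regularization against collapse
mixture_mstep <- function(x, resp, ridge_scale) {
  k <- ncol(resp)
  n <- nrow(x)
  regularized <- FALSE
  weights <- colSums(resp) / n
  means <- matrix(0, k, ncol(x))
  covs <- vector("list", k)
  for (j in seq_len(k)) {
    w <- resp[, j]
    sw <- sum(w)
    mu <- colSums(x * w) / sw
    xc <- sweep(x, 2, mu)
    sig <- crossprod(xc * sqrt(w / sw), xc / sqrt(sw) * sqrt(sw))
    sig <- crossprod(xc * sqrt(w)) / sw
    ok <- tryCatch({ chol(sig); TRUE }, error = function(e) FALSE)
    if (!ok || min(diag(sig)) < .Machine$double.eps) {
      sig <- sig + diag(ridge_scale, ncol(x))
      regularized <- TRUE
    }
    means[j, ] <- mu
    covs[[j]] <- sig
  }
  list(weights = weights, means = means, covs = covs,
       regularized = regularized)
}

#' Fit a 1- or 2-component full-covariance Gaussian mixture
#'
#' EM with seeded k-means-style initializations (each restart hard-assigns
#' every point to the nearest of `k` randomly chosen data points), run to a
#' log-likelihood change below `tol` or `max_iter` iterations; the best of
#' `n_restarts` starts is kept. The per-iteration log-likelihood trace is
#' retained so monotonicity (an EM guarantee) can be audited. Collapsing
#' covariances are ridged (1e-6 of the mean channel variance on the diagonal)
#' and flagged.
#'
#' @param x numeric matrix (colonies x 3) of normalized channel intensities.
#' @param k number of components, 1 or 2.
#' @param n_restarts random restarts for `k = 2` (the `k = 1` fit is closed
#'   form: sample mean and maximum-likelihood covariance).
#' @param seed RNG seed making the fit deterministic.
#' @param tol,max_iter EM convergence controls.
#' @return object of class `mixture_fit`: `k`, `means` (k x 3), `covs`,
#'   `weights`, `loglik`, `bic`, `n`, `loglik_trace`, `regularized`,
#'   `degenerate`.
#' @export
fit_mixture <- function(x, k, n_restarts = 10, seed = 1,
                        tol = 1e-8, max_iter = 500) {
  x <- as.matrix(x)
  stopifnot(k %in% c(1L, 2L))
  n <- nrow(x)
  if (n < 10 * k) {
    stop("validation error: need at least ", 10 * k, " colonies for k = ", k)
  }
  d <- ncol(x)
  degenerate <- all(apply(x, 2, function(v) diff(range(v)) == 0))
  ridge_scale <- 1e-6 * mean(apply(x, 2, stats::var))
  if (ridge_scale <= 0) ridge_scale <- 1e-12

  finish <- function(weights, means, covs, loglik, trace, regularized) {
    n_par <- if (k == 1) d + d * (d + 1) / 2 else
      2 * (d + d * (d + 1) / 2) + 1
    structure(list(k = k, weights = weights, means = means, covs = covs,
                   loglik = loglik, bic = -2 * loglik + n_par * log(n),
                   n = n, loglik_trace = trace, regularized = regularized,
                   degenerate = degenerate),
              class = "mixture_fit")
  }

  if (k == 1) {
    mu <- colMeans(x)
    sig <- crossprod(sweep(x, 2, mu)) / n
    regularized <- FALSE
    if (degenerate || inherits(tryCatch(chol(sig), error = identity),
                               "error")) {
      sig <- sig + diag(max(ridge_scale, 1e-12), d)
      regularized <- TRUE
    }
    ll <- mixture_loglik(x, matrix(mu, 1), list(sig), 1)$loglik
    return(finish(1, matrix(mu, 1), list(sig), ll, ll, regularized))
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # hard assignment to the nearest of k random data points; a soft floor
    # keeps both components alive when a centre draws few points
    centres <- x[sample.int(n, k), , drop = FALSE]
    d2 <- vapply(seq_len(k), function(j) {
      rowSums(sweep(x, 2, centres[j, ])^2)
    }, numeric(n))
    resp <- matrix(0.05, n, k)
    resp[cbind(seq_len(n), max.col(-d2))] <- 0.95
    resp <- resp / rowSums(resp)
    fit <- .cpp_gmm_em(x, resp, tol, max_iter, ridge_scale)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  covs <- lapply(seq_len(k), function(j) best$covs[, , j])
  finish(as.numeric(best$weights), best$means, covs, best$loglik,
         as.numeric(best$trace), best$regularized)
}

# Pure-R EM iteration (M step from responsibilities, then E step); the
# reference route used to cross-check the compiled EM in tests.
em_iterate_r <- function(x, resp, ridge_scale) {
  m <- mixture_mstep(x, resp, ridge_scale)
  e <- mixture_loglik(x, m$means, m$covs, m$weights)
  list(weights = m$weights, means = m$means, covs = m$covs,
       loglik = e$loglik, resp = exp(e$log_resp))
}

# Mahalanobis separation of the two component means under the
# weight-pooled within-component covariance
mixture_separation <- function(fit2) {
  stopifnot(fit2$k == 2)
  pooled <- fit2$weights[1] * fit2$covs[[1]] + fit2$weights[2] * fit2$covs[[2]]
  dmu <- fit2$means[1, ] - fit2$means[2, ]
  sqrt(drop(dmu %*% solve(pooled, dmu)))
}

#' Choose between the unimodal and bimodal description of a plate
#'
#' A plate is called bimodal only when the two-component fit is preferred by
#' BIC *and* the two component means are at least `sep_min` Mahalanobis units
#' apart under the pooled covariance *and* neither weight is negligible.
#' The separation guard is what rejects two-component fits that merely chase
#' the non-Gaussian shape of a unimodal cloud past the merge threshold.
#'
#' @param fit1,fit2 [fit_mixture()] results with `k = 1` and `k = 2` on the
#'   same data.
#' @param sep_min minimum Mahalanobis separation (default 2).
#' @param w_min minimum component weight (default 0.05).
#' @return `"bimodal"` or `"unimodal"`, with attribute `criteria`.
#' @export
select_model <- function(fit1, fit2, sep_min = 2, w_min = 0.05) {
  stopifnot(fit1$k == 1, fit2$k == 2, fit1$n == fit2$n)
  sep <- mixture_separation(fit2)
  crit <- c(bic = fit2$bic < fit1$bic,
            separation = sep >= sep_min,
            weight = min(fit2$weights) >= w_min)
  structure(if (all(crit)) "bimodal" else "unimodal",
            criteria = crit, separation = sep)
}

#' Classify colonies as silenced ('off') or expressing ('on')
#'
#' Maximum-posterior assignment under the two-component fit. The 'off'
#' (pigmented, *ADE2* silenced) component is the one with the larger red
#' channel mean; an exact red tie is broken by the larger projection on
#' `axis` (if supplied) and flagged.
#'
#' @param fit2 a `k = 2` [fit_mixture()].
#' @param x the colony matrix the fit was made on.
#' @param axis optional tie-break direction.
#' @return data.frame with `label` (`"off"`/`"on"`), `posterior_off`; the
#'   attribute `off_component` records which mixture component is 'off' and
#'   `red_tie` whether the tie-break fired.
#' @export
classify_colonies <- function(fit2, x, axis = NULL) {
  stopifnot(fit2$k == 2)
  x <- as.matrix(x)
  e <- mixture_loglik(x, fit2$means, fit2$covs, fit2$weights)
  post <- exp(e$log_resp)
  red_tie <- FALSE
  if (fit2$means[1, 1] != fit2$means[2, 1]) {
    off <- which.max(fit2$means[, 1])
  } else {
    red_tie <- TRUE
    if (is.null(axis)) axis <- c(1, 0, 0)
    off <- which.max(fit2$means %*% axis)
  }
  out <- data.frame(
    label = ifelse(post[, off] >= 0.5, "off", "on"),
    posterior_off = post[, off]
  )
  attr(out, "off_component") <- off
  attr(out, "red_tie") <- red_tie
  out
}

#' Leading principal direction of on/off mean differences
#'
#' The projection axis for branch plots: the leading principal component of
#' the set of ('off' mean - 'on' mean) difference vectors across
#' concentrations, taken about the origin (the differences themselves, not
#' their scatter around their centroid, carry the signal). The sign is fixed
#' so the mean projected difference is non-negative.
#'
#' @param diffs numeric matrix (concentrations x 3) of difference vectors;
#'   at least 2 rows.
#' @return unit 3-vector, with attribute `mean_zero` flagging a mean-zero
#'   difference set (orientation then arbitrary).
#' @export
projection_axis <- function(diffs) {
  diffs <- as.matrix(diffs)
  if (nrow(diffs) < 2) {
    stop("validation error: need difference vectors from >= 2 concentrations")
  }
  sv <- svd(diffs)
  axis <- sv$v[, 1]
  mp <- mean(diffs %*% axis)
  mean_zero <- abs(mp) < 1e-12
  if (mp < 0) axis <- -axis
  structure(axis / sqrt(sum(axis^2)), mean_zero = mean_zero)
}

#' Trace pigmentation branches across concentrations
#'
#' The full plate-series analysis: per plate, normalize, fit both mixture
#' models, select; then build the projection axis from the bimodal plates'
#' on/off mean differences, project all selected means on it, and locate the
#' merge as the first concentration of the final unimodal run. The transition
#' is additionally typed by how bimodality is lost: `"mean_merging"` when the
#' projected separation has collapsed (last-bimodal gap at most
#' `merge_ratio` of the maximum gap, the continuous pitchfork-like signature)
#' versus `"weight_vanishing"` when the branches stay separated but the 'off'
#' component's weight dies out (the saddle-node-like signature).
#'
#' @param colors data.frame with columns `plate_id`, `concentration_uM`,
#'   `colony_id`, `R`, `G`, `B`.
#' @param sep_min,w_min selection thresholds, see [select_model()].
#' @param n_restarts,seed EM controls; per-plate seeds are derived from
#'   `seed` by [derive_seed()].
#' @param merge_ratio gap-ratio boundary between the two merge types.
#' @return object of class `branch_trace`: per-concentration table
#'   (`concentration_uM`, `modality`, `proj_on`, `proj_off`, `proj_single`,
#'   `w_off`, `gap`, `pooled_sd`), `axis`, `merge_concentration`,
#'   `merge_uncertainty`, `merge_type`, `flags`.
#' @export
trace_branches <- function(colors, sep_min = 2, w_min = 0.05,
                           n_restarts = 10, seed = 1, merge_ratio = 0.6) {
  required <- c("plate_id", "concentration_uM", "R", "G", "B")
  if (!all(required %in% names(colors))) {
    stop("missing columns: ",
         paste(setdiff(required, names(colors)), collapse = ", "))
  }
  concs <- sort(unique(colors$concentration_uM))
  if (length(concs) < 2) stop("need plates spanning >= 2 concentrations")

  per_conc <- lapply(concs, function(cc) {
    rows <- colors[colors$concentration_uM == cc, , drop = FALSE]
    # normalization is per plate; plates at one concentration are pooled
    # after each is normalized to its own grand mean
    xs <- lapply(split(rows, rows$plate_id), function(p) {
      normalize_plate(as.matrix(p[, c("R", "G", "B")]))
    })
    x <- do.call(rbind, xs)
    sd_plate <- derive_seed(seed, paste0("plate_", cc))
    f1 <- fit_mixture(x, 1)
    f2 <- fit_mixture(x, 2, n_restarts = n_restarts, seed = sd_plate)
    sel <- select_model(f1, f2, sep_min = sep_min, w_min = w_min)
    list(conc = cc, x = x, fit1 = f1, fit2 = f2, modality = as.character(sel))
  })

  modality <- vapply(per_conc, `[[`, character(1), "modality")
  bimodal_idx <- which(modality == "bimodal")

  flags <- character(0)
  # identify 'off' (redder) component per bimodal plate and collect diffs
  comp_off <- integer(length(per_conc))
  for (i in bimodal_idx) {
    comp_off[i] <- which.max(per_conc[[i]]$fit2$means[, 1])
  }
  if (length(bimodal_idx) >= 2) {
    diffs <- t(vapply(bimodal_idx, function(i) {
      f <- per_conc[[i]]$fit2
      f$means[comp_off[i], ] - f$means[3 - comp_off[i], ]
    }, numeric(3)))
    axis <- projection_axis(diffs)
  } else {
    axis <- structure(c(1, 0, 0), mean_zero = FALSE)
    if (length(bimodal_idx) > 0) {
      flags <- c(flags, "axis_default_single_bimodal_plate")
    }
  }

  tab <- do.call(rbind, lapply(seq_along(per_conc), function(i) {
    p <- per_conc[[i]]
    if (p$modality == "bimodal") {
      f <- p$fit2
      off <- comp_off[i]
      on <- 3 - off
      pooled <- f$weights[1] * f$covs[[1]] + f$weights[2] * f$covs[[2]]
      data.frame(concentration_uM = p$conc, modality = "bimodal",
                 proj_on = drop(f$means[on, ] %*% axis),
                 proj_off = drop(f$means[off, ] %*% axis),
                 proj_single = NA_real_, w_off = f$weights[off],
                 gap = drop((f$means[off, ] - f$means[on, ]) %*% axis),
                 pooled_sd = sqrt(drop(t(axis) %*% pooled %*% axis)))
    } else {
      f <- p$fit1
      data.frame(concentration_uM = p$conc, modality = "unimodal",
                 proj_on = NA_real_, proj_off = NA_real_,
                 proj_single = drop(f$means[1, ] %*% axis),
                 w_off = NA_real_, gap = NA_real_,
                 pooled_sd = sqrt(drop(t(axis) %*% f$covs[[1]] %*% axis)))
    }
  }))

  uni <- modality == "unimodal"
  if (!any(uni)) {
    merge_c <- NA_real_
    merge_unc <- NA_real_
    flags <- c(flags, "no_unimodal_plate")
  } else {
    # first entry of the final unimodal run
    run_start <- max(which(!uni), 0) + 1
    if (run_start > length(uni)) {
      # bimodal reappears above a unimodal plate only if pattern non-monotone
    }
    final_run <- length(uni) + 1 - rev(cumprod(rev(uni)))  # not used; clarity
    idx <- if (all(uni)) 1L else max(which(!uni)) + 1L
    if (idx > length(concs)) {
      merge_c <- NA_real_
      merge_unc <- NA_real_
      flags <- c(flags, "no_unimodal_plate_above_last_bimodal")
    } else {
      merge_c <- concs[idx]
      merge_unc <- if (idx == 1) NA_real_ else concs[idx] - concs[idx - 1]
    }
    if (any(uni[seq_len(max(c(0, which(!uni))))])) {
      flags <- c(flags, "non_monotone_modality_pattern")
    }
  }

  if (length(bimodal_idx) == 0) {
    merge_type <- "monostable_everywhere"
  } else if (!any(uni)) {
    merge_type <- "no_merge_observed"
  } else {
    gaps <- tab$gap[bimodal_idx]
    merge_type <- if (gaps[length(gaps)] <= merge_ratio * max(gaps)) {
      "mean_merging"
    } else {
      "weight_vanishing"
    }
  }

  structure(list(table = tab, axis = axis, merge_concentration = merge_c,
                 merge_uncertainty = merge_unc, merge_type = merge_type,
                 flags = flags),
            class = "branch_trace")
}

#' @export
print.branch_trace <- function(x, ...) {
  cat("Pigmentation branch trace\n")
  print(x$table, row.names = FALSE)
  cat("merge at ", x$merge_concentration, " uM (+/- ", x$merge_uncertainty,
      "), type: ", x$merge_type, "\n", sep = "")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
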
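# Penalized additive modelling of relative richness. Smooth terms are thin
# plate regression splines with a maximum basis dimension of 10 (superfluous
# knots are penalized away rather than selected), smoothing parameters chosen
# by GCV; the 2-D spatial term s(X, Y) is fitted and evaluated on ocean cells
# only, which takes over the boundary-limiting role of a soap-film smoother.
# Candidate models are ranked by AIC computed with effective degrees of
# freedom, and terms are retained under the delta-AIC > 2 improvement rule.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from an ordinary linear
#' regression (with intercept) of covariate j on the remaining covariates.
#' A perfectly collinear covariate is reported as `Inf` rather than raising
#' an error. Values below 3 are conventionally read as absence of
#' problematic multicollinearity.
#'
#' @param design A data frame.
#' @param covariates Character vector of numeric column names (>= 2).
#' @return Tibble: `covariate`, `vif`.
#' @export
vif <- function(design, covariates) {
  stopifnot(all(covariates %in% names(design)), length(covariates) >= 2,
            nrow(design) >= 3)
  out <- purrr::map_dbl(covariates, function(v) {
    others <- setdiff(covariates, v)
    f <- stats::reformulate(others, response = v)
    # a perfectly collinear covariate triggers a harmless perfect-fit
    # warning on its auxiliary regression; the Inf VIF is the answer
    r2 <- suppressWarnings(summary(stats::lm(f, data = design))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  tibble::tibble(covariate = covariates, vif = out)
}

# canonical model terms: key -> smooth construct and display label
am_term_defs <- function(k = 10, k_xy = 30) {
  list(
    sst  = list(label = "SST",  spec = sprintf("s(sst_mean, k = %d, bs = 'tp')", k)),
    chl  = list(label = "CHL",  spec = sprintf("s(chl_log10, k = %d, bs = 'tp')", k)),
    xy   = list(label = "XY",   spec = sprintf("s(x, y, k = %d, bs = 'tp')", k_xy)),
    null = list(label = "null", spec = sprintf("s(null_usage, k = %d, bs = 'tp')", k))
  )
}

#' Fit a penalized additive model
#'
#' Thin-wrapper additive-model fit: 1-D penalized thin plate regression
#' splines (basis dimension `k`, i.e. a maximum of `k` knots), an optional
#' 2-D spatial smooth, and optional linear terms, with smoothing parameters
#' chosen by GCV. The engine is `mgcv::gam()`.
#'
#' @param data Data frame with the response and covariates; no missing
#'   values.
#' @param response Response column name.
#' @param smooth_1d Character vector of columns to model as 1-D smooths.
#' @param smooth_2d Optional length-2 character vector (e.g. `c("x", "y")`)
#'   for one 2-D thin plate smooth.
#' @param linear Optional character vector of linear-term columns.
#' @param k Basis dimension for 1-D smooths (default 10).
#' @param k_2d Basis dimension for the 2-D smooth (default 30).
#' @param family Response family (default `gaussian()`; `poisson()` is the
#'   natural alternative for small-count richness).
#' @param method Smoothing-parameter criterion (default `"GCV.Cp"`).
#' @param ... Passed to `mgcv::gam()` (e.g. fixed `sp`).
#' @return A `hexrich_am` fit: the underlying `gam` object plus term
#'   bookkeeping; supports [tidy()], [glance()], [smooth_peak()],
#'   [residual_variogram()].
#' @export
fit_penalized_am <- function(data, response, smooth_1d = character(),
                             smooth_2d = NULL, linear = character(),
                             k = 10, k_2d = 30, family = stats::gaussian(),
                             method = "GCV.Cp", ...) {
  cols <- c(response, smooth_1d, smooth_2d, linear)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(data[cols])))) {
    stop("non-finite values in model columns")
  }
  parts <- c(
    sprintf("s(%s, k = %d, bs = 'tp')", smooth_1d, k),
    if (!is.null(smooth_2d)) {
      sprintf("s(%s, %s, k = %d, bs = 'tp')", smooth_2d[1], smooth_2d[2], k_2d)
    },
    linear
  )
  if (length(parts) == 0) parts <- "1"
  f <- stats::as.formula(paste(response, "~", paste(parts, collapse = " + ")))
  g <- mgcv::gam(f, data = data, family = family, method = method, ...)
  new_hexrich_am(g, response = response, data = data)
}

new_hexrich_am <- function(gam_fit, response, data, term_keys = NULL) {
  structure(
    list(
      gam = gam_fit,
      response = response,
      data = data,
      term_keys = term_keys,
      edf_total = sum(gam_fit$edf),
      aic = stats::AIC(gam_fit),
      adj_r2 = summary(gam_fit)$r.sq
    ),
    class = "hexrich_am"
  )
}

#' @export
print.hexrich_am <- function(x, ...) {
  cat(sprintf(
    "hexrich_am: %s ~ %s\n  n = %d, total edf = %.2f, AIC = %.2f, adj R2 = %.3f\n",
    x$response, paste(attr(stats::terms(x$gam), "term.labels"), collapse = " + "),
    nrow(x$data), x$edf_total, x$aic, x$adj_r2
  ))
  invisible(x)
}

#' Fit the richness additive model on a design table
#'
#' The study's global model: relative richness against smooths of SST,
#' log10 CHL, null usage, and a 2-D spatial smooth of the projected cell
#' coordinates, any subset selectable by term key.
#'
#' @param design A [cell_covariates()]-style design table joined with a
#'   `richness` column; ocean cells, no missing values.
#' @param terms Term keys among `"sst"`, `"chl"`, `"xy"`, `"null"`.
#' @param k,k_xy Basis dimensions (defaults 10 and 30).
#' @param family Response family (default Gaussian/identity, matching
#'   adjusted-R2 reporting on richness counts).
#' @param method Smoothing criterion (default `"REML"`; `"GCV.Cp"`
#'   available). REML with the double penalty (`select = TRUE`) shrinks
#'   weakly supported components and stabilises the partial effects of
#'   covariates that are themselves smooth functions of space.
#' @param select Use mgcv's double (null-space) penalty (default TRUE).
#' @param ... Passed to `mgcv::gam()`.
#' @return A `hexrich_am` fit.
#' @export
fit_richness_gam <- function(design, terms = c("sst", "chl", "xy", "null"),
                             k = 10, k_xy = 30, family = stats::gaussian(),
                             method = "REML", select = TRUE, ...) {
  defs <- am_term_defs(k = k, k_xy = k_xy)
  bad <- setdiff(terms, names(defs))
  if (length(bad) > 0) stop("unknown term key(s): ", paste(bad, collapse = ", "))
  if (length(terms) == 0) stop("need at least one term")
  need <- c("richness",
            if ("sst" %in% terms) "sst_mean",
            if ("chl" %in% terms) "chl_log10",
            if ("null" %in% terms) "null_usage",
            if ("xy" %in% terms) c("x", "y"))
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    stop("design table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(design) < 50) stop("need >= 50 rows to fit the richness model")
  specs <- vapply(defs[terms], `[[`, character(1), "spec")
  f <- stats::as.formula(paste("richness ~", paste(specs, collapse = " + ")))
  g <- mgcv::gam(f, data = design, family = family, method = method,
                 select = select, ...)
  new_hexrich_am(g, response = "richness", data = design, term_keys = terms)
}

#' All-subsets AIC model selection over the candidate terms
#'
#' Fits every non-empty subset of the candidate term set, ranks by AIC and
#' reports models within `report_within` of the best. The retained model is
#' the most parsimonious (lowest total d.f.) model whose AIC is within
#' `delta_retain` of the lowest: a term is kept only when its inclusion
#' improves AIC by more than `delta_retain`. AIC ties below 1e-6 rank the
#' smaller-d.f. model first.
#'
#' @param design Design table as for [fit_richness_gam()].
#' @param candidates Candidate term keys (default all four).
#' @param delta_retain Retention threshold (default 2).
#' @param report_within Reporting window in delta-AIC (default 6).
#' @param all_subsets Fit every non-empty subset of `candidates` (default);
#'   `FALSE` fits the full candidate model only.
#' @param ... Passed to [fit_richness_gam()].
#' @return A `model_table` tibble: `rank`, `terms`, `df`, `aic`,
#'   `delta_aic`, `retained`, restricted to the reporting window; the full
#'   ranking is in attribute `full_table`, the best and retained fits in
#'   attributes `best_fit` / `retained_fit`.
#' @export
select_model <- function(design, candidates = c("sst", "chl", "xy", "null"),
                         delta_retain = 2, report_within = 6,
                         all_subsets = TRUE, ...) {
  stopifnot(length(candidates) >= 1)
  defs <- am_term_defs()
  subsets <- if (all_subsets) {
    purrr::map(
      seq_len(2^length(candidates) - 1),
      function(m) candidates[bitwAnd(m, 2^(seq_along(candidates) - 1)) > 0]
    )
  } else {
    list(candidates)
  }
  fits <- purrr::map(subsets, function(tt) fit_richness_gam(design, terms = tt, ...))
  tab <- tibble::tibble(
    term_keys = subsets,
    terms = purrr::map_chr(subsets, function(tt) {
      paste(vapply(defs[tt], `[[`, character(1), "label"), collapse = " + ")
    }),
    n_terms = lengths(subsets),
    df = purrr::map_dbl(fits, "edf_total"),
    aic = purrr::map_dbl(fits, "aic")
  )
  ord <- order(round(tab$aic / 1e-6) * 1e-6, tab$df)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$rank <- seq_len(nrow(tab))
  tab$delta_aic <- tab$aic - tab$aic[1]
  within_retain <- which(tab$delta_aic <= delta_retain)
  retained_idx <- within_retain[order(tab$df[within_retain])][1]
  tab$retained <- seq_len(nrow(tab)) == retained_idx
  out <- tab[tab$delta_aic <= report_within,
             c("rank", "terms", "n_terms", "df", "aic", "delta_aic", "retained")]
  attr(out, "full_table") <- tab[, c("rank", "terms", "n_terms", "df",
                                     "aic", "delta_aic", "retained")]
  attr(out, "term_keys") <- tab$term_keys
  attr(out, "best_fit") <- fits[[1]]
  attr(out, "retained_fit") <- fits[[retained_idx]]
  class(out) <- c("model_table", class(out))
  out
}

#' Location of the optimum of a fitted 1-D smooth
#'
#' Evaluates the centred smooth of `term` on a dense grid over the observed
#' covariate range and locates the response optimum: the highest interior
#' mode (turning point) of the estimated effect. An environmental optimum
#' is a turning point by definition; monotone runs into the extremes of the
#' covariate range — where data are sparse and concurvity with the spatial
#' smooth leaves the partial effect weakly determined — are not read as
#' optima. When the effect is monotone over the whole observed range (no
#' interior mode exists) the boundary argmax is returned. Also returns the
#' contiguous interval of grid points around the peak whose estimate lies
#' within 2 pointwise standard errors of it — the covariate band the model
#' cannot distinguish from the optimum.
#'
#' @param fit A `hexrich_am`.
#' @param term Covariate column name of a fitted 1-D smooth (e.g.
#'   `"sst_mean"`).
#' @param n_eval Grid size (default 200).
#' @return A `smooth_peak` list: `term`, `peak`, `lower`, `upper`,
#'   `interior` (whether the peak is an interior mode), and the evaluation
#'   `grid` tibble (`value`, `est`, `se`).
#' @export
smooth_peak <- function(fit, term, n_eval = 200) {
  stopifnot(inherits(fit, "hexrich_am"))
  labels <- vapply(fit$gam$smooth, function(s) s$label, character(1))
  target <- which(vapply(fit$gam$smooth, function(s) {
    length(s$term) == 1 && s$term == term
  }, logical(1)))
  if (length(target) != 1) {
    stop("'", term, "' is not a fitted 1-D smooth of this model")
  }
  rng <- range(fit$data[[term]])
  grid_vals <- seq(rng[1], rng[2], length.out = n_eval)
  nd <- fit$data[rep(1, n_eval), , drop = FALSE]
  num <- vapply(nd, is.numeric, logical(1))
  nd[num] <- lapply(fit$data[num], function(col) rep(stats::median(col), n_eval))
  nd[[term]] <- grid_vals
  pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep(labels[target], colnames(pr$fit), fixed = TRUE)[1]
  est <- pr$fit[, col]
  se <- pr$se.fit[, col]
  # highest interior mode; boundary argmax only for a monotone effect
  interior <- which(est[2:(n_eval - 1)] >= est[1:(n_eval - 2)] &
                      est[2:(n_eval - 1)] >= est[3:n_eval]) + 1L
  i_max <- if (length(interior) > 0) {
    interior[which.max(est[interior])]
  } else {
    which.max(est)
  }
  ok <- est >= est[i_max] - 2 * se
  # contiguous run containing the peak
  lo <- i_max
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i_max
  while (hi < n_eval && ok[hi + 1]) hi <- hi + 1
  structure(
    list(
      term = term,
      peak = grid_vals[i_max],
      lower = grid_vals[lo],
      upper = grid_vals[hi],
      interior = length(interior) > 0,
      grid = tibble::tibble(value = grid_vals, est = est, se = se)
    ),
    class = "smooth_peak"
  )
}

#' @export
print.smooth_peak <- function(x, ...) {
  cat(sprintf(
    "smooth_peak of %s: argmax %.3f, 2-s.e. interval [%.3f, %.3f]\n",
    x$term, x$peak, x$lower, x$upper
  ))
  invisible(x)
}

#' Empirical residual variogram with a permutation envelope
#'
#' Semivariance `gamma(h) = mean of 0.5 (r_i - r_j)^2` over point pairs in
#' distance bins up to half the maximum pairwise distance, with a Monte
#' Carlo null envelope (per-bin min/max over `n_perm` random permutations of
#' residuals across locations). Residuals inside the envelope in (almost)
#' every bin indicate no detectable spatial autocorrelation. For large n, a
#' random subset of `max_points` locations is used (all pairwise work is
#' O(n^2)).
#'
#' @param residuals Numeric residual vector.
#' @param x,y Projected coordinates (km), same length as `residuals`.
#' @param n_bins Number of distance bins (default 15).
#' @param n_perm Number of permutations (default 99).
#' @param max_points Subsample cap (default 1500).
#' @param seed Integer seed for the permutations/subsample.
#' @return A `variogram` tibble: `dist_mid`, `n_pairs`, `gamma`, `env_lo`,
#'   `env_hi`, with attributes `n_points` and `n_perm`.
#' @export
residual_variogram <- function(residuals, x, y, n_bins = 15, n_perm = 99,
                               max_points = 1500, seed = 1) {
  n <- length(residuals)
  stopifnot(length(x) == n, length(y) == n, n >= 30)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n > max_points) {
    idx <- sample.int(n, max_points)
    residuals <- residuals[idx]
    x <- x[idx]
    y <- y[idx]
    n <- max_points
  }
  d <- stats::dist(cbind(x, y))
  h_max <- max(d) / 2
  breaks <- seq(0, h_max, length.out = n_bins + 1)
  bin <- cut(as.vector(d), breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  keep <- !is.na(bin)
  bin <- bin[keep]
  gamma_of <- function(r) {
    sq <- 0.5 * as.vector(stats::dist(r))^2
    vapply(seq_len(n_bins), function(b) {
      v <- sq[keep][bin == b]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  gamma_obs <- gamma_of(residuals)
  n_pairs <- tabulate(bin, nbins = n_bins)
  perm <- vapply(seq_len(n_perm), function(i) gamma_of(sample(residuals)),
                 numeric(n_bins))
  out <- tibble::tibble(
    dist_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    n_pairs = n_pairs,
    gamma = gamma_obs,
    env_lo = apply(perm, 1, min, na.rm = TRUE),
    env_hi = apply(perm, 1, max, na.rm = TRUE)
  )
  attr(out, "n_points") <- n
  attr(out, "n_perm") <- n_perm
  class(out) <- c("variogram", class(out))
  out
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
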
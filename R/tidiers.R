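# broom-style tidiers for fitted additive models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted additive model
#'
#' One row per smooth term with effective degrees of freedom, reference
#' d.f., F statistic and approximate p-value.
#'
#' @param x A `hexrich_am`.
#' @param ... Unused.
#' @return A tibble: `term`, `edf`, `ref_df`, `statistic`, `p.value`.
#' @method tidy hexrich_am
#' @export
tidy.hexrich_am <- function(x, ...) {
  s <- summary(x$gam)
  st <- s$s.table
  if (is.null(st) || nrow(st) == 0) {
    return(tibble::tibble(
      term = character(0), edf = numeric(0), ref_df = numeric(0),
      statistic = numeric(0), p.value = numeric(0)
    ))
  }
  tibble::tibble(
    term = rownames(st),
    edf = st[, "edf"],
    ref_df = st[, "Ref.df"],
    statistic = st[, "F"],
    p.value = st[, "p-value"]
  )
}

#' Model-level summary of a fitted additive model
#'
#' @param x A `hexrich_am`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `df`, `aic`, `adj_r2`, `deviance_expl`.
#' @method glance hexrich_am
#' @export
glance.hexrich_am <- function(x, ...) {
  s <- summary(x$gam)
  tibble::tibble(
    nobs = nrow(x$data),
    df = x$edf_total,
    aic = x$aic,
    adj_r2 = x$adj_r2,
    deviance_expl = s$dev.expl
  )
}
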
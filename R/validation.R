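#' Rank regression of risk scores against observed N losses
#'
#' Observed N losses across land uses are right-skewed and clustered, so
#' both risk scores and observed losses are converted to ranks (rank 1 =
#' greatest; ties receive average ranks) before an ordinary least-squares
#' regression of observation rank on risk rank. The fit carries 95 \%
#' confidence and prediction bands (pointwise t-based) and the count of
#' points falling outside the prediction band.
#'
#' The raw-scale OLS slope of loss on risk is also retained
#' (`slope_raw`): ranks are invariant to rescaling, so any systematic
#' attenuation of the index for a land use is only visible on the raw
#' scale, and [scale_factor()] consumes this slope.
#'
#' @param risks numeric vector of risk scores.
#' @param observations either a numeric vector of N losses
#'   (kg N ha^-1 yr^-1) or a data.frame with a `loss` column (the
#'   observation-record layout).
#' @param level confidence level for the bands.
#' @return object of class `rank_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `n_outside_pi`, `degenerate`,
#'   `slope_raw`, `level`, and `data` (ranks, fitted values and band
#'   limits per point).
#' @export
rank_regression <- function(risks, observations, level = 0.95) {
  obs <- if (is.data.frame(observations)) observations$loss else observations
  if (length(risks) != length(obs)) {
    stop("risks and observations must be paired (same length)")
  }
  n <- length(risks)
  if (n < 3) stop("rank regression needs at least 3 pairs")
  if (any(!is.finite(risks)) || any(!is.finite(obs))) {
    stop("risks and observations must be finite")
  }
  # rank 1 = greatest
  rx <- rank(-risks, ties.method = "average")
  ry <- rank(-obs, ties.method = "average")
  degenerate <- stats::var(rx) == 0 || stats::var(ry) == 0
  slope_raw <- if (stats::var(risks) > 0) {
    stats::cov(risks, obs) / stats::var(risks)
  } else NA_real_
  if (degenerate) {
    out <- list(slope = NA_real_, intercept = NA_real_, r_squared = 0,
                p_value = NA_real_, n = n, n_outside_pi = 0L,
                degenerate = TRUE, slope_raw = slope_raw, level = level,
                data = data.frame(risk_rank = rx, obs_rank = ry))
    class(out) <- "rank_regression"
    return(out)
  }
  fit <- stats::lm(ry ~ rx)
  # a noiseless monotone pairing is a legitimate input: silence the
  # "essentially perfect fit" advisory it triggers in summary.lm
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ci <- stats::predict(fit, interval = "confidence", level = level)
  pi <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level)
  )
  # numeric guard: an exact fit has ~1e-14 residuals and a zero-width band;
  # a point is only "outside" when beyond the band by more than rank noise
  eps <- 1e-8 * max(1, diff(range(ry)))
  outside <- ry < pi[, "lwr"] - eps | ry > pi[, "upr"] + eps
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = n,
    n_outside_pi = sum(outside),
    degenerate = FALSE,
    slope_raw = slope_raw,
    level = level,
    data = data.frame(risk = risks, loss = obs, risk_rank = rx, obs_rank = ry,
                      fitted = ci[, "fit"], conf_lwr = ci[, "lwr"],
                      conf_upr = ci[, "upr"], pred_lwr = pi[, "lwr"],
                      pred_upr = pi[, "upr"], outside_pi = outside),
    fit = fit
  )
  class(out) <- "rank_regression"
  out
}

#' @export
print.rank_regression <- function(x, ...) {
  cat("Rank regression of observed N loss on risk score (rank 1 = greatest)\n")
  if (x$degenerate) {
    cat("  degenerate fit: zero variance in ranks; r2 reported as 0\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d, slope = %.3f, intercept = %.3f\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  r2 = %.3f, p = %.3g\n", x$r_squared, x$p_value))
  cat(sprintf("  %d of %d points outside the %.0f%% prediction band\n",
              x$n_outside_pi, x$n, 100 * x$level))
  invisible(x)
}

#' @export
summary.rank_regression <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    cat(sprintf("  raw-scale slope of risk on loss: %.4f\n", object$slope_raw))
  }
  invisible(object)
}

#' @export
coef.rank_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Plot a rank regression with confidence and prediction bands
#'
#' @param x a [rank_regression()] object.
#' @param ... passed to [plot()].
#' @export
plot.rank_regression <- function(x, ...) {
  if (x$degenerate) {
    warning("degenerate fit; nothing to plot")
    return(invisible(x))
  }
  d <- x$data[order(x$data$risk_rank), ]
  graphics::plot(d$risk_rank, d$obs_rank,
                 xlab = "Rank of N loss risk (1 = greatest)",
                 ylab = "Rank of observed N loss (1 = greatest)",
                 pch = ifelse(d$outside_pi, 17, 19), ...)
  graphics::lines(d$risk_rank, d$fitted, lwd = 2)
  graphics::lines(d$risk_rank, d$conf_lwr, lty = 2)
  graphics::lines(d$risk_rank, d$conf_upr, lty = 2)
  graphics::lines(d$risk_rank, d$pred_lwr, lty = 3)
  graphics::lines(d$risk_rank, d$pred_upr, lty = 3)
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("r2 = %.2f, p = %.2g", x$r_squared,
                                      x$p_value),
                              "95% confidence", "95% prediction"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1))
  invisible(x)
}

#' Source sensitivity of the risk index
#'
#' Rescales one source category at a time by each factor (default 50 \% and
#' 150 \%), recomputes the index, and reports the ratio of the perturbed
#' total to the baseline total, split by pathway. A ratio of 1 means the
#' score is insensitive to that source -- including the case where the
#' source is simply absent.
#'
#' @param sources a [monthly_sources()] table (one block) or a data.frame of
#'   block-month rows carrying a `block_id` column and the source columns.
#' @param transport data.frame with `month`, `leach_risk`, `runoff_risk`
#'   (and `block_id` when `sources` spans blocks), aligned to `sources`.
#' @param factors scaling factors to apply to each source category.
#' @param literal_eq2 passed to [runoff_index()].
#' @return data.frame with columns `source`, `factor`, `leach_ratio`,
#'   `runoff_ratio`, `total_ratio`. Ratios are `NA` (flagged via the
#'   `undefined` column) when the corresponding baseline total is zero.
#' @export
sensitivity_analysis <- function(sources, transport, factors = c(0.5, 1.5),
                                 literal_eq2 = FALSE) {
  .check_sources(sources)
  if ("block_id" %in% names(sources)) {
    key_s <- paste(sources$block_id, sources$month)
    key_t <- paste(transport$block_id, transport$month)
  } else {
    key_s <- as.character(sources$month)
    key_t <- as.character(transport$month)
  }
  idx <- match(key_s, key_t)
  if (anyNA(idx)) stop("transport risks missing for some source rows")
  lr <- transport$leach_risk[idx]
  rr <- transport$runoff_risk[idx]
  totals <- function(src) {
    li <- leaching_index(src, lr)
    ri <- runoff_index(src, rr, leach_risk = lr, literal_eq2 = literal_eq2)
    c(leach = sum(li), runoff = sum(ri), total = sum(li) + sum(ri))
  }
  base <- totals(sources)
  grid <- expand.grid(source = .source_categories, factor = factors,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    src <- sources
    src[[grid$source[i]]] <- src[[grid$source[i]]] * grid$factor[i]
    tot <- totals(src)
    ratio <- ifelse(base > 0, tot / base, NA_real_)
    data.frame(source = grid$source[i], factor = grid$factor[i],
               leach_ratio = ratio[["leach"]],
               runoff_ratio = ratio[["runoff"]],
               total_ratio = ratio[["total"]],
               undefined = base[["total"]] <= 0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Land-use scale factor relative to a reference fit
#'
#' Diagnoses a systematic attenuation of the risk index for one land use:
#' the focal land use's raw-scale slope of observed loss per unit risk,
#' relative to the reference slope (equivalently, how many times lower the
#' focal risk-versus-loss slope runs than the reference). A focal cohort
#' whose index runs k times too low yields a scale factor of about k.
#' The loss-on-risk orientation keeps observation noise in the dependent
#' variable, so the ratio is not attenuated by noisy losses. Uncertainty
#' comes from a seeded bootstrap over the focal pairs (the reference slope
#' is held fixed).
#'
#' @param risks risk scores for the focal land use.
#' @param observations observed losses paired with `risks` (vector or
#'   data.frame with `loss`).
#' @param reference a [rank_regression()] fit of the reference cohort
#'   (its `slope_raw` is used), or a list with elements `risks` and
#'   `observations` from which the reference slope is computed directly.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level of the percentile interval.
#' @param seed optional integer seed for the bootstrap.
#' @return list of class `scale_factor`: `estimate`, `ci` (percentile
#'   interval), `n`, `n_boot`, `degenerate`.
#' @export
scale_factor <- function(risks, observations, reference, n_boot = 1000,
                         conf = 0.95, seed = NULL) {
  obs <- if (is.data.frame(observations)) observations$loss else observations
  if (length(risks) != length(obs)) stop("risks and observations must be paired")
  n <- length(risks)
  if (n < 3) stop("scale factor needs at least 3 focal pairs")
  raw_slope <- function(r, o) stats::cov(r, o) / stats::var(r)
  ref_slope <- if (inherits(reference, "rank_regression")) {
    reference$slope_raw
  } else {
    ro <- if (is.data.frame(reference$observations)) {
      reference$observations$loss
    } else reference$observations
    raw_slope(reference$risks, ro)
  }
  focal <- raw_slope(risks, obs)
  if (!is.finite(focal) || !is.finite(ref_slope) || ref_slope == 0) {
    return(structure(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                          n = n, n_boot = n_boot, degenerate = TRUE),
                     class = "scale_factor"))
  }
  est <- focal / ref_slope
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    s <- raw_slope(risks[j], obs[j])
    if (is.finite(s)) s / ref_slope else NA_real_
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(estimate = est, ci = ci, n = n, n_boot = n_boot,
                 conf = conf, degenerate = FALSE, boot = boot),
            class = "scale_factor")
}

#' @export
print.scale_factor <- function(x, ...) {
  if (x$degenerate) {
    cat("Scale factor: degenerate focal fit (zero or undefined slope)\n")
    return(invisible(x))
  }
  cat(sprintf("Land-use scale factor: %.2f (bootstrap %.0f%% CI %.2f-%.2f, n = %d)\n",
              x$estimate, 100 * x$conf, x$ci[1], x$ci[2], x$n))
  invisible(x)
}
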
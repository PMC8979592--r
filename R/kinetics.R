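## Trajectory analysis: lag/exponential growth fits of membrane accumulation,
## cluster-size free-energy landscapes with critical-nucleus intercepts,
## first-passage times and stoichiometry.

#' Fit a lag + exponential growth curve
#'
#' Least-squares fit of `y(t) = b + E (1 - exp(-k (t - tau))) H(t - tau)`
#' with the Heaviside factor exactly as written; the primary observables are
#' the lag time `tau` and the growth rate `k`, with the initial growth
#' steepness `kE` reported from the linearization valid for
#' `tau < t < tau + 0.1/k`.
#'
#' @param data A data frame with time and response columns.
#' @param time,value Column names (tidy-select strings), defaults
#'   `"time_s"`, `"value"`.
#' @param multistart Number of jittered restarts if the first fit fails.
#' @return A `growth_fit` object (see [tidy.growth_fit()],
#'   [glance.growth_fit()], [autoplot.growth_fit()]); if no growth phase is
#'   discernible (`k <= 0` or non-convergence) the `flag` field is set and
#'   estimates are `NA`.
#' @export
#' @examples
#' d <- generate_growth_curve(b = 10, tau = 13, k = 1/121, E = 5000)
#' glance(fit_lag_exponential(d))
fit_lag_exponential <- function(data, time = "time_s", value = "value",
                                multistart = 5) {
  t <- data[[time]]; y <- data[[value]]
  stopifnot(length(t) >= 20, length(t) == length(y))
  ord <- order(t); t <- t[ord]; y <- y[ord]

  start0 <- list(
    b = mean(y[seq_len(max(2, floor(0.1 * length(y))))]),
    tau = t[which(y - min(y) >= 0.05 * (max(y) - min(y)))[1]],
    k = 1 / diff(range(t)),
    E = max(y) - min(y))
  if (!is.finite(start0$tau)) start0$tau <- t[2]

  model <- function(p, tt) {
    p["b"] + p["E"] * (1 - exp(-p["k"] * (tt - p["tau"]))) * (tt >= p["tau"])
  }
  tryfit <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(
        par = unlist(st),
        fn = function(p) model(p, t) - y,
        lower = c(b = -Inf, tau = 0, k = 1e-12, E = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  fit <- tryfit(start0)
  tries <- 0
  while ((is.null(fit) || fit$deviance > stats::var(y) * length(y)) &&
         tries < multistart) {
    tries <- tries + 1
    st <- start0
    st$tau <- abs(start0$tau * stats::runif(1, 0.2, 2))
    st$k <- start0$k * 10^stats::runif(1, -1, 1)
    f2 <- tryfit(st)
    if (!is.null(f2) && (is.null(fit) || f2$deviance < fit$deviance))
      fit <- f2
  }

  flag <- NULL
  est <- c(b = NA_real_, tau = NA_real_, k = NA_real_, E = NA_real_)
  resid_norm <- NA_real_; se <- rep(NA_real_, 4)
  if (is.null(fit)) {
    flag <- "no discernable lag/growth"
  } else {
    est <- fit$par
    if (est["k"] <= 0 || !is.finite(est["k"])) {
      flag <- "no discernable lag/growth"
    } else {
      resid_norm <- sqrt(fit$deviance)
      covm <- tryCatch(stats::vcov(fit), error = function(e) NULL)
      if (!is.null(covm)) se <- sqrt(pmax(0, diag(covm)))
    }
  }
  structure(list(
    estimate = est, se = stats::setNames(se, names(est)),
    kE = unname(est["k"] * est["E"]),
    residual_norm = resid_norm, flag = flag,
    data = tibble(time_s = t, value = y),
    fitted = if (is.null(flag)) model(est, t) else rep(NA_real_, length(t))),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("<growth_fit> flagged:", x$flag, "\n")
  } else {
    cat("<growth_fit> tau =", signif(x$estimate["tau"], 4),
        "s, 1/k =", signif(1 / x$estimate["k"], 4),
        "s, E =", signif(x$estimate["E"], 4),
        ", kE =", signif(x$kE, 4), "\n")
  }
  invisible(x)
}

#' Tidy a growth fit
#' @param x A `growth_fit`. @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate),
         std.error = unname(x$se))
}

#' One-row summary of a growth fit
#' @param x A `growth_fit`. @param ... Unused.
#' @return Tibble with `tau`, `k`, `inv_k`, `E`, `b`, `kE`,
#'   `residual_norm`, `flagged`.
#' @export
glance.growth_fit <- function(x, ...) {
  e <- x$estimate
  tibble(tau = unname(e["tau"]), k = unname(e["k"]),
         inv_k = unname(1 / e["k"]), E = unname(e["E"]), b = unname(e["b"]),
         kE = x$kE, residual_norm = x$residual_norm,
         flagged = !is.null(x$flag))
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "membrane clathrin (copies/um^2)")
  if (is.null(object$flag)) {
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = object$data$time_s, value = object$fitted),
      color = "firebrick")
  }
  p
}

#' Affine rescaling of an arbitrary-unit time series
#'
#' `(y - offset) * scale`; leaves the lag time and growth rate of a
#' lag/exponential fit invariant while scaling the extent `E`.
#'
#' @param data Data frame with a value column. @param offset,scale Affine
#'   parameters (`scale` must be nonzero).
#' @param value Value column name.
#' @return The data frame with the value column transformed.
#' @export
rescale_experiment <- function(data, offset = 300, scale = 1.7,
                               value = "value") {
  if (!is.numeric(scale) || scale == 0) abort("scale must be nonzero")
  data[[value]] <- (data[[value]] - offset) * scale
  data
}

#' Cluster-size occupancy landscape -ln P(n)
#'
#' Number-weighted size distribution over the cluster censuses of a window of
#' frames (each cluster in each frame counts once; monomers included), mapped
#' to the energy-like metric `-ln P(n)`, which at equilibrium is the free
#' energy of lattice size n in k_B T.
#'
#' @param x An `rd_trajectory` or a bare list of per-frame integer size
#'   vectors.
#' @param window `"full"`, `"growth"`, `"equilibrium"`, or a numeric
#'   time/fraction range `c(lo, hi)`. The growth window is `[tau, t(0.9 E)]`
#'   from the trajectory's own growth fit; equilibrium is the final 20% of
#'   frames.
#' @param weighting `"number"` (default) or `"mass"` (clusters weighted by
#'   their size).
#' @return A `size_landscape` tibble: `n`, `count`, `p`, `minus_log_p`, with
#'   the window recorded as an attribute. `sum(p) == 1` within the window.
#' @export
size_landscape <- function(x, window = "full", weighting = "number") {
  weighting <- match.arg(weighting, c("number", "mass"))
  if (inherits(x, "rd_trajectory")) {
    census <- x$census
    times <- x$frames$time_s
  } else {
    census <- x
    times <- seq_along(census)
  }
  nfr <- length(census)
  if (nfr == 0) abort("empty census")
  idx <- seq_len(nfr)
  if (is.character(window)) {
    window <- match.arg(window, c("full", "growth", "equilibrium"))
    if (window == "equilibrium") {
      idx <- seq.int(max(1L, floor(0.8 * nfr) + 1L), nfr)
    } else if (window == "growth") {
      if (!inherits(x, "rd_trajectory"))
        abort("growth window needs an rd_trajectory")
      yc <- if ("mem_clathrin" %in% names(x$frames) &&
                max(x$frames$mem_clathrin) > 0)
        x$frames$mem_clathrin else x$frames$largest
      gf <- fit_lag_exponential(tibble(time_s = times, value = yc))
      if (!is.null(gf$flag)) abort("no growth phase discernible")
      lo <- gf$estimate["tau"]
      hi_i <- which(yc >= gf$estimate["b"] + 0.9 * gf$estimate["E"])[1]
      hi <- if (is.na(hi_i)) max(times) else times[hi_i]
      idx <- which(times >= lo & times <= hi)
    }
  } else {
    idx <- which(times >= window[1] & times <= window[2])
  }
  if (length(idx) == 0) abort("window selects no frames")
  sizes <- unlist(census[idx], use.names = FALSE)
  if (length(sizes) == 0) abort("window contains no clusters")
  w <- if (weighting == "mass") sizes else rep(1, length(sizes))
  agg <- stats::aggregate(w, list(n = sizes), sum)
  p <- agg$x / sum(agg$x)
  out <- tibble(n = agg$n, count = agg$x, p = p, minus_log_p = -log(p))
  attr(out, "window") <- window
  attr(out, "n_frames") <- length(idx)
  class(out) <- c("size_landscape", class(out))
  out
}

#' @export
autoplot.size_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n,
                                       y = .data$minus_log_p)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "lattice size n (trimers)",
                  y = expression(-ln ~ P(n) ~ (k[B] * T)))
}

#' Critical-nucleus intercepts from a size landscape
#'
#' Fits a three-segment rise / plateau / fall model to the (median-filtered)
#' landscape by least squares over all changepoint pairs: a linear barrier
#' rising to the plateau level at `n1` (the critical nucleus; smaller
#' lattices are disassembly-prone), a constant plateau, and a linear well
#' edge descending beyond `n2` (start of stabilized growth). Flags are set
#' instead of intercepts when the fitted rise is not actually rising, the
#' plateau is not flat at `slope_tol`, or no descending well follows.
#'
#' @param landscape A [size_landscape()].
#' @param smooth Median-filter window (odd; 5 by default).
#' @param slope_tol Plateau flatness tolerance, k_B T per trimer.
#' @return A `nucleation_metrics` list: `n1`, `n2`, `plateau_kBT`,
#'   `no_barrier`, `no_well`.
#' @export
plateau_intercepts <- function(landscape, smooth = 5, slope_tol = 0.02) {
  stopifnot(is.data.frame(landscape), all(c("n", "minus_log_p") %in%
                                          names(landscape)))
  d <- landscape[order(landscape$n), ]
  n_all <- seq(min(d$n), max(d$n))
  g <- stats::approx(d$n, d$minus_log_p, xout = n_all)$y
  gs <- if (length(g) >= smooth)
    stats::runmed(g, k = smooth, endrule = "median") else g
  N <- length(gs)
  out <- list(n1 = NA_real_, n2 = NA_real_, plateau_kBT = NA_real_,
              no_barrier = FALSE, no_well = FALSE)
  class(out) <- "nucleation_metrics"
  if (N < 6) { out$no_barrier <- TRUE; out$no_well <- TRUE; return(out) }

  cs <- cumsum(gs)
  seg_sse <- function(i0, i1, y0, y1) {
    # SSE of gs[i0:i1] against the line through (i0, y0) and (i1, y1)
    idx <- i0:i1
    if (i1 == i0) return((gs[i0] - y0)^2)
    pred <- y0 + (y1 - y0) * (idx - i0) / (i1 - i0)
    sum((gs[idx] - pred)^2)
  }
  best <- list(sse = Inf, i1 = NA, i2 = NA, L = NA)
  for (i1 in 2:(N - 3)) {
    for (i2 in (i1 + 2):(N - 1)) {
      L <- (cs[i2] - cs[i1 - 1]) / (i2 - i1 + 1)
      sse <- seg_sse(1, i1, gs[1], L) +
        sum((gs[i1:i2] - L)^2) +
        seg_sse(i2, N, L, gs[N])
      if (sse < best$sse) best <- list(sse = sse, i1 = i1, i2 = i2, L = L)
    }
  }
  L <- best$L
  out$plateau_kBT <- L
  # plateau flatness: regression slope inside [i1, i2] against its own
  # standard error (so sampling noise does not masquerade as slope, while a
  # noiseless ramp cannot pass as flat)
  idx <- best$i1:best$i2
  pl_fit <- stats::lm(gs[idx] ~ idx)
  pslope <- stats::coef(pl_fit)[2]
  pse <- tryCatch(
    suppressWarnings(summary(pl_fit)$coefficients[2, 2]),
    error = function(e) 0)
  if (!is.finite(pse)) pse <- 0
  rise <- (L - gs[1]) / (best$i1 - 1)
  fall <- (gs[N] - L) / (N - best$i2)
  flat_ok <- abs(pslope) <= max(slope_tol, 3 * pse)
  if (rise > slope_tol && flat_ok) out$n1 <- n_all[best$i1]
  else out$no_barrier <- TRUE
  if (fall < -slope_tol && flat_ok) out$n2 <- n_all[best$i2]
  else out$no_well <- TRUE
  out
}

#' @export
print.nucleation_metrics <- function(x, ...) {
  cat("<nucleation_metrics> n1 =", signif(x$n1, 4), " n2 =",
      signif(x$n2, 4), " plateau =", signif(x$plateau_kBT, 3), "kBT",
      if (x$no_barrier) "(no barrier)" else "",
      if (x$no_well) "(no well)" else "", "\n")
  invisible(x)
}

#' First-passage time of the largest cluster to a threshold size
#'
#' @param trajectories An `rd_trajectory` or list thereof; alternatively a
#'   data frame with `time_s` and `largest`.
#' @param n_star Threshold size (trimers).
#' @return A tibble, one row per trajectory: `tau_obs` (s, NA when censored),
#'   `censored`; plus attribute columns via `summarize` by the caller.
#' @export
first_passage_to <- function(trajectories, n_star) {
  if (inherits(trajectories, "rd_trajectory") ||
      is.data.frame(trajectories)) {
    trajectories <- list(trajectories)
  }
  purrr::imap_dfr(trajectories, function(tr, i) {
    fr <- if (inherits(tr, "rd_trajectory")) tr$frames else tr
    hit <- which(fr$largest >= n_star)[1]
    tibble(trajectory = i,
           n_star = n_star,
           tau_obs = if (is.na(hit)) NA_real_ else fr$time_s[hit],
           censored = is.na(hit))
  })
}

#' Membrane clathrin:adaptor stoichiometry per frame
#'
#' @param trajectory An `rd_trajectory` with membrane copies of both species.
#' @return A tibble `(time_s, ratio, undefined)`; frames with zero membrane
#'   adaptors are flagged undefined.
#' @export
stoichiometry_series <- function(trajectory) {
  fr <- trajectory$frames
  tibble(time_s = fr$time_s,
         ratio = ifelse(fr$mem_adaptor > 0,
                        fr$mem_clathrin / fr$mem_adaptor, NA_real_),
         undefined = fr$mem_adaptor == 0)
}
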
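#' Segmented-regression design for an interrupted time series
#'
#' For a quarterly proportion series and three pre-specified
#' change points, builds the design of the linear model
#' \deqn{y_t = \alpha + \beta T_t + \sum_q \theta_q Q_{qt}
#'       + \sum_k \delta_k S_{kt}
#'       + \sum_k \gamma_k S_{kt}(T_t - T_k) + \epsilon_t}
#' where \eqn{y_t} is the outcome in percentage points, \eqn{T_t} the
#' quarter index, \eqn{Q_2,Q_3,Q_4} quarter-of-year indicators,
#' \eqn{S_k} a step equal to 0 before and 1 from change point \eqn{k},
#' and the interactions -- centred at their change point -- carry the
#' slope changes. Centring makes \eqn{\delta_k} the pure level shift at
#' quarter \eqn{T_k}: observed minus the value expected by extrapolating
#' the pre-change trend.
#'
#' Time is measured in quarters, so slopes read as percentage points per
#' annual quarter; a yearly time unit is a linear reparameterisation and
#' is available via `time_unit = "year"`.
#'
#' @param series tibble with `quarter` (labels) and `proportion` in
#'   `[0, 1]` (or `y_pp` already in percentage points).
#' @param change_points three increasing quarter labels.
#' @param time_unit `"quarter"` (default) or `"year"`.
#' @return tibble of class `itsa_design` with `y` and regressors;
#'   attributes `change_points`, `time_unit`.
#' @export
itsa_design <- function(series,
                        change_points = c("2002Q4", "2009Q3", "2013Q2"),
                        time_unit = c("quarter", "year")) {
  time_unit <- match.arg(time_unit)
  cp <- quarter_index(change_points)
  if (length(cp) != 3L || is.unsorted(cp, strictly = TRUE)) {
    stop("change_points must be three strictly increasing quarters")
  }
  qi <- quarter_index(series$quarter)
  era <- findInterval(qi, cp)
  if (any(table(factor(era, levels = 0:3)) < 2L)) {
    stop("each era needs at least 2 quarters for identifiability")
  }
  y <- if ("y_pp" %in% names(series)) series$y_pp else 100 * series$proportion
  unit <- if (time_unit == "year") 4 else 1
  t_rel <- (qi - qi[1]) / unit
  d <- tibble::tibble(
    quarter = series$quarter, y = y, t = t_rel,
    Q2 = as.integer(qi %% 4L == 1L),
    Q3 = as.integer(qi %% 4L == 2L),
    Q4 = as.integer(qi %% 4L == 3L)
  )
  for (k in 1:3) d[[paste0("S", k)]] <- as.integer(qi >= cp[k])
  for (k in 1:3) d[[paste0("I", k)]] <- d[[paste0("S", k)]] * (qi - cp[k]) / unit
  structure(d, class = c("itsa_design", class(d)),
            change_points = change_points, time_unit = time_unit)
}

#' Fit the interrupted time-series model
#'
#' Ordinary least squares on the design from [itsa_design()]. `robust =
#' TRUE` swaps in heteroskedasticity-and-autocorrelation-consistent
#' (Newey-West) standard errors; point estimates are unchanged.
#'
#' @param design an `itsa_design`.
#' @param robust use Newey-West standard errors (needs the `sandwich`
#'   package); default plain OLS.
#' @param conf_level confidence level for the intervals.
#' @return object of class `itsa_fit`: `coefficients` tibble (term,
#'   estimate, se, lower, upper), level shifts `delta`, slope changes
#'   `gamma`, baseline slope `beta`, `segment_slopes` (per-era slope =
#'   beta + cumulative gamma), `counterfactuals` (observed/expected/
#'   shift at each change point), the underlying `lm` and the design.
#' @export
fit_itsa <- function(design, robust = FALSE, conf_level = 0.95) {
  stopifnot(inherits(design, "itsa_design"))
  terms <- c("t", "Q2", "Q3", "Q4", "S1", "S2", "S3", "I1", "I2", "I3")
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  m <- stats::lm(fml, data = design)
  qr_rank <- m$qr$rank
  if (qr_rank < length(terms) + 1L) stop("rank-deficient ITSA design")
  est <- stats::coef(m)
  vc <- if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      stop("robust standard errors need the 'sandwich' package")
    }
    sandwich::NeweyWest(m, prewhite = FALSE)
  } else {
    stats::vcov(m)
  }
  se <- sqrt(diag(vc))
  zc <- stats::qt(1 - (1 - conf_level) / 2, df = m$df.residual)
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    lower = unname(est - zc * se), upper = unname(est + zc * se)
  )
  delta <- est[c("S1", "S2", "S3")]
  gamma <- est[c("I1", "I2", "I3")]
  beta <- est[["t"]]
  fit <- structure(
    list(
      coefficients = coefs,
      delta = unname(delta), gamma = unname(gamma), beta = beta,
      segment_slopes = beta + c(0, cumsum(unname(gamma))),
      conf_level = conf_level, robust = robust,
      change_points = attr(design, "change_points"),
      time_unit = attr(design, "time_unit"),
      model = m, design = design
    ),
    class = "itsa_fit"
  )
  fit$counterfactuals <- dplyr::bind_rows(
    lapply(1:3, function(k) itsa_counterfactual(fit, k))
  )
  fit
}

#' Observed vs expected value at a change point
#'
#' The expected value extrapolates the fitted trend from before change
#' point `k` (the step and slope-change of change point `k` zeroed;
#' earlier changes retained). Because the interaction is centred, the
#' shift equals the fitted step coefficient \eqn{\delta_k} exactly, and
#' observed (model) = expected + shift.
#'
#' @param fit an `itsa_fit`.
#' @param k change point number (1--3) or its quarter label.
#' @return one-row tibble: `change_point`, `observed`, `expected`,
#'   `shift`.
#' @export
itsa_counterfactual <- function(fit, k) {
  stopifnot(inherits(fit, "itsa_fit"))
  if (is.character(k)) {
    k <- match(k, fit$change_points)
    if (is.na(k)) stop("change point not among the fitted ones")
  }
  stopifnot(k %in% 1:3)
  d <- fit$design
  row <- d[quarter_index(d$quarter) == quarter_index(fit$change_points[k]), ]
  if (nrow(row) != 1L) stop("change point outside the fitted series")
  observed <- unname(stats::predict(fit$model, newdata = row))
  cf <- row
  cf[[paste0("S", k)]] <- 0L
  cf[[paste0("I", k)]] <- 0
  expected <- unname(stats::predict(fit$model, newdata = cf))
  tibble::tibble(
    change_point = fit$change_points[k],
    observed = observed, expected = expected, shift = observed - expected
  )
}

#' @export
print.itsa_fit <- function(x, ...) {
  cat("Interrupted time-series fit (",
      if (x$robust) "Newey-West" else "OLS", " SEs), time unit: ",
      x$time_unit, "\n", sep = "")
  cat("Change points:", paste(x$change_points, collapse = ", "), "\n")
  cat(sprintf("Baseline slope: %.3f pp per %s\n", x$beta, x$time_unit))
  for (k in 1:3) {
    cat(sprintf(
      "  %s: level shift %+.2f pp, slope change %+.3f -> segment slope %.3f\n",
      x$change_points[k], x$delta[k], x$gamma[k], x$segment_slopes[k + 1]
    ))
  }
  invisible(x)
}

#' Plot a quarterly series with its segmented fit
#'
#' Observed proportions, the fitted segments, and vertical lines at the
#' change points.
#'
#' @param series the series passed to [itsa_design()].
#' @param fit an `itsa_fit`.
#' @return a ggplot object.
#' @export
plot_itsa <- function(series, fit) {
  d <- fit$design
  d$fitted <- stats::fitted(fit$model)
  d$qi <- quarter_index(d$quarter)
  cp <- quarter_index(fit$change_points)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$qi)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = cp - 0.5, linetype = "dashed") +
    ggplot2::scale_x_continuous(
      breaks = d$qi[d$qi %% 8 == 0],
      labels = quarter_label(d$qi[d$qi %% 8 == 0])
    ) +
    ggplot2::labs(x = "quarter of birth", y = "% with readmission") +
    ggplot2::theme_minimal()
}
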
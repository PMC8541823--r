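#' Miniature EPSP event series
#'
#' Container for the spontaneous miniature excitatory postsynaptic potential
#' (mEPSP) amplitudes recorded from one muscle fiber, together with optional
#' event times and the recording duration.
#'
#' @param amplitudes numeric vector of event amplitudes in mV; all must be > 0.
#' @param duration recording duration in seconds (> 0), or `NA` if unknown.
#' @param times optional numeric vector of event times in seconds,
#'   nondecreasing and within `[0, duration]`; must match `amplitudes` in
#'   length when given.
#' @param cell_id label for the recorded cell.
#'
#' @return An object of class `event_series`.
#' @export
event_series <- function(amplitudes, duration = NA_real_, times = NULL,
                         cell_id = "cell") {
  # zero events is a valid (silent) recording; binning such a series errors
  amplitudes <- as.numeric(amplitudes)
  if (anyNA(amplitudes) || any(!is.finite(amplitudes)))
    stop("event_series: amplitudes must be finite", call. = FALSE)
  if (any(amplitudes <= 0))
    stop("event_series: all amplitudes must be > 0 mV", call. = FALSE)
  if (!is.na(duration) && duration <= 0)
    stop("event_series: duration must be > 0 s", call. = FALSE)
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(amplitudes))
      stop("event_series: times and amplitudes lengths differ", call. = FALSE)
    if (is.unsorted(times))
      stop("event_series: times must be nondecreasing", call. = FALSE)
    if (!is.na(duration) && (any(times < 0) || any(times > duration)))
      stop("event_series: times must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(amplitudes = amplitudes, times = times, duration = duration,
         cell_id = cell_id),
    class = "event_series"
  )
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d events, duration %s s\n",
              x$cell_id, length(x$amplitudes),
              ifelse(is.na(x$duration), "?", format(x$duration))))
  invisible(x)
}

#' Build an mEPSP amplitude histogram
#'
#' Bins event amplitudes into uniform half-open bins `[k*w, (k+1)*w)` anchored
#' at 0 mV. The 0.01-mV default bin width matches the standard construction of
#' quantal amplitude histograms. Trailing empty bins are trimmed.
#'
#' @param events an [event_series], or a bare numeric vector of amplitudes.
#' @param bin_width bin width in mV (default 0.01).
#'
#' @return An object of class `amplitude_histogram` with fields `bin_width`,
#'   `bin_edges` (length `nbins + 1`, starting at 0) and integer `counts`.
#' @export
build_histogram <- function(events, bin_width = 0.01) {
  amp <- if (inherits(events, "event_series")) events$amplitudes
         else as.numeric(events)
  if (length(amp) == 0L)
    stop("build_histogram: no amplitudes to bin", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("build_histogram: bin_width must be > 0", call. = FALSE)
  # half-open bins: amplitude exactly on an edge goes to the right bin
  idx <- bin_index(amp, bin_width)   # 0-based bin index
  nbins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbins)
  amplitude_histogram(bin_width, counts)
}

#' Construct an amplitude histogram from counts
#'
#' @param bin_width bin width in mV.
#' @param counts nonnegative counts per bin, bins anchored at 0.
#' @return An `amplitude_histogram`.
#' @export
amplitude_histogram <- function(bin_width, counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  structure(
    list(bin_width = bin_width,
         bin_edges = seq(0, by = bin_width, length.out = length(counts) + 1L),
         counts = counts),
    class = "amplitude_histogram"
  )
}

#' @export
print.amplitude_histogram <- function(x, ...) {
  cat(sprintf("<amplitude_histogram> %d bins of %g mV, %g events\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

# 0-based half-open bin index, robust to x/w landing epsilon below an
# integer (values on an edge must go to the right bin)
bin_index <- function(x, w) {
  r <- x / w
  i <- floor(r)
  i + (r - i > 1 - 1e-9)
}

bin_centers <- function(hist) {
  hist$bin_edges[-length(hist$bin_edges)] + hist$bin_width / 2
}

#' Binomial x Gaussian quantal release model
#'
#' Parameters of the quantal model of mEPSP amplitudes: the number of quanta
#' in an event follows a binomial distribution with `n` releasable quanta and
#' release probability `p`; an event of `i` quanta has Gaussian amplitude with
#' mean `i * q` and SD `i^peak_sd_exponent * sigma0`.
#'
#' `peak_sd_exponent = 0.5` corresponds to independent quanta whose variances
#' add (SD grows as the square root of the quantal content); `1.0` makes the
#' SD itself proportional to the content. Both conventions appear in the
#' quantal-analysis literature; the default is 0.5.
#'
#' @param q unitary (quantal) amplitude in mV, > 0.
#' @param sigma0 SD of a single quantum in mV, >= 0.
#' @param n total releasable quanta, integer >= 1.
#' @param p release probability in (0, 1).
#' @param peak_sd_exponent 0.5 or 1.0.
#' @return An object of class `quantal_model`.
#' @export
quantal_model <- function(q, sigma0, n, p, peak_sd_exponent = 0.5) {
  if (!is.finite(q) || q <= 0) stop("q must be > 0", call. = FALSE)
  if (!is.finite(sigma0) || sigma0 < 0) stop("sigma0 must be >= 0", call. = FALSE)
  if (!is.finite(n) || n < 1 || n != round(n)) stop("n must be an integer >= 1", call. = FALSE)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (!peak_sd_exponent %in% c(0.5, 1.0))
    stop("peak_sd_exponent must be 0.5 or 1.0", call. = FALSE)
  structure(
    list(q = q, sigma0 = sigma0, n = as.integer(n), p = p,
         peak_sd_exponent = peak_sd_exponent),
    class = "quantal_model"
  )
}

#' @export
print.quantal_model <- function(x, ...) {
  cat(sprintf(
    "<quantal_model> q = %.4g mV, sigma0 = %.4g mV, n = %d, p = %.3f (SD ~ i^%g)\n",
    x$q, x$sigma0, x$n, x$p, x$peak_sd_exponent))
  invisible(x)
}

#' Probability that an event contains i quanta
#'
#' Binomial probability `C(n,i) p^i (1-p)^(n-i)`. With `truncate = TRUE`
#' (spontaneous events carry at least one quantum) the distribution is
#' restricted to `i >= 1` and renormalized by `1 - (1-p)^n`.
#'
#' @param model a [quantal_model].
#' @param i integer quantal content, `0 <= i <= n` (`1 <= i` when truncated).
#' @param truncate restrict to `i >= 1` with renormalization (default TRUE).
#' @return Probability mass at `i` (vectorized over `i`).
#' @export
quantal_content_pmf <- function(model, i, truncate = TRUE) {
  if (any(i != round(i))) stop("i must be integer", call. = FALSE)
  lo <- if (truncate) 1L else 0L
  if (any(i < lo) || any(i > model$n))
    stop(sprintf("i must lie in [%d, %d]", lo, model$n), call. = FALSE)
  pm <- stats::dbinom(i, size = model$n, prob = model$p)
  if (truncate) pm <- pm / (1 - (1 - model$p)^model$n)
  pm
}

#' SD of the amplitude peak for i quanta
#'
#' @param model a [quantal_model].
#' @param i quantal content, integer >= 1 (vectorized).
#' @return Peak SD in mV: `i^peak_sd_exponent * sigma0`.
#' @export
peak_sd <- function(model, i) {
  if (any(i < 1) || any(i != round(i)))
    stop("i must be an integer >= 1", call. = FALSE)
  i^model$peak_sd_exponent * model$sigma0
}

#' Gaussian peak density
#'
#' Density of the Gaussian describing amplitude scatter around one quantal
#' peak, evaluated at amplitude `y`.
#'
#' @param mu peak mean in mV.
#' @param sigma peak SD in mV, > 0.
#' @param y amplitude in mV (vectorized).
#' @return Density value(s).
#' @export
peak_density <- function(mu, sigma, y) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  stats::dnorm(y, mean = mu, sd = sigma)
}

#' Theoretical mEPSP amplitude distribution over histogram bins
#'
#' Expected event count per bin under the binomial x Gaussian convolution
#' model: each quantal content `i >= 1` contributes a Gaussian peak at
#' `i * q` with SD `peak_sd(model, i)`, weighted by the (truncated) binomial
#' probability and scaled so peak areas carry the predicted numbers of events.
#' Gaussian mass per bin is computed from CDF differences, not midpoint
#' density, because the 0.01-mV bins can be comparable to the peak SD.
#'
#' In the degenerate limit `sigma0 = 0` all mass of peak `i` is assigned to
#' the bin containing `i * q`.
#'
#' @param model a [quantal_model].
#' @param n_events number of events the distribution is scaled to.
#' @param hist an [amplitude_histogram] supplying the bin grid.
#' @param truncate passed to [quantal_content_pmf()].
#' @return List with `expected_counts` (per bin), `coverage` (fraction of
#'   model mass inside the histogram range) and `warning` (non-NULL when more
#'   than 1% of the mass falls outside the bins).
#' @export
theoretical_distribution <- function(model, n_events, hist, truncate = TRUE) {
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  edges <- hist$bin_edges
  nb <- length(hist$counts)
  i <- seq_len(model$n)
  w <- quantal_content_pmf(model, i, truncate = truncate)
  expected <- numeric(nb)
  for (k in seq_along(i)) {
    mu <- i[k] * model$q
    s <- peak_sd(model, i[k])
    if (s > 0) {
      mass <- diff(stats::pnorm(edges, mean = mu, sd = s))
    } else {
      mass <- numeric(nb)
      # point mass: half-open bins, value on an edge goes right
      b <- bin_index(mu, hist$bin_width) + 1L
      if (b >= 1L && b <= nb) mass[b] <- 1
    }
    expected <- expected + w[k] * mass
  }
  coverage <- sum(expected)
  expected <- n_events * expected
  warn <- NULL
  if (coverage < 0.99)
    warn <- sprintf("histogram range covers only %.1f%% of model mass",
                    100 * coverage)
  list(expected_counts = expected, coverage = coverage, warning = warn)
}

# Poisson negative log-likelihood of observed bin counts given expectations
poisson_nll <- function(observed, expected) {
  eps <- 1e-12
  sum(expected - observed * log(expected + eps))
}

# initial guess for q from the dominant spacing of histogram peaks:
# autocorrelation of lightly smoothed counts, first local max at lag > 0,
# with the histogram mode as fallback
init_quantal_size <- function(hist) {
  counts <- hist$counts
  w <- hist$bin_width
  k <- min(5L, max(1L, length(counts)))
  if (k %% 2 == 0) k <- k - 1L
  sm <- stats::filter(counts, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  mode_q <- bin_centers(hist)[which.max(sm)]
  cands <- mode_q
  if (length(counts) >= 8L) {
    ac <- stats::acf(as.numeric(sm), lag.max = length(counts) - 1L,
                     plot = FALSE, demean = TRUE)$acf[, 1, 1]
    # first interior local maximum after the lag-0 peak
    lags <- which(diff(sign(diff(ac))) == -2)  # positions of local maxima - 1
    if (length(lags) > 0) cands <- c(lags[1] * w, cands)
  }
  cands[cands > 0]
}

#' Fit the quantal model to an amplitude histogram
#'
#' Estimates (q, sigma0, n, p) by minimizing a Poisson negative log-likelihood
#' over bins (default) or a least-squares criterion. Optimization uses an
#' outer grid over integer `n` and, for each `n`, bounded multi-start local
#' optimization over (q, sigma0, p) on a log/logit scale. Starting values for
#' `q` come from the dominant spacing of the smoothed histogram
#' (autocorrelation) and the histogram mode; start jitter is seeded for
#' determinism. Equal objectives tie-break toward smaller `n`.
#'
#' @param hist an [amplitude_histogram].
#' @param n_max largest `n` in the outer grid (default 10).
#' @param peak_sd_exponent 0.5 or 1.0; see [quantal_model()].
#' @param truncate use the `i >= 1` truncated binomial (default TRUE).
#' @param objective `"poisson"` (negative log-likelihood) or `"ls"`.
#' @param n_starts local-optimization starts per `n` (default 6).
#' @param min_events minimum events required in the histogram (default 30).
#' @param seed integer seed for start jitter.
#' @return An object of class `quantal_fit`: fields `model` ([quantal_model]),
#'   `n_events`, `objective`, `expected_counts`, `quantal_size`, `status`
#'   (`"ok"` or `"failed"`).
#' @export
fit_quantal_model <- function(hist, n_max = 10L, peak_sd_exponent = 0.5,
                              truncate = TRUE, objective = c("poisson", "ls"),
                              n_starts = 6L, min_events = 30L, seed = 1L) {
  objective <- match.arg(objective)
  counts <- hist$counts
  n_events <- sum(counts)
  if (n_events < min_events)
    stop(sprintf("fit_quantal_model: %g events < required floor %d",
                 n_events, min_events), call. = FALSE)

  obj_fun <- function(theta, n) {
    q <- exp(theta[1]); s0 <- exp(theta[2]); p <- stats::plogis(theta[3])
    if (!is.finite(q) || !is.finite(s0) || p <= 0 || p >= 1) return(1e12)
    model <- tryCatch(
      quantal_model(q, max(s0, 1e-9), n, min(max(p, 1e-9), 1 - 1e-9),
                    peak_sd_exponent),
      error = function(e) NULL)
    if (is.null(model)) return(1e12)
    td <- theoretical_distribution(model, n_events, hist, truncate = truncate)
    if (objective == "poisson") poisson_nll(counts, td$expected_counts)
    else sum((counts - td$expected_counts)^2)
  }

  q_cands <- init_quantal_size(hist)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  for (n in seq_len(n_max)) {
    starts <- list()
    for (q0 in q_cands[seq_len(min(2L, length(q_cands)))]) {
      for (p0 in c(0.2, 0.5)) {
        starts[[length(starts) + 1L]] <-
          c(log(q0), log(max(0.25 * q0, hist$bin_width)), stats::qlogis(p0))
      }
    }
    while (length(starts) < n_starts) {
      base <- starts[[1L + (length(starts) %% 4L)]]
      starts[[length(starts) + 1L]] <- base + stats::rnorm(3, sd = 0.3)
    }
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, obj_fun, n = n, method = "Nelder-Mead",
                     control = list(maxit = 800, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      # polish the best candidates
      if (is.null(best) || fit$value < best$value + 1) {
        fit2 <- tryCatch(
          stats::optim(fit$par, obj_fun, n = n, method = "BFGS",
                       control = list(maxit = 200, reltol = 1e-12)),
          error = function(e) NULL)
        if (!is.null(fit2) && fit2$value < fit$value) fit <- fit2
      }
      # tie-break equal objectives toward smaller n (strict improvement needed)
      if (is.null(best) || fit$value < best$value - 1e-9) {
        best <- list(value = fit$value, par = fit$par, n = n)
      }
    }
  }

  if (is.null(best)) {
    return(structure(
      list(model = NULL, n_events = n_events, objective = NA_real_,
           expected_counts = NULL, quantal_size = NA_real_, status = "failed"),
      class = "quantal_fit"))
  }
  model <- quantal_model(exp(best$par[1]), exp(best$par[2]), best$n,
                         stats::plogis(best$par[3]), peak_sd_exponent)
  td <- theoretical_distribution(model, n_events, hist, truncate = truncate)
  structure(
    list(model = model, n_events = n_events, objective = best$value,
         expected_counts = td$expected_counts, quantal_size = model$q,
         status = "ok"),
    class = "quantal_fit")
}

#' @export
print.quantal_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat("<quantal_fit> FAILED\n"); return(invisible(x))
  }
  cat(sprintf(
    "<quantal_fit> q = %.4f mV (n = %d, p = %.3f, sigma0 = %.4f), %g events, objective %.3f\n",
    x$model$q, x$model$n, x$model$p, x$model$sigma0, x$n_events, x$objective))
  invisible(x)
}

#' mEPSP frequency
#'
#' @param events an [event_series] with a known duration.
#' @return Event frequency in Hz (`count / duration`).
#' @export
mepsp_frequency <- function(events) {
  if (is.na(events$duration))
    stop("mepsp_frequency: recording duration is missing", call. = FALSE)
  length(events$amplitudes) / events$duration
}
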
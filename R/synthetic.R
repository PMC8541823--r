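#' Simulate mEPSP events from the quantal model
#'
#' Generative counterpart of the binomial x Gaussian convolution: each event
#' draws a quantal content from the (truncated) binomial, then an amplitude
#' from a Gaussian centered at `i * q` with SD `peak_sd(model, i)`, plus
#' optional baseline measurement noise. Event times follow a homogeneous
#' Poisson process. Negative or zero draws (possible for large noise) are
#' redrawn, preserving amplitude positivity.
#'
#' @param model a [quantal_model].
#' @param n_events number of events to simulate (>= 1).
#' @param noise_sd baseline recording noise SD in mV (default 0).
#' @param rate_hz event rate for the Poisson event times (default 2 Hz).
#' @param truncate draw contents from the `i >= 1` truncated binomial
#'   (default TRUE).
#' @param seed integer seed.
#' @return An [event_series]; attribute `"ground_truth"` records the
#'   generating parameters and the drawn quantal contents.
#' @export
simulate_mepsp_events <- function(model, n_events, noise_sd = 0,
                                  rate_hz = 2, truncate = TRUE, seed = 1L) {
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  set.seed(seed)
  i_vals <- if (truncate) seq_len(model$n) else 0:model$n
  pm <- quantal_content_pmf(model, i_vals, truncate = truncate)
  content <- sample(i_vals, n_events, replace = TRUE, prob = pm)
  amp <- numeric(n_events)
  for (k in seq_len(n_events)) {
    i <- content[k]
    mu <- i * model$q
    s <- sqrt((if (i >= 1) peak_sd(model, i) else 0)^2 + noise_sd^2)
    a <- if (s > 0) stats::rnorm(1, mu, s) else mu
    while (a <= 0) a <- if (s > 0) stats::rnorm(1, mu, s) else mu + 1e-6
    amp[k] <- a
  }
  gaps <- stats::rexp(n_events, rate = rate_hz)
  times <- cumsum(gaps)
  duration <- ceiling(times[n_events])
  ev <- event_series(amp, duration = duration, times = times,
                     cell_id = sprintf("sim-seed%d", seed))
  attr(ev, "ground_truth") <- list(model = model, n_events = n_events,
                                   noise_sd = noise_sd, rate_hz = rate_hz,
                                   truncate = truncate, seed = seed,
                                   content = content)
  ev
}

#' Simulate a crawling larva track
#'
#' Area series: baseline plus a sinusoid completing exactly `n_waves` cycles
#' over the recording (peaks strictly interior), plus Gaussian measurement
#' noise. The centroid advances at constant speed along a slowly turning
#' heading so the total path length equals `n_waves * stride_mm`. Spine
#' length and width are constant with small jitter.
#'
#' @param n_waves programmed number of peristaltic waves (>= 0).
#' @param stride_mm distance advanced per wave (default 1.5 mm).
#' @param fps frame rate (default 12.5 frames/s).
#' @param duration recording duration in s (default 120).
#' @param noise area noise SD as a fraction of the oscillation amplitude
#'   (default 0.05).
#' @param seed integer seed.
#' @return A [larva_track]; attribute `"ground_truth"` records the programmed
#'   parameters.
#' @export
simulate_crawl <- function(n_waves, stride_mm = 1.5, fps = 12.5,
                           duration = 120, noise = 0.05, seed = 1L) {
  if (n_waves < 0) stop("n_waves must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- round(fps * duration)
  t <- (seq_len(n) - 1) / fps
  base_area <- 6        # mm^2, typical third-instar projected area
  amp <- 0.8            # mm^2 oscillation amplitude
  area <- base_area + if (n_waves > 0)
    amp * sin(2 * pi * n_waves * t / duration - pi / 2) else 0
  area <- area + stats::rnorm(n, sd = noise * amp)
  area <- pmax(area, 0.1 * base_area)
  # constant-speed path with a gentle, smooth heading drift
  total <- n_waves * stride_mm
  step <- total / (n - 1)
  heading <- cumsum(c(0, stats::rnorm(n - 2, sd = 0.01)))
  dx <- step * cos(c(0, heading))
  dy <- step * sin(c(0, heading))
  x <- cumsum(c(10, dx[-1]))
  y <- cumsum(c(10, dy[-1]))
  spine <- 4 + stats::rnorm(n, sd = 0.02)
  width <- 0.8 + stats::rnorm(n, sd = 0.01)
  tr <- larva_track(x, y, area, spine_length = spine, width = width,
                    fps = fps, larva_id = sprintf("sim-seed%d", seed))
  attr(tr, "ground_truth") <- list(n_waves = n_waves, stride_mm = stride_mm,
                                   distance = total, fps = fps,
                                   duration = duration, noise = noise,
                                   seed = seed)
  tr
}

# lay one Gaussian punctum per selected grid cell; returns an intensity image
place_puncta <- function(nrow_px, ncol_px, centers, amplitude = 100,
                         sigma_px = 1.6) {
  img <- matrix(0, nrow_px, ncol_px)
  if (nrow(centers) == 0) return(img)
  half <- ceiling(4 * sigma_px)
  off <- seq(-half, half)
  kern <- exp(-outer(off^2, off^2, "+") / (2 * sigma_px^2))
  for (k in seq_len(nrow(centers))) {
    r <- centers[k, 1]; c0 <- centers[k, 2]
    rr <- r + off; cc <- c0 + off
    ok_r <- rr >= 1 & rr <= nrow_px; ok_c <- cc >= 1 & cc <= ncol_px
    img[rr[ok_r], cc[ok_c]] <- img[rr[ok_r], cc[ok_c]] +
      amplitude * kern[ok_r, ok_c]
  }
  img
}

# jittered grid positions guaranteeing non-overlapping puncta footprints
punctum_grid <- function(n, nrow_px, ncol_px, cell = 12L) {
  gr <- floor(nrow_px / cell); gc <- floor(ncol_px / cell)
  if (n > gr * gc) stop("too many puncta for image size", call. = FALSE)
  cells <- sample(gr * gc, n)
  row0 <- ((cells - 1) %% gr) * cell
  col0 <- ((cells - 1) %/% gr) * cell
  jit <- function(m) sample(seq(5, cell - 5), m, replace = TRUE)
  cbind(row0 + jit(n), col0 + jit(n))
}

#' Simulate a paired pHluorin quench/collapse scan
#'
#' Emulates the two-compartment NMJ geometry of the pH-probe experiment:
#' punctate fluorescence with a surface (membrane) component, quenchable by
#' acid superfusion, and an intravesicular component that is visible at rest
#' only where acidification is defective. `vesicular_fraction` is the
#' fraction of the resting signal that is quench-resistant (intravesicular).
#'
#' * `condition = "quench"`: first scan shows all resting signal; the second
#'   (acidic) scan retains only the quench-resistant fraction, so the
#'   expected area-fraction ratio is `vesicular_fraction`.
#' * `condition = "collapse"`: first scan shows surface signal plus any
#'   unacidified vesicular signal; the second (NH4Cl) scan reveals the full
#'   vesicular pool of relative size `vesicle_membrane_ratio`, so with
#'   `vesicular_fraction = 0` the expected ratio is
#'   `1 + vesicle_membrane_ratio`.
#'
#' @param vesicular_fraction fraction in `[0, 1]` of the resting signal that
#'   is intravesicular (quench-resistant).
#' @param condition `"quench"` or `"collapse"`.
#' @param puncta_count number of resting-signal puncta (default 60).
#' @param vesicle_membrane_ratio vesicular:membrane pool size ratio used by
#'   the collapse condition (default 2).
#' @param noise_sd background noise SD in intensity units (default 2).
#' @param dim_px image side length in pixels (default 192).
#' @param seed integer seed.
#' @return List with `first`, `second` ([image_scan]s), `threshold`
#'   (3x background SD, the recorded test threshold) and `truth` (expected
#'   ratio and constructed punctum counts).
#' @export
simulate_nmj_pair <- function(vesicular_fraction,
                              condition = c("quench", "collapse"),
                              puncta_count = 60L, vesicle_membrane_ratio = 2,
                              noise_sd = 2, dim_px = 192L, seed = 1L) {
  condition <- match.arg(condition)
  if (vesicular_fraction < 0 || vesicular_fraction > 1)
    stop("vesicular_fraction must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  if (condition == "quench") {
    n_first <- puncta_count
    n_resist <- round(vesicular_fraction * puncta_count)
    centers <- punctum_grid(n_first, dim_px, dim_px)
    first_img <- place_puncta(dim_px, dim_px, centers)
    keep <- if (n_resist > 0) centers[seq_len(n_resist), , drop = FALSE]
            else centers[0, , drop = FALSE]
    second_img <- place_puncta(dim_px, dim_px, keep)
    expected_ratio <- if (n_first > 0) n_resist / n_first else NA_real_
    truth_counts <- c(first = n_first, second = n_resist)
  } else {
    n_mem <- puncta_count
    n_ves <- round(vesicle_membrane_ratio * puncta_count)
    n_ves_visible <- round(vesicular_fraction * n_ves)
    centers <- punctum_grid(n_mem + n_ves, dim_px, dim_px)
    mem <- centers[seq_len(n_mem), , drop = FALSE]
    ves <- centers[n_mem + seq_len(n_ves), , drop = FALSE]
    ves_vis <- if (n_ves_visible > 0) ves[seq_len(n_ves_visible), , drop = FALSE]
               else ves[0, , drop = FALSE]
    first_img <- place_puncta(dim_px, dim_px, rbind(mem, ves_vis))
    second_img <- place_puncta(dim_px, dim_px, rbind(mem, ves))
    expected_ratio <- (n_mem + n_ves) / (n_mem + n_ves_visible)
    truth_counts <- c(first = n_mem + n_ves_visible, second = n_mem + n_ves)
  }
  first_img <- pmax(first_img + stats::rnorm(length(first_img), sd = noise_sd), 0)
  second_img <- pmax(second_img + stats::rnorm(length(second_img), sd = noise_sd), 0)
  list(
    first = image_scan(matrix(first_img, dim_px, dim_px), "HL3"),
    second = image_scan(matrix(second_img, dim_px, dim_px),
                        if (condition == "quench") "HL3-pH5.5" else "HL3-NH4Cl"),
    threshold = 3 * noise_sd,
    truth = list(condition = condition,
                 vesicular_fraction = vesicular_fraction,
                 expected_ratio = expected_ratio, counts = truth_counts,
                 seed = seed)
  )
}

#' Simulate an FM-dye load/unload image pair
#'
#' Loaded scan: dye puncta within a synaptic mask region. Unloaded scan: the
#' same signal scaled by `1 - released_fraction`, plus background noise. The
#' mask marks the punctum footprints (the GFP-labeled synaptic area).
#'
#' @param released_fraction fraction of the loaded dye released in `[0, 1]`.
#' @param puncta_count number of dye puncta (default 40).
#' @param noise_sd background noise SD (default 0.5).
#' @param dim_px image side (default 160).
#' @param seed integer seed.
#' @return List with `loaded`, `unloaded` ([image_scan]s), `mask` (logical
#'   matrix) and `truth`.
#' @export
simulate_fm_pair <- function(released_fraction, puncta_count = 40L,
                             noise_sd = 0.5, dim_px = 160L, seed = 1L) {
  if (released_fraction < 0 || released_fraction > 1)
    stop("released_fraction must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  centers <- punctum_grid(puncta_count, dim_px, dim_px)
  signal <- place_puncta(dim_px, dim_px, centers)
  # mask only the bright punctum cores, as a GFP mask would, so residual
  # background contributes negligibly to the masked intensity
  mask <- signal > 1
  loaded <- pmax(signal + stats::rnorm(length(signal), sd = noise_sd), 0)
  unloaded <- pmax((1 - released_fraction) * signal +
                     stats::rnorm(length(signal), sd = noise_sd), 0)
  list(
    loaded = image_scan(matrix(loaded, dim_px, dim_px), "loaded"),
    unloaded = image_scan(matrix(unloaded, dim_px, dim_px), "unloaded"),
    mask = mask,
    truth = list(released_fraction = released_fraction, seed = seed)
  )
}

#' Simulate a co-IP peptide intensity table
#'
#' Log-normal baseline protein abundances across three experiments and two
#' groups (bait/control); spiked proteins have their bait-group abundance
#' multiplied by a per-experiment fold change. Each protein contributes 1-8
#' peptides whose intensities scatter around the protein abundance; missing
#' values arise from detection-limit dropout: the probability of a missing
#' measurement falls steeply with intensity, so confidently quantified
#' (high-intensity) measurements are essentially always present while
#' near-limit ones drop out.
#'
#' @param n_proteins number of background proteins (default 100).
#' @param spiked named list `protein_id -> numeric fold per experiment`
#'   (length `n_experiments`).
#' @param n_experiments number of experiments (default 3).
#' @param missing_rate dropout probability for a measurement at reference
#'   intensity 1e5 (default 0.05); scales as `(1e5 / intensity)^1.5`.
#' @param seed integer seed.
#' @return Peptide-level data.frame for [top3_abundance()]; attribute
#'   `"ground_truth"` records the spiked set and folds.
#' @export
simulate_coip <- function(n_proteins = 100L, spiked = list(),
                          n_experiments = 3L, missing_rate = 0.05,
                          seed = 1L) {
  if (length(spiked) && any(unlist(spiked) <= 0))
    stop("folds must be > 0", call. = FALSE)
  set.seed(seed)
  prot <- sprintf("P%03d", seq_len(n_proteins))
  prot <- union(prot, names(spiked))
  rows <- list()
  for (pid in prot) {
    base <- exp(stats::rnorm(1, mean = log(1e6), sd = 1))
    n_pep <- sample(1:8, 1)
    folds <- if (pid %in% names(spiked)) spiked[[pid]]
             else rep(1, n_experiments)
    for (e in seq_len(n_experiments)) {
      for (grp in c("bait", "control")) {
        mult <- if (grp == "bait") folds[e] else 1
        for (pep in seq_len(n_pep)) {
          inten <- base * mult * exp(stats::rnorm(1, sd = 0.25)) *
            exp(-0.3 * (pep - 1))          # peptide response gradient
          # detection-limit dropout: steep in intensity, negligible for
          # bright measurements
          p_miss <- min(0.95, missing_rate * (1e5 / inten)^1.5)
          if (stats::runif(1) < p_miss) inten <- NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, gene_symbol = pid,
            peptide_id = sprintf("%s_pep%d", pid, pep),
            experiment = e, group = grp, intensity = inten,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(spiked = spiked, seed = seed,
                                    n_experiments = n_experiments)
  out
}
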
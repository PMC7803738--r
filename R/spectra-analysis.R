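#' Named default peak-search windows
#'
#' Spectral windows (nm) bracketing the absorption bands tracked across
#' temperature: the hemoglobin Soret band, the oxyhemoglobin alpha/beta
#' doublet, the near-infrared deoxyhemoglobin band, and the two water bands
#' near 1200 and 1450 nm.
#'
#' @return A named list of `c(lower, upper)` windows in nm.
#' @export
peak_windows <- function() {
  list(
    soret = c(400, 470),
    oxy_alpha_beta = c(520, 600),
    deoxy_nir = c(860, 950),
    water_1200 = c(1120, 1260),
    water_1450 = c(1350, 1550)
  )
}

resolve_window <- function(window) {
  if (is.character(window)) {
    w <- peak_windows()
    if (!window %in% names(w)) {
      stop(sprintf("unknown window '%s'; known windows: %s", window,
                   paste(names(w), collapse = ", ")), call. = FALSE)
    }
    return(w[[window]])
  }
  stopifnot(is.numeric(window), length(window) == 2, window[1] < window[2])
  window
}

#' Locate an absorption maximum within a spectral window
#'
#' Restricts the spectrum to the window and locates the maximum of `value`.
#' `method = "parabolic"` takes the discrete argmax and, when it is interior
#' and the three bracketing points are strictly concave, refines it by
#' three-point parabolic interpolation (otherwise the grid argmax is
#' returned as is; on a flat window the leftmost argmax is returned with a
#' degeneracy flag). `method = "gaussian"` fits a Gaussian band on a linear
#' background, `b0 + b1 (lambda - c) + A exp(-(lambda - c)^2 / (2 s^2))`,
#' by Levenberg-Marquardt least squares — the noise-robust choice for band
#' localization on single noisy spectra — and falls back to the parabolic
#' estimate if the fit fails or leaves the window.
#'
#' @param spectrum Data frame with a wavelength column (`wavelength_nm`) and
#'   a value column.
#' @param window A `c(lower, upper)` window in nm, or the name of one of
#'   [peak_windows()].
#' @param value Name of the value column (default `"mu_a_mm"`).
#' @param method `"parabolic"` (default) or `"gaussian"`.
#' @return A one-row tibble: `wavelength`, `value`, `window_lo`,
#'   `window_hi`, `method`, `degenerate`.
#' @examples
#' sp <- tibble::tibble(wavelength_nm = seq(1350, 1550, 2),
#'                      mu_a_mm = exp(-(wavelength_nm - 1441)^2 / 4050))
#' find_peak(sp, "water_1450")
#' @export
find_peak <- function(spectrum, window, value = "mu_a_mm",
                      method = c("parabolic", "gaussian")) {
  method <- match.arg(method)
  win <- resolve_window(window)
  stopifnot(is.data.frame(spectrum), "wavelength_nm" %in% names(spectrum),
            value %in% names(spectrum))
  sub <- spectrum[spectrum$wavelength_nm >= win[1] &
                    spectrum$wavelength_nm <= win[2], , drop = FALSE]
  sub <- sub[is.finite(sub[[value]]), , drop = FALSE]
  if (nrow(sub) < 3) {
    stop("need at least 3 grid points inside the window", call. = FALSE)
  }
  wl <- sub$wavelength_nm
  y <- sub[[value]]

  degenerate <- length(unique(y)) == 1
  i <- which.max(y)  # leftmost argmax on ties
  peak_wl <- wl[i]
  peak_val <- y[i]
  used <- "discrete"

  parabolic <- function() {
    if (i > 1 && i < length(y)) {
      y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
      # concave 3-point stencil required for refinement (ties allowed:
      # a symmetric maximum straddling two grid points interpolates to
      # their midpoint)
      if (y2 >= y1 && y2 >= y3) {
        h1 <- wl[i] - wl[i - 1]; h2 <- wl[i + 1] - wl[i]
        # vertex of the interpolating parabola (general spacing)
        denom <- h2 * (y1 - y2) + h1 * (y3 - y2)  # < 0 when concave
        if (denom < 0) {
          dx <- 0.5 * (h2^2 * (y1 - y2) - h1^2 * (y3 - y2)) / denom
          if (abs(dx) <= max(h1, h2)) {
            a <- denom / (h1 * h2 * (h1 + h2))
            bq <- (h1^2 * (y3 - y2) - h2^2 * (y1 - y2)) /
              (h1 * h2 * (h1 + h2))
            return(list(wl = wl[i] + dx, val = y2 + bq * dx + a * dx^2))
          }
        }
      }
    }
    NULL
  }

  if (!degenerate && method == "parabolic") {
    ref <- parabolic()
    if (!is.null(ref)) {
      peak_wl <- ref$wl; peak_val <- ref$val; used <- "parabolic"
    }
  } else if (!degenerate && method == "gaussian") {
    rng <- diff(range(wl))
    fit <- tryCatch({
      start <- list(b0 = min(y), b1 = 0, A = max(y) - min(y),
                    c = wl[i], s = rng / 8)
      # width and centre kept inside the window so the fit cannot trade the
      # band against the background on noisy spectra
      minpack.lm::nlsLM(
        y ~ b0 + b1 * (wl - c) + A * exp(-(wl - c)^2 / (2 * s^2)),
        start = start,
        lower = c(b0 = -Inf, b1 = -Inf, A = 0,
                  c = win[1] + 0.05 * rng, s = mean(diff(wl))),
        upper = c(b0 = Inf, b1 = Inf, A = Inf,
                  c = win[2] - 0.05 * rng, s = rng / 3),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    ok <- !is.null(fit)
    if (ok) {
      cf <- stats::coef(fit)
      ok <- is.finite(cf[["c"]]) && cf[["c"]] >= win[1] &&
        cf[["c"]] <= win[2] && abs(cf[["c"]] - wl[i]) <= rng / 3
    }
    if (ok) {
      peak_wl <- cf[["c"]]
      peak_val <- cf[["b0"]] + cf[["A"]]
      used <- "gaussian"
    } else {
      ref <- parabolic()
      if (!is.null(ref)) {
        peak_wl <- ref$wl; peak_val <- ref$val; used <- "parabolic"
      }
    }
  }

  tibble::tibble(
    wavelength = peak_wl, value = peak_val,
    window_lo = win[1], window_hi = win[2],
    method = used, degenerate = degenerate
  )
}

#' Resolve two overlapping absorption bands in one window
#'
#' Fits a two-Gaussian model on a linear background,
#' `b0 + b1 (lambda - m) + A1 G(c1, s1) + A2 G(c2, s2)`, by
#' Levenberg-Marquardt least squares — the standard treatment for the
#' oxyhemoglobin alpha/beta doublet, where single-band fits in sub-windows
#' are biased outward by the neighbouring band's tail. Components are
#' started at the discrete argmaxes of the two window halves and each
#' centre is constrained to its half.
#'
#' @inheritParams find_peak
#' @return A two-row tibble (one per component, ordered by wavelength):
#'   `wavelength`, `value`, `window_lo`, `window_hi`, `method`,
#'   `degenerate`.
#' @export
find_doublet <- function(spectrum, window, value = "mu_a_mm") {
  win <- resolve_window(window)
  sub <- spectrum[spectrum$wavelength_nm >= win[1] &
                    spectrum$wavelength_nm <= win[2], , drop = FALSE]
  sub <- sub[is.finite(sub[[value]]), , drop = FALSE]
  if (nrow(sub) < 9) {
    stop("need at least 9 grid points inside the window", call. = FALSE)
  }
  wl <- sub$wavelength_nm
  y <- sub[[value]]
  mid <- mean(win)
  lo <- wl <= mid
  i1 <- which.max(y[lo])
  i2 <- which.max(y[!lo])
  c1_0 <- wl[lo][i1]
  c2_0 <- wl[!lo][i2]
  rng <- diff(win)
  s0 <- rng / 8
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b0 + b1 * (wl - mid) +
        A1 * exp(-(wl - c1)^2 / (2 * s1^2)) +
        A2 * exp(-(wl - c2)^2 / (2 * s2^2)),
      start = list(b0 = min(y), b1 = 0, A1 = max(y[lo]) - min(y),
                   A2 = max(y[!lo]) - min(y), c1 = c1_0, c2 = c2_0,
                   s1 = s0, s2 = s0),
      lower = c(b0 = -Inf, b1 = -Inf, A1 = 0, A2 = 0,
                c1 = win[1], c2 = mid, s1 = mean(diff(wl)),
                s2 = mean(diff(wl))),
      upper = c(b0 = Inf, b1 = Inf, A1 = Inf, A2 = Inf,
                c1 = mid, c2 = win[2], s1 = rng / 3, s2 = rng / 3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to independent single-band fits in the two halves
    return(dplyr::bind_rows(
      find_peak(sub, c(win[1], mid), value = value, method = "gaussian"),
      find_peak(sub, c(mid, win[2]), value = value, method = "gaussian")))
  }
  cf <- stats::coef(fit)
  tibble::tibble(
    wavelength = c(cf[["c1"]], cf[["c2"]]),
    value = c(cf[["b0"]] + cf[["A1"]], cf[["b0"]] + cf[["A2"]]),
    window_lo = win[1], window_hi = win[2],
    method = "gaussian2", degenerate = FALSE
  )
}

#' Ordinary least-squares spectral gradient
#'
#' Slope of `value` versus wavelength over a window, with its standard
#' error, via [stats::lm()].
#'
#' @inheritParams find_peak
#' @param value Name of the value column (e.g. `"mu_s_mm"` or
#'   `"mu_s_prime_mm"`).
#' @return A one-row tibble: `slope` (units of value per nm),
#'   `standard_error`, `window_lo`, `window_hi`, `n_points`.
#' @export
fit_gradient <- function(spectrum, window, value = "mu_s_mm") {
  win <- resolve_window(window)
  stopifnot(is.data.frame(spectrum), "wavelength_nm" %in% names(spectrum),
            value %in% names(spectrum))
  sub <- spectrum[spectrum$wavelength_nm >= win[1] &
                    spectrum$wavelength_nm <= win[2], , drop = FALSE]
  sub <- sub[is.finite(sub[[value]]), , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 points in window", call. = FALSE)
  if (length(unique(sub$wavelength_nm)) < 2) {
    stop("singular design: a single wavelength cannot define a gradient",
         call. = FALSE)
  }
  fit <- stats::lm(sub[[value]] ~ sub$wavelength_nm)
  # exact fits trigger the "essentially perfect fit" note; SE 0 is a valid
  # answer here
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(
    slope = sm[2, 1], standard_error = sm[2, 2],
    window_lo = win[1], window_hi = win[2], n_points = nrow(sub)
  )
}

welch_or_flag <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 ||
      (stats::sd(a) == 0 && stats::sd(b) == 0)) {
    return(list(p = NA_real_, flag = "low_power"))
  }
  list(p = stats::t.test(a, b)$p.value, flag = "ok")
}

permutation_p <- function(a, b, n_permutations, seed) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_permutations)) {
    idx <- sample.int(length(pooled), na)
    stat <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (stat >= obs - 1e-15) hits <- hits + 1L
  }
  (hits + 1) / (n_permutations + 1)
}

#' Compare per-replicate peak positions between two temperature groups
#'
#' Two-stage analysis of a band shift: each replicate is summarized by its
#' peak wavelength, and the groups are compared by a Welch two-sample test
#' on those summaries (for balanced designs this is equivalent to a
#' random-intercept model on replicate summaries), optionally supplemented
#' by a seeded permutation test on the difference of group means.
#'
#' @param peaks_a,peaks_b Numeric vectors of per-replicate peak wavelengths
#'   (nm) for the two groups.
#' @param labels Length-2 character vector naming the groups.
#' @param permutation Logical; also compute a permutation p-value.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Seed for the permutation resampling.
#' @return A one-row tibble: `group_a`, `group_b`, `estimate_difference`
#'   (mean of `a` minus mean of `b`, nm), `p_value` (Welch),
#'   `p_permutation` (or `NA`), `method`, `flag` (`"ok"` or `"low_power"`
#'   when a group has fewer than 2 replicates or both are degenerate).
#' @export
estimate_shift <- function(peaks_a, peaks_b, labels = c("a", "b"),
                           permutation = FALSE, n_permutations = 1e4,
                           seed = 1L) {
  stopifnot(is.numeric(peaks_a), is.numeric(peaks_b),
            length(peaks_a) >= 1, length(peaks_b) >= 1)
  est <- mean(peaks_a) - mean(peaks_b)
  w <- welch_or_flag(peaks_a, peaks_b)
  pp <- if (permutation && w$flag == "ok") {
    permutation_p(peaks_a, peaks_b, n_permutations, seed)
  } else {
    NA_real_
  }
  tibble::tibble(
    group_a = labels[1], group_b = labels[2],
    estimate_difference = est, p_value = w$p, p_permutation = pp,
    method = if (permutation) "two-stage-summary+permutation"
             else "two-stage-summary",
    flag = w$flag
  )
}

#' Compare replicate-level summaries between temperature groups
#'
#' General two-stage group comparison on any per-replicate summary
#' statistic (a peak wavelength, a spectral gradient, ...): Welch test on
#' the summaries as the primary method, seeded permutation test as the
#' optional second.
#'
#' @param summaries Data frame with columns `temperature` (group label),
#'   `replicate`, and `value` (the per-replicate summary).
#' @param contrast Length-2 character vector `(label_a, label_b)`.
#' @inheritParams estimate_shift
#' @return A one-row tibble as in [estimate_shift()].
#' @export
compare_temperature_groups <- function(summaries, contrast,
                                       permutation = FALSE,
                                       n_permutations = 1e4, seed = 1L) {
  stopifnot(is.data.frame(summaries),
            all(c("temperature", "value") %in% names(summaries)),
            length(contrast) == 2)
  present <- unique(summaries$temperature)
  missing <- setdiff(contrast, present)
  if (length(missing) > 0) {
    stop(sprintf("unknown temperature label(s): %s (present: %s)",
                 paste(missing, collapse = ", "),
                 paste(present, collapse = ", ")), call. = FALSE)
  }
  a <- summaries$value[summaries$temperature == contrast[1]]
  b <- summaries$value[summaries$temperature == contrast[2]]
  estimate_shift(a, b, labels = contrast, permutation = permutation,
                 n_permutations = n_permutations, seed = seed)
}

#' Analyze recovered spectra: band shifts and scattering gradients
#'
#' Pipeline wrapper over the analysis stage: given recovered per-replicate
#' spectra grouped by temperature, computes per-replicate peak wavelengths
#' in each requested window and per-replicate scattering /
#' reduced-scattering gradients, then contrasts the temperature groups.
#'
#' @param spectra Data frame with columns `temperature`, `replicate`,
#'   `wavelength_nm`, `mu_a_mm`, `mu_s_mm`, `mu_s_prime_mm`.
#' @param windows Character vector of window names from [peak_windows()].
#' @param contrasts List of length-2 character vectors of temperature
#'   labels.
#' @param gradient_window `c(lo, hi)` window (nm) for the scattering
#'   gradients.
#' @param peak_method Peak-localization method passed to [find_peak()].
#' @inheritParams estimate_shift
#' @return A tibble with one row per (quantity x contrast): columns
#'   `quantity`, `window_lo`, `window_hi`, `group_a`, `group_b`,
#'   `estimate_difference`, `p_value`, `p_permutation`, `flag`.
#' @export
analyze_band_shifts <- function(spectra,
                                windows = c("water_1450", "water_1200",
                                            "soret"),
                                contrasts = list(c("25C", "60C"),
                                                 c("36C", "60C")),
                                gradient_window = c(500, 1500),
                                peak_method = "gaussian",
                                permutation = FALSE,
                                n_permutations = 1e4, seed = 1L) {
  stopifnot(all(c("temperature", "replicate", "wavelength_nm",
                  "mu_a_mm") %in% names(spectra)))

  per_replicate <- function(fun) {
    dplyr::group_modify(
      dplyr::group_by(spectra, .data$temperature, .data$replicate),
      fun) |>
      dplyr::ungroup()
  }

  out <- list()
  wl_range <- range(spectra$wavelength_nm)
  for (wname in windows) {
    win <- resolve_window(wname)
    if (win[1] < wl_range[1] || win[2] > wl_range[2]) next
    peaks <- per_replicate(function(df, key) {
      pk <- find_peak(df, wname, value = "mu_a_mm", method = peak_method)
      tibble::tibble(value = pk$wavelength)
    })
    for (ct in contrasts) {
      if (!all(ct %in% peaks$temperature)) next
      cmp <- compare_temperature_groups(
        peaks, ct, permutation = permutation,
        n_permutations = n_permutations, seed = seed)
      cmp$quantity <- paste0("peak_", wname)
      cmp$window_lo <- win[1]; cmp$window_hi <- win[2]
      out[[length(out) + 1]] <- cmp
    }
  }

  for (col in intersect(c("mu_s_mm", "mu_s_prime_mm"), names(spectra))) {
    gw <- c(max(gradient_window[1], wl_range[1]),
            min(gradient_window[2], wl_range[2]))
    if (gw[2] - gw[1] < 10) next
    grads <- per_replicate(function(df, key) {
      gr <- fit_gradient(df, gw, value = col)
      tibble::tibble(value = gr$slope)
    })
    for (ct in contrasts) {
      if (!all(ct %in% grads$temperature)) next
      cmp <- compare_temperature_groups(
        grads, ct, permutation = permutation,
        n_permutations = n_permutations, seed = seed)
      cmp$quantity <- paste0("gradient_", col)
      cmp$window_lo <- gw[1]; cmp$window_hi <- gw[2]
      out[[length(out) + 1]] <- cmp
    }
  }

  res <- dplyr::bind_rows(out)
  dplyr::select(res, "quantity", "window_lo", "window_hi",
                "group_a", "group_b", "estimate_difference",
                "p_value", "p_permutation", "method", "flag")
}
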
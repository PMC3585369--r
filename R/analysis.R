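#' Periodogram power spectral density
#'
#' Plain (rectangular-window, untapered) periodogram of a real time series:
#' one-sided PSD on the DFT frequency grid. Satisfies the discrete Parseval
#' identity: `sum(psd * df) == mean(x^2)` to numerical precision, so for a
#' zero-mean signal the integral of the PSD equals the variance.
#'
#' @param x numeric time series (at least 2 s of samples).
#' @param fs sampling rate in Hz.
#' @return A list of class `psd_estimate` with `freq` (Hz, 0..Nyquist),
#'   `power` (V^2/Hz) and `df` (grid step, Hz).
#' @export
psd_periodogram <- function(x, fs) {
  n <- length(x)
  if (n < 2 * fs) stop("signal too short: need at least 2 s of samples")
  X <- stats::fft(x)
  nf <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nf)])^2 / (fs * n)
  # one-sided: double all bins except DC and (for even n) Nyquist
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  structure(list(freq = (seq_len(nf) - 1) * fs / n, power = p * scale,
                 df = fs / n),
            class = "psd_estimate")
}

#' Band power from a periodogram
#'
#' Integrates the one-sided PSD over `[f1, f2]` (rectangle rule on the
#' periodogram grid, endpoints inclusive). The default band is the alpha
#' band, 8-12 Hz.
#'
#' @param psd a `psd_estimate` from [psd_periodogram()].
#' @param f1,f2 band edges in Hz, `0 < f1 < f2 <=` Nyquist.
#' @return Band power in V^2.
#' @export
alpha_power <- function(psd, f1 = 8, f2 = 12) {
  if (!is.finite(f1) || !is.finite(f2) || f1 >= f2) {
    stop("band edges must satisfy f1 < f2")
  }
  if (f2 > max(psd$freq) + 1e-9) stop("band exceeds the Nyquist frequency")
  sel <- psd$freq >= f1 & psd$freq <= f2
  sum(psd$power[sel]) * psd$df
}

#' Per-trial alpha power of an EEG record
#'
#' Convenience wrapper: periodogram alpha-band power of every channel.
#'
#' @param eeg an `eeg_record`.
#' @param f1,f2 band edges (Hz).
#' @return Named numeric vector, one power (V^2) per electrode.
#' @export
eeg_alpha_power <- function(eeg, f1 = 8, f2 = 12) {
  p <- apply(eeg$X, 1, function(ch) alpha_power(psd_periodogram(ch, eeg$fs),
                                                f1, f2))
  names(p) <- eeg$electrode_names
  p
}

#' Collect per-trial band powers into a power result
#'
#' @param powers trials x electrodes matrix (or list of per-trial vectors)
#'   of band powers.
#' @param electrodes electrode names.
#' @param band length-2 band edges (Hz).
#' @return An object of class `power_result`.
#' @export
power_result <- function(powers, electrodes, band = c(8, 12)) {
  if (is.list(powers)) powers <- do.call(rbind, powers)
  powers <- as.matrix(powers)
  colnames(powers) <- electrodes
  if (any(powers < 0)) stop("band powers must be non-negative")
  structure(list(powers = powers, electrodes = electrodes, band = band,
                 n_trials = nrow(powers)),
            class = "power_result")
}

#' Compare alpha power between conditions
#'
#' Per-electrode relative change in mean band power between a baseline and a
#' stimulation condition, with a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test across trials. Significance is assessed per electrode at level
#' `alpha_level`, uncorrected by default (`correction = "bonferroni"`
#' multiplies the threshold by `1/n_electrodes`).
#'
#' @param base,stim `power_result` objects with identical electrodes and at
#'   least 2 trials each.
#' @param alpha_level significance level (default 0.05).
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return A data.frame of class `comparison_result` with columns
#'   `electrode`, `mean_base`, `mean_stim`, `pct_change`, `p`, `significant`.
#' @export
compare_conditions <- function(base, stim, alpha_level = 0.05,
                               correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (!identical(base$electrodes, stim$electrodes)) {
    stop("electrode sets differ between conditions")
  }
  if (base$n_trials < 2 || stim$n_trials < 2) {
    stop("need at least 2 trials per condition")
  }
  thr <- if (correction == "bonferroni") {
    alpha_level / length(base$electrodes)
  } else {
    alpha_level
  }
  rows <- lapply(seq_along(base$electrodes), function(i) {
    b <- base$powers[, i]
    s <- stim$powers[, i]
    p <- if (identical(b, s)) 1 else {
      suppressWarnings(stats::wilcox.test(s, b, exact = FALSE)$p.value)
    }
    data.frame(electrode = base$electrodes[i], mean_base = mean(b),
               mean_stim = mean(s),
               pct_change = 100 * (mean(s) - mean(b)) / mean(b),
               p = p, significant = p < thr)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Calibrate the field-effect scaling constant
#'
#' Evaluates a stimulation experiment over a grid of lambda values and
#' returns the lambda whose mean percent alpha-power change at the target
#' electrode is closest to `target_percent` (14% by default, at POz under
#' 10 Hz tACS). With `interpolate = TRUE` the returned lambda is linearly
#' interpolated between the two grid points bracketing the target.
#'
#' @param experiment a function `lambda -> percent change` (deterministic
#'   given its internal seeds).
#' @param target_percent target percent change (default 14).
#' @param grid increasing numeric vector of candidate lambdas (>= 2 values).
#' @param interpolate interpolate between bracketing grid points (ignored
#'   when `method` is given explicitly).
#' @param method `"interpolate"` (linear interpolation between the
#'   bracketing grid points), `"nearest"` (closest grid point), or
#'   `"regression"` (least-squares power-law fit `log(response) ~
#'   log(lambda)` over the grid points clearly above the noise floor,
#'   inverted at the target; pools the grid evaluations and is the most
#'   precise under trial-sampling noise).
#' @return A list of class `lambda_calibration`: `lambda` (the selected
#'   value), `grid`, `response` (percent change per grid point),
#'   `target_percent`, `method`.
#' @export
calibrate_lambda <- function(experiment, target_percent = 14, grid,
                             interpolate = TRUE,
                             method = c("interpolate", "nearest",
                                        "regression")) {
  if (missing(method)) {
    method <- if (interpolate) "interpolate" else "nearest"
  } else {
    method <- match.arg(method)
  }
  if (length(grid) < 2) stop("grid must contain at least 2 lambda values")
  grid <- sort(grid)
  response <- vapply(grid, experiment, numeric(1))
  if (target_percent > max(response) || target_percent < min(response)) {
    stop("non-bracketing grid: target ", target_percent,
         "% outside achieved range [", round(min(response), 2), ", ",
         round(max(response), 2), "]%")
  }
  lam <- switch(method,
    interpolate = {
      # first crossing of the target along the grid; interpolate on the
      # response's natural (log-log, power-law) scale when possible, which
      # is unbiased for a convex response, otherwise linearly
      idx <- which(diff(sign(response - target_percent)) != 0)[1]
      if (is.na(idx)) {
        grid[which.min(abs(response - target_percent))]
      } else {
        r1 <- response[idx]; r2 <- response[idx + 1]
        l1 <- grid[idx]; l2 <- grid[idx + 1]
        if (r1 > 0 && r2 > 0 && l1 > 0 && target_percent > 0) {
          gamma <- log(r2 / r1) / log(l2 / l1)
          l1 * (target_percent / r1)^(1 / gamma)
        } else {
          l1 + (target_percent - r1) / (r2 - r1) * (l2 - l1)
        }
      }
    },
    nearest = grid[which.min(abs(response - target_percent))],
    regression = {
      # power-law response model; use the points clearly above the
      # trial-sampling noise floor
      keep <- response > 0.15 * target_percent & grid > 0
      if (sum(keep) < 3) {
        grid[which.min(abs(response - target_percent))]
      } else {
        fit <- stats::lm(log(response[keep]) ~ log(grid[keep]))
        co <- stats::coef(fit)
        exp((log(target_percent) - co[[1]]) / co[[2]])
      }
    })
  structure(list(lambda = lam, grid = grid, response = response,
                 target_percent = target_percent, method = method),
            class = "lambda_calibration")
}

#' @export
print.lambda_calibration <- function(x, ...) {
  cat(sprintf("<lambda_calibration> lambda* = %.3f (target %.1f%%)\n",
              x$lambda, x$target_percent))
  for (i in seq_along(x$grid)) {
    cat(sprintf("  lambda %6.2f -> %+7.2f%%\n", x$grid[i], x$response[i]))
  }
  invisible(x)
}

#' tACS frequency sweep
#'
#' Runs a stimulated-versus-baseline comparison at each tACS frequency
#' (independent seeds per frequency) and collects the per-electrode results.
#' Because a sweep tests every electrode at each of the swept frequencies
#' against the same no-stimulation condition, the per-electrode significance
#' flags are, by default, Bonferroni-corrected across the swept frequencies
#' (`p_adjust = "none"` restores the raw per-comparison flags).
#'
#' @param experiment a function `frequency -> comparison_result`.
#' @param freqs numeric vector of tACS frequencies in Hz (default 4-16 Hz
#'   in 1 Hz steps).
#' @param p_adjust correction across the swept frequencies within each
#'   electrode: `"bonferroni"` (default) or `"none"`.
#' @param alpha_level significance level applied to the (possibly
#'   corrected) p-values.
#' @return A data.frame with a `frequency` column prepended to each
#'   comparison row.
#' @export
frequency_sweep <- function(experiment, freqs = 4:16,
                            p_adjust = c("bonferroni", "none"),
                            alpha_level = 0.05) {
  p_adjust <- match.arg(p_adjust)
  if (length(freqs) == 0) stop("freqs must be non-empty")
  out <- lapply(freqs, function(f) {
    cmp <- experiment(f)
    cbind(frequency = f, as.data.frame(cmp))
  })
  out <- do.call(rbind, out)
  if (p_adjust == "bonferroni") {
    for (el in unique(out$electrode)) {
      sel <- out$electrode == el
      out$significant[sel] <-
        stats::p.adjust(out$p[sel], "bonferroni") < alpha_level
    }
  }
  out
}

#' Write a comparison or sweep table as delimited text
#'
#' @param table a `comparison_result` or sweep data.frame.
#' @param path file path.
#' @export
write_results_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
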
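#' Acquisition protocol for synthetic spectra
#'
#' Defaults emulate the multi-frequency sweep protocol behind the fitted
#' tables: 61 distinct frequencies between 0.1 Hz and 100 kHz, 20 replicate
#' sweeps, and an instrument error below 0.1% (modeled as relative noise
#' 1e-3).
#'
#' @param f_min,f_max sweep limits in Hz, `f_min < f_max`, both > 0.
#' @param n_freq number of frequencies (>= 2), log-spaced.
#' @param n_replicates number of replicate sweeps (>= 1).
#' @param noise_rel relative noise scale (>= 0); 0 gives exact model curves.
#' @param seed integer RNG seed for the noise draws.
#' @return an object of class `"fracz_acq"`.
#' @export
acquisition_spec <- function(f_min = 0.1, f_max = 1e5, n_freq = 61L,
                             n_replicates = 20L, noise_rel = 1e-3,
                             seed = 1L) {
  assert_number(f_min, "f_min", lower = 0, strict_lower = TRUE)
  assert_number(f_max, "f_max", lower = f_min, strict_lower = TRUE)
  if (!is_number(n_freq) || n_freq < 2 || n_freq != round(n_freq)) {
    stop_fracz("invalid spec: n_freq must be an integer >= 2")
  }
  if (!is_number(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates)) {
    stop_fracz("invalid spec: n_replicates must be an integer >= 1")
  }
  assert_number(noise_rel, "noise_rel", lower = 0)
  if (!is_number(seed) || seed != round(seed)) {
    stop_fracz("invalid spec: seed must be an integer")
  }
  structure(list(f_min = f_min, f_max = f_max, n_freq = as.integer(n_freq),
                 n_replicates = as.integer(n_replicates),
                 noise_rel = noise_rel, seed = as.integer(seed)),
            class = "fracz_acq")
}

#' Logarithmic frequency grid of an acquisition
#'
#' `n_freq` log-spaced frequencies from `f_min` to `f_max` inclusive; the
#' ratio between consecutive frequencies is constant and the endpoints are
#' exact.
#'
#' @param acq an [acquisition_spec()].
#' @return strictly increasing frequency vector in Hz.
#' @examples
#' g <- default_grid(acquisition_spec())
#' length(g); range(g)
#' @export
default_grid <- function(acq = acquisition_spec()) {
  stopifnot(inherits(acq, "fracz_acq"))
  f <- exp(seq(log(acq$f_min), log(acq$f_max), length.out = acq$n_freq))
  f[1L] <- acq$f_min
  f[acq$n_freq] <- acq$f_max
  frequency_grid(f)
}

new_spectrum <- function(f, z, replicate = 1L) {
  out <- data.frame(
    frequency_hz = f,
    z_real_ohm = Re(z),
    z_imag_ohm = Im(z),
    replicate = as.integer(replicate)
  )
  class(out) <- c("fracz_spectrum", "data.frame")
  out
}

validate_spectrum <- function(spectrum) {
  if (!is.data.frame(spectrum)) {
    stop_fracz("data error: spectrum must be a data frame")
  }
  need <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% names(spectrum))) {
    stop_fracz("data error: spectrum needs columns ",
               paste(need, collapse = ", "))
  }
  if (is.null(spectrum$replicate)) spectrum$replicate <- 1L
  for (rep_id in unique(spectrum$replicate)) {
    frequency_grid(spectrum$frequency_hz[spectrum$replicate == rep_id])
  }
  class(spectrum) <- unique(c("fracz_spectrum", class(spectrum)))
  spectrum
}

#' Simulate a synthetic bioimpedance spectrum
#'
#' Evaluates the model on the acquisition grid and perturbs each replicate
#' with independent multiplicative complex Gaussian noise,
#' \eqn{Z_{meas} = Z (1 + \sigma(\varepsilon_1 + j \varepsilon_2))} with
#' \eqn{\varepsilon \sim N(0,1)} i.i.d. per frequency and replicate, so the
#' replicate coefficient of variation of \eqn{|Z|} is approximately
#' `noise_rel`.  The draw is reproducible from `acq$seed` and the caller's
#' RNG state is left untouched.  `noise_rel = 0` returns the exact model
#' curve in every replicate.
#'
#' @param spec_model a [model_spec()].
#' @param acq an [acquisition_spec()].
#' @return a spectrum data frame with columns
#'   `frequency_hz, z_real_ohm, z_imag_ohm, replicate`.
#' @examples
#' sp <- simulate_spectrum(table_fixture("C2-d025"), acquisition_spec(seed = 7))
#' head(sp)
#' @export
simulate_spectrum <- function(spec_model, acq = acquisition_spec()) {
  stopifnot(inherits(spec_model, "fracz_model"), inherits(acq, "fracz_acq"))
  f <- default_grid(acq)
  z0 <- eval_serial(spec_model, f)
  n <- length(f)
  make_rep <- function(rep_id, z) new_spectrum(f, z, replicate = rep_id)
  if (acq$noise_rel == 0) {
    reps <- lapply(seq_len(acq$n_replicates), make_rep, z = z0)
  } else {
    reps <- with_seed(acq$seed, {
      lapply(seq_len(acq$n_replicates), function(rep_id) {
        w <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
        make_rep(rep_id, z0 * (1 + acq$noise_rel * w))
      })
    })
  }
  out <- do.call(rbind, reps)
  attr(out, "acq") <- acq
  class(out) <- c("fracz_spectrum", "data.frame")
  out
}

# Reference fitted-parameter columns (LM fits to human-skin spectra at two
# electrode diameters) shipped as fixtures; units are
# megaohm (R0), kiloohm (Rinf), seconds (tau); p, alpha and the memory
# coefficients are dimensionless.  Element resistance increments follow the
# dispersion-weight convention dR_k = p_k * (R0 - Rinf).
fixture_db <- function() {
  list(
    "C2-d025" = list(
      r0 = 1.120, r_inf = 1.911,
      els = list(list(kind = "cole", alpha = 0.743, tau = 0.266, p = 0.267),
                 list(kind = "cole", alpha = 0.851, tau = 1.414, p = 0.733))),
    "GC2-d025" = list(
      r0 = 1.119, r_inf = 0.680,
      els = list(list(kind = "gencole", alpha = 0.819, tau = 0.240,
                      p = 0.422, beta = -0.015),
                 list(kind = "gencole", alpha = 0.805, tau = 2.883,
                      p = 0.655, beta = 0.074))),
    "C2-d20" = list(
      r0 = 1.353, r_inf = 1.718,
      els = list(list(kind = "cole", alpha = 0.784, tau = 0.110, p = 0.200),
                 list(kind = "cole", alpha = 0.831, tau = 0.687, p = 0.800))),
    "C1GC1-d20" = list(
      r0 = 1.354, r_inf = 2.963,
      els = list(list(kind = "gencole", alpha = 0.532, tau = 1.900,
                      p = 1.596, beta = 0.024),
                 list(kind = "cole", alpha = 0.961, tau = 2.704, p = 0.356))),
    "GGC1-d025" = list(
      r0 = 0.642, r_inf = 1.060,
      els = list(list(kind = "ggc", alpha = 0.940, tau = 0.281,
                      beta = -0.043233, gamma = -0.131216, delta = -0.054793,
                      epsilon = -0.009557, zeta = -0.000652))),
    "GGC1-d20" = list(
      r0 = 1.461, r_inf = 2.530,
      els = list(list(kind = "ggc", alpha = 0.707, tau = 0.604,
                      beta = 0.010132, gamma = -0.004308, delta = -0.007025,
                      epsilon = -0.002536, zeta = -0.000206)))
  )
}

#' Reference fitted-parameter fixtures
#'
#' Returns the model populated from one of the reference fitted-parameter
#' columns (electrode diameters 0.25 cm and 2.0 cm at 1.0 V).  Table units
#' (megaohm, kiloohm) are converted to ohm; times stay in seconds.
#'
#' @param name one of `"C2-d025"`, `"GC2-d025"`, `"C2-d20"`, `"C1GC1-d20"`,
#'   `"GGC1-d025"`, `"GGC1-d20"`.
#' @return a [model_spec()].
#' @examples
#' table_fixture("GGC1-d20")
#' @export
table_fixture <- function(name) {
  db <- fixture_db()
  if (!is.character(name) || length(name) != 1L || !name %in% names(db)) {
    stop_fracz("unknown fixture \"", paste(name, collapse = ","),
               "\"; valid names: ", paste(names(db), collapse = ", "))
  }
  fx <- db[[name]]
  els <- lapply(fx$els, function(e) {
    new_element(e$kind, alpha = e$alpha, tau = e$tau, p = e$p %||% 1,
                beta = e$beta %||% 0, gamma = e$gamma %||% 0,
                delta = e$delta %||% 0, epsilon = e$epsilon %||% 0,
                zeta = e$zeta %||% 0)
  })
  model_spec(r_inf = fx$r_inf * 1e3, elements = els, r0 = fx$r0 * 1e6)
}
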
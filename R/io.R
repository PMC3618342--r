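# CSV and JSON readers/writers.  One CSV dialect, declared header, no
# sniffing: `frequency_hz,z_real_ohm,z_imag_ohm[,replicate]`, UTF-8, '.'
# decimal separator, one row per (frequency, replicate).

#' Read an impedance spectrum from CSV
#'
#' @param path path to a CSV file in the package dialect.
#' @return a validated spectrum data frame.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_fracz("parse error: file not found: ", path)
  header <- utils::read.csv(path, nrows = 1L, header = TRUE,
                            check.names = FALSE)
  need <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  if (!identical(names(header)[seq_along(need)], need) ||
      !(ncol(header) %in% c(3L, 4L)) ||
      (ncol(header) == 4L && names(header)[4L] != "replicate")) {
    stop_fracz("parse error: malformed header in ", path,
               " (expected frequency_hz,z_real_ohm,z_imag_ohm[,replicate])")
  }
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  num <- function(col, colname) {
    v <- suppressWarnings(as.numeric(raw[[colname]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop_fracz("parse error: non-numeric ", colname, " at data row ",
                 bad[1L], " of ", path)
    }
    v
  }
  f <- num(1, "frequency_hz")
  zr <- num(2, "z_real_ohm")
  zi <- num(3, "z_imag_ohm")
  rep_id <- if (ncol(raw) == 4L) {
    r <- suppressWarnings(as.integer(raw$replicate))
    if (any(is.na(r))) {
      stop_fracz("parse error: non-integer replicate at data row ",
                 which(is.na(r))[1L], " of ", path)
    }
    r
  } else rep(1L, length(f))
  bad_f <- which(f <= 0)
  if (length(bad_f)) {
    stop_fracz("parse error: non-positive frequency at data row ", bad_f[1L],
               " of ", path)
  }
  sp <- new_spectrum(f, complex(real = zr, imaginary = zi), rep_id)
  validate_spectrum(sp)
}

#' Write an impedance spectrum to CSV
#'
#' Full double precision is preserved (`digits = 17`), so a write/read
#' round trip reproduces the values exactly.
#'
#' @param spectrum a spectrum data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  spectrum <- validate_spectrum(spectrum)
  df <- data.frame(
    frequency_hz = format(spectrum$frequency_hz, digits = 17, trim = TRUE,
                          scientific = NA),
    z_real_ohm = format(spectrum$z_real_ohm, digits = 17, trim = TRUE,
                        scientific = NA),
    z_imag_ohm = format(spectrum$z_imag_ohm, digits = 17, trim = TRUE,
                        scientific = NA),
    replicate = spectrum$replicate
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# table-unit parameter list of a model (megaohm / kiloohm / seconds)
spec_report_params <- function(spec) {
  out <- list(
    label = spec$label %||% "custom",
    r_inf_kohm = spec$r_inf / 1e3,
    r0_mohm = if (!is.null(spec$r0)) spec$r0 / 1e6 else NULL,
    elements = lapply(spec$elements, function(el) {
      e <- list(kind = el$kind, dr_mohm = el$dr / 1e6, alpha = el$alpha,
                tau_s = el$tau, p = el$p)
      if (el$kind == "gencole") e$beta <- el$beta
      if (el$kind == "ggc") {
        e <- c(e, list(beta = el$beta, gamma = el$gamma, delta = el$delta,
                       epsilon = el$epsilon, zeta = el$zeta))
      }
      e
    })
  )
  out[!vapply(out, is.null, TRUE)]
}

#' Write a fit report
#'
#' Emits the fitted parameters in table units (megaohm, kiloohm, seconds),
#' the mean square error in each convention, convergence information, and
#' plot-ready Cole-plot columns (Re Z, -Im Z of the fitted model at the data
#' frequencies).  JSON is the machine contract; `format = "text"` writes a
#' small human-readable summary instead.
#'
#' @param result a `"fracz_fit"`.
#' @param path output path.
#' @param format `"json"` (default) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path, format = c("json", "text")) {
  stopifnot(inherits(result, "fracz_fit"))
  format <- match.arg(format)
  z_fit <- eval_serial(result$spec, result$frequency_hz)
  rpt <- list(
    converged = result$converged,
    message = result$message,
    n_iter = result$n_iter,
    n_free = result$n_free,
    mse_ohm2 = result$mse,
    mse_mohm2 = result$mse_mohm2,
    mse_scaled_1e7 = result$mse_scaled,
    parameters = spec_report_params(result$spec),
    cole_plot = list(
      frequency_hz = result$frequency_hz,
      re_z_ohm = Re(z_fit),
      neg_im_z_ohm = -Im(z_fit)
    )
  )
  if (format == "json") {
    jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("model: %s%s", rpt$parameters$label,
              if (!rpt$converged) "   *** NOT CONVERGED ***" else ""),
      sprintf("mse: %.8g ohm^2   (x 1e7 table units: %.6g)",
              rpt$mse_ohm2, rpt$mse_scaled_1e7),
      sprintf("iterations: %d (%s)", rpt$n_iter, rpt$message),
      sprintf("R_inf: %.6g kohm   R0: %.6g Mohm",
              rpt$parameters$r_inf_kohm, rpt$parameters$r0_mohm %||% NA),
      vapply(rpt$parameters$elements, function(e) {
        paste0(sprintf("  %s: alpha=%.6g tau=%.6g s p=%.6g",
                       e$kind, e$alpha, e$tau_s, e$p),
               if (!is.null(e$beta)) sprintf(" beta=%.6g", e$beta) else "")
      }, "")
    ), con)
  }
  invisible(path)
}

#' Read a fit report written by [write_fit_report()]
#' @param path path to the JSON report.
#' @return the report as a list.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read / write a model configuration
#'
#' The configuration is structured JSON with fields `model` (canonical
#' label or null), `r_inf_ohm`, and a list of `elements` blocks carrying
#' `kind`, `dr_ohm`, `alpha`, `tau_s`, `p`, `beta` and optional
#' `gamma/delta/epsilon/zeta`.
#'
#' @param path configuration path.
#' @return a [model_spec()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop_fracz("parse error: file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$r_inf_ohm) || is.null(cfg$elements)) {
    stop_fracz("parse error: config needs `r_inf_ohm` and `elements`")
  }
  els <- lapply(cfg$elements, function(e) {
    new_element(e$kind %||% "cole", alpha = e$alpha, tau = e$tau_s,
                p = e$p %||% 1, beta = e$beta %||% 0, gamma = e$gamma %||% 0,
                delta = e$delta %||% 0, epsilon = e$epsilon %||% 0,
                zeta = e$zeta %||% 0, dr = e$dr_ohm)
  })
  model_spec(r_inf = cfg$r_inf_ohm, elements = els,
             r0 = cfg$r0_ohm %||% NULL, label = cfg$model %||% NULL)
}

#' @rdname read_model_config
#' @param spec a [model_spec()].
#' @export
write_model_config <- function(spec, path) {
  stopifnot(inherits(spec, "fracz_model"))
  cfg <- list(
    model = spec$label,
    r_inf_ohm = spec$r_inf,
    r0_ohm = spec$r0,
    elements = lapply(spec$elements, function(el) {
      e <- list(kind = el$kind, dr_ohm = el$dr, alpha = el$alpha,
                tau_s = el$tau, p = el$p, beta = el$beta)
      if (el$kind == "ggc") {
        e <- c(e, list(gamma = el$gamma, delta = el$delta,
                       epsilon = el$epsilon, zeta = el$zeta))
      }
      e
    })
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
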
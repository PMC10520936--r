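# Terahertz unipolar picosecond pulse-train stimulus.

#' Construct a unipolar pulse train
#'
#' Describes the applied terahertz unipolar picosecond pulse-train electric
#' field: a train of same-sign rectangular (optionally raised-cosine-edged)
#' pulses of peak field `E0` at repetition frequency `f_rep`, on-fraction
#' `duty`, truncated exactly at the stimulation duration `t_on`.
#'
#' @param E0 peak field, V/m.
#' @param f_rep repetition frequency, Hz.
#' @param duty duty cycle in (0, 1); the pulse width is `duty / f_rep`.
#' @param t_on stimulation duration, s; the field is identically zero for
#'   `t >= t_on`.
#' @param envelope `"rectangular"` (ideal steps) or `"raised_cosine"`
#'   (cosine-smoothed edges over a fraction `edge_frac` of the pulse width,
#'   provided because ideal steps can destabilise explicit time stepping).
#' @param edge_frac edge fraction for the raised-cosine envelope.
#' @param direction unit vector along the polar axis of the stimulation.
#' @return A list of class `thz_pulse_train`.
#' @examples
#' tr <- pulse_train(f_rep = 0.5e12)
#' pulse_width(tr)  # 1 ps
#' @export
pulse_train <- function(E0 = 5e7, f_rep = 0.5e12, duty = 0.5,
                        t_on = 1.2e-9, envelope = c("rectangular",
                                                    "raised_cosine"),
                        edge_frac = 0.1, direction = c(0, 0, 1)) {
  envelope <- match.arg(envelope)
  stopifnot(E0 >= 0, f_rep > 0, duty > 0, duty < 1 || (duty == 1),
            t_on > 0, edge_frac >= 0, edge_frac <= 0.5)
  if (duty >= 1) stop("duty cycle must lie strictly inside (0, 1)")
  structure(list(E0 = E0, f_rep = f_rep, duty = duty, t_on = t_on,
                 envelope = envelope, edge_frac = edge_frac,
                 direction = direction / sqrt(sum(direction^2))),
            class = "thz_pulse_train")
}

#' @export
print.thz_pulse_train <- function(x, ...) {
  cat(sprintf("<thz_pulse_train> E0 = %.3g V/m, f_rep = %.3g THz, duty = %.2f, width = %.3g ps, t_on = %.3g ns (%s)\n",
              x$E0, x$f_rep / 1e12, x$duty, pulse_width(x) * 1e12,
              x$t_on * 1e9, x$envelope))
  invisible(x)
}

#' Pulse width of a train
#'
#' The on-duration of each unipolar pulse, `duty / f_rep`. At duty cycle
#' 0.5 the widths at 0.1, 0.5 and 1.2 THz are 5 ps, 1 ps and ~0.417 ps.
#'
#' @param train a [pulse_train()].
#' @return Width in seconds.
#' @export
pulse_width <- function(train) train$duty / train$f_rep

#' Instantaneous applied field magnitude
#'
#' Evaluates the scalar field magnitude at times `t` (vectorised). The
#' field equals `E0` during the on-fraction of each period while
#' `t < t_on`, is zero during the off-fraction and for all `t >= t_on`,
#' and is never negative (unipolar).
#'
#' @param train a [pulse_train()].
#' @param t times in seconds, all `>= 0`.
#' @return Field magnitudes, V/m, same length as `t`.
#' @export
field_at <- function(train, t) {
  if (any(t < 0)) stop("field_at: t must be >= 0")
  period <- 1 / train$f_rep
  w <- pulse_width(train)
  phase <- t - floor(t / period) * period
  on <- (t < train$t_on) & (phase < w)
  if (train$envelope == "rectangular") {
    out <- ifelse(on, train$E0, 0)
  } else {
    e <- train$edge_frac * w
    shape <- function(s) {
      ifelse(s < e, 0.5 * (1 - cos(pi * s / e)),
        ifelse(s > w - e, 0.5 * (1 - cos(pi * (w - s) / e)), 1))
    }
    out <- ifelse(on, train$E0 * shape(phase), 0)
  }
  out
}

#' Write the sampled stimulus to a two-column CSV
#'
#' @param train a [pulse_train()].
#' @param path output CSV path (`time_s,field_V_per_m`).
#' @param dt sampling interval, s; defaults to 1/40 of the pulse width.
#' @return `path`, invisibly.
#' @export
write_stimulus_csv <- function(train, path, dt = pulse_width(train) / 40) {
  t <- seq(0, train$t_on, by = dt)
  utils::write.csv(data.frame(time_s = t, field_V_per_m = field_at(train, t)),
                   path, row.names = FALSE)
  invisible(path)
}
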
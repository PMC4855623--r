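#' FLASH acquisition protocol
#'
#' Describes one multi-echo spoiled gradient-echo (FLASH) acquisition:
#' repetition time, nominal excitation flip angle and the echo-time train.
#' The dual-flip-angle mapping protocol uses two of these, a PD-weighted
#' one (low flip angle) and a T1-weighted one (high flip angle), sharing
#' TR and echo times.
#'
#' @param tr_ms Repetition time in ms (> 0).
#' @param flip_deg Nominal flip angle in degrees, in (0, 90).
#' @param te_ms Numeric vector of echo times in ms, strictly increasing,
#'   all positive.
#' @return An object of class `flash_protocol`.
#' @examples
#' flash_protocol_defaults("pdw")
#' flash_protocol(24.5, 21, seq(2.34, 18.72, length.out = 8))
#' @export
flash_protocol <- function(tr_ms, flip_deg, te_ms) {
  assert_that(is.numeric(tr_ms) && length(tr_ms) == 1 && tr_ms > 0,
              "tr_ms must be a single positive number")
  assert_that(is.numeric(flip_deg) && length(flip_deg) == 1 &&
                flip_deg > 0 && flip_deg < 90,
              "flip_deg must be in (0, 90)")
  assert_that(is.numeric(te_ms) && length(te_ms) >= 1 && all(te_ms > 0),
              "te_ms must be positive")
  assert_that(all(diff(te_ms) > 0) || length(te_ms) == 1,
              "te_ms must be strictly increasing")
  structure(list(tr_ms = tr_ms, flip_deg = flip_deg, te_ms = as.numeric(te_ms)),
            class = "flash_protocol")
}

#' Default dual-flip-angle FLASH protocols
#'
#' The acquisition protocol used throughout: TR = 24.5 ms with flip angle
#' 6 deg (PD-weighted) or 21 deg (T1-weighted), eight equidistant echoes
#' between 2.34 and 18.72 ms.
#'
#' @param which `"pdw"` or `"t1w"`.
#' @return A [flash_protocol()].
#' @export
flash_protocol_defaults <- function(which = c("pdw", "t1w")) {
  which <- match.arg(which)
  flash_protocol(tr_ms = 24.5,
                 flip_deg = if (which == "pdw") 6 else 21,
                 te_ms = seq(2.34, 18.72, length.out = 8))
}

#' @export
print.flash_protocol <- function(x, ...) {
  cat(sprintf("FLASH protocol: TR = %g ms, alpha = %g deg, %d echoes (%g..%g ms)\n",
              x$tr_ms, x$flip_deg, length(x$te_ms), min(x$te_ms), max(x$te_ms)))
  invisible(x)
}

#' MPRAGE protocol for synthetic T1-weighted images
#'
#' Timing and flip angle of the simulated magnetization-prepared rapid
#' gradient-echo (MPRAGE) sequence. One cycle is: adiabatic inversion,
#' free recovery, a train of `n_lines` low-angle excitations spaced
#' `es_ms` apart (readout duration `tau = n_lines * es_ms`), then a
#' recovery delay TD until the next inversion.
#'
#' The inversion time can follow two conventions: `"center"` (default)
#' measures TI from the inversion to the *center* of the readout train,
#' so the pre-train recovery is `ti_ms - tau/2` and
#' `td = tr - ti - tau/2`; `"start"` measures TI to the start of the
#' train, so the pre-train recovery is `ti_ms` and `td = tr - ti - tau`.
#' With the default parameters (TI = 960 ms, tau = 1742.4 ms,
#' TR = 2420 ms) only the `"center"` convention yields a non-negative TD,
#' which is why it is the default.
#'
#' @param flip_deg Excitation flip angle alpha in degrees (default 9).
#' @param es_ms Echo spacing in ms (default 9.9).
#' @param ti_ms Inversion time in ms (default 960).
#' @param te_ms Echo time of the simulated readout in ms (default 3, a
#'   typical short MPRAGE echo time; it only enters through the R2*
#'   decay factor `exp(-te * r2s)`).
#' @param n_lines Number of readout lines per inversion (default 176).
#' @param tr_ms Cycle repetition time in ms (default 2420).
#' @param ti_convention `"center"` or `"start"`, see Details.
#' @return An object of class `mprage_protocol` with derived fields
#'   `tau_ms` (readout duration), `ti_pre_ms` (recovery before the
#'   train) and `td_ms` (recovery after the train).
#' @examples
#' mprage_protocol()
#' @export
mprage_protocol <- function(flip_deg = 9, es_ms = 9.9, ti_ms = 960,
                            te_ms = 3, n_lines = 176, tr_ms = 2420,
                            ti_convention = c("center", "start")) {
  ti_convention <- match.arg(ti_convention)
  for (v in list(flip_deg, es_ms, ti_ms, te_ms, n_lines, tr_ms))
    assert_that(is.numeric(v) && length(v) == 1 && v > 0,
                "all MPRAGE protocol parameters must be single positive numbers")
  assert_that(flip_deg < 90, "flip_deg must be below 90 (cos(alpha) > 0)")
  assert_that(n_lines == round(n_lines), "n_lines must be an integer")
  tau_ms <- n_lines * es_ms
  if (ti_convention == "center") {
    ti_pre_ms <- ti_ms - tau_ms / 2
    td_ms <- tr_ms - ti_ms - tau_ms / 2
  } else {
    ti_pre_ms <- ti_ms
    td_ms <- tr_ms - ti_ms - tau_ms
  }
  assert_that(ti_pre_ms > 0,
              "pre-train recovery (TI minus half readout) must be positive")
  assert_that(td_ms >= 0, "recovery delay TD must be non-negative; check TR/TI/tau")
  structure(list(flip_deg = flip_deg, es_ms = es_ms, ti_ms = ti_ms,
                 te_ms = te_ms, n_lines = as.integer(n_lines), tr_ms = tr_ms,
                 tau_ms = tau_ms, ti_pre_ms = ti_pre_ms, td_ms = td_ms,
                 ti_convention = ti_convention),
            class = "mprage_protocol")
}

#' @export
print.mprage_protocol <- function(x, ...) {
  cat(sprintf(paste0("MPRAGE protocol: alpha = %g deg, ES = %g ms, TI = %g ms (%s),\n",
                     "  TE = %g ms, tau = %g ms (%d lines), TR = %g ms, TD = %g ms\n"),
              x$flip_deg, x$es_ms, x$ti_ms, x$ti_convention,
              x$te_ms, x$tau_ms, x$n_lines, x$tr_ms, x$td_ms))
  invisible(x)
}

#' Read / write protocols as YAML
#'
#' FLASH protocol files carry keys `tr_ms`, `flip_deg`, `te_ms`;
#' MPRAGE protocol files carry `flip_deg`, `es_ms`, `ti_ms`, `te_ms`,
#' `n_lines`, `tr_ms` and optionally `ti_convention`.
#'
#' @param path File path.
#' @param type `"flash"` or `"mprage"`.
#' @return The protocol object; `write_protocol_yaml` returns `path`
#'   invisibly.
#' @export
read_protocol_yaml <- function(path, type = c("flash", "mprage")) {
  type <- match.arg(type)
  y <- yaml::read_yaml(path)
  if (type == "flash") {
    for (k in c("tr_ms", "flip_deg", "te_ms"))
      assert_that(!is.null(y[[k]]), paste0("protocol file missing key '", k, "'"))
    flash_protocol(y$tr_ms, y$flip_deg, unlist(y$te_ms))
  } else {
    for (k in c("flip_deg", "es_ms", "ti_ms", "tr_ms"))
      assert_that(!is.null(y[[k]]), paste0("protocol file missing key '", k, "'"))
    mprage_protocol(flip_deg = y$flip_deg, es_ms = y$es_ms, ti_ms = y$ti_ms,
                    te_ms = y$te_ms %||% 3, n_lines = y$n_lines %||% 176,
                    tr_ms = y$tr_ms,
                    ti_convention = y$ti_convention %||% "center")
  }
}

#' @rdname read_protocol_yaml
#' @param protocol A `flash_protocol` or `mprage_protocol` object.
#' @export
write_protocol_yaml <- function(protocol, path) {
  keep <- setdiff(names(unclass(protocol)),
                  c("tau_ms", "ti_pre_ms", "td_ms"))
  yaml::write_yaml(unclass(protocol)[keep], path)
  invisible(path)
}
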
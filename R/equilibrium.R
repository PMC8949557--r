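# Desorption equilibrium temperature of grain (CAE three-parameter model).
#
# The equilibrium temperature Te is the temperature at which grain of a given
# moisture is in equilibrium with air of a given relative humidity; it is the
# zero point of effective accumulated temperature. The published rendering of
# the model equation is typographically ambiguous, so the functional form is
# kept behind a small registry: the default form is chosen to yield
# physically plausible Te (about 25 C near target moisture for corn), and
# every downstream consumer depends only on the Te value, never on the form.

.te_forms <- new.env(parent = emptyenv())

#' Register a Te model form
#'
#' Adds (or replaces) a functional form in the equilibrium-temperature
#' registry. A form is a function `(ERH, EMC, A, B, C) -> Te` in degrees C.
#'
#' @param name Form identifier.
#' @param fn Function of `(ERH, EMC, A, B, C)`.
#' @export
register_te_form <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .te_forms)
  invisible(name)
}

#' @rdname register_te_form
#' @export
te_forms <- function() sort(ls(.te_forms))

# Default reconstruction: Te = ln((1-ERH)/(-ln ERH)) - A - B * EMC^C.
register_te_form("cae-log-ratio", function(ERH, EMC, A, B, C) {
  log((1 - ERH) / (-log(ERH))) - A - B * EMC^C
})

# Alternative literal reading with the C constant as a divisor.
register_te_form("cae-linear-div-C", function(ERH, EMC, A, B, C) {
  (log(1 - ERH) - log(ERH) - A - B * EMC) / C
})

#' CAE model constants
#'
#' Grain-variety-specific constants of the three-parameter CAE desorption
#' equilibrium model. The defaults are the published corn desorption values.
#'
#' @param A,B,C Model constants (defaults 4.218, -32.013, -0.0274 for corn).
#' @return An object of class `cae_constants`.
#' @export
cae_constants <- function(A = 4.218, B = -32.013, C = -0.0274) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C))
  structure(list(A = A, B = B, C = C), class = "cae_constants")
}

#' Desorption equilibrium temperature
#'
#' Computes the grain desorption equilibrium temperature Te (degrees C) from
#' the equilibrium relative humidity and equilibrium moisture content via the
#' selected CAE model form. With the default form and corn constants, Te
#' decreases in EMC at fixed ERH: wetter grain is in equilibrium at lower
#' temperature, so drier targets raise the accumulation zero point.
#'
#' @param ERH Equilibrium relative humidity, fraction strictly inside (0, 1).
#' @param EMC Equilibrium moisture content, percent dry basis, > 0. In the
#'   closed drying loop this is the drying target moisture.
#' @param constants A [cae_constants()] object.
#' @param form Model-form id from the registry (see [te_forms()]).
#' @return Equilibrium temperature in degrees C.
#' @examples
#' equilibrium_temperature(0.5, 14.5)  # about 25.2 C
#' @export
equilibrium_temperature <- function(ERH, EMC, constants = cae_constants(),
                                    form = "cae-log-ratio") {
  stopifnot(inherits(constants, "cae_constants"))
  if (any(ERH <= 0 | ERH >= 1)) {
    stop_eatdry("eatdry_domain", "ERH must lie strictly inside (0, 1)")
  }
  if (any(EMC <= 0)) stop_eatdry("eatdry_domain", "EMC (% d.b.) must be > 0")
  if (!exists(form, envir = .te_forms, inherits = FALSE)) {
    stop_eatdry("eatdry_config", sprintf(
      "unknown Te model form '%s'; registered forms: %s",
      form, paste(te_forms(), collapse = ", ")))
  }
  fn <- get(form, envir = .te_forms)
  te <- fn(ERH, EMC, constants$A, constants$B, constants$C)
  if (any(!is.finite(te))) {
    stop_eatdry("eatdry_domain", "equilibrium temperature is not finite for these inputs")
  }
  te
}
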
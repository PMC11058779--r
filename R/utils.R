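# internal helpers shared across modules

#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 1) {
  # base round() is banker's rounding; tables here use arithmetic half-up
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @keywords internal
#' @noRd
stop_sh <- function(..., class = "streamhealth_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
#' @noRd
assert_that <- function(ok, ..., class = "streamhealth_error") {
  if (!isTRUE(ok)) stop_sh(..., class = class)
  invisible(TRUE)
}

# Canonical guild label sets
TROPHIC_LEVELS   <- c("Omn", "Ins", "Car")
HABITAT_LEVELS   <- c("BT", "RB", "RB-WC", "WC")
TOLERANCE_LEVELS <- c("SS", "IS", "TS")

# Chemistry variable order used throughout (units as in the field tables:
# WT degC; DO, TSS, TOC, BOD, TN, NH4_N, NO3_N mg/L; EC uS/cm;
# TP, PO4_P, Chl_a ug/L; TN_TP dimensionless)
CHEM_VARS <- c("WT", "DO", "EC", "TSS", "TOC", "BOD", "TN",
               "NH4_N", "NO3_N", "TP", "PO4_P", "TN_TP", "Chl_a")
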
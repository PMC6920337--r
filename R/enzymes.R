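#' Restriction enzymes
#'
#' An enzyme is described by its name, IUPAC recognition sequence, and the
#' remnant — the part of the site expected immediately after the barcode in a
#' preprocessed GBS-style read (for PstI the TASSEL convention is `TGCAG`,
#' the recognition minus its leading base).
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition sequence.
#' @param remnant remnant fragment; must be a suffix of `recognition`
#'   (or equal to it).
#' @return a list of class `mra_enzyme`.
#' @examples
#' PstI()
#' restriction_enzyme("ApeKI", "GCWGC", "CWGC")
#' @export
restriction_enzyme <- function(name, recognition, remnant = recognition) {
  recognition <- toupper(recognition)
  remnant <- toupper(remnant)
  if (!nzchar(recognition)) stop("empty recognition sequence")
  iupac_to_regex(recognition)  # validates alphabet
  if (!endsWith(recognition, remnant))
    stop("remnant '", remnant, "' is not a suffix of recognition '",
         recognition, "'")
  structure(list(name = name, recognition = recognition, remnant = remnant),
            class = "mra_enzyme")
}

#' @rdname restriction_enzyme
#' @export
PstI <- function() restriction_enzyme("PstI", "CTGCAG", "TGCAG")

#' @rdname restriction_enzyme
#' @export
MspI <- function() restriction_enzyme("MspI", "CCGG", "CGG")

#' @rdname restriction_enzyme
#' @export
EcoRI <- function() restriction_enzyme("EcoRI", "GAATTC", "AATTC")

#' @rdname restriction_enzyme
#' @export
ApeKI <- function() restriction_enzyme("ApeKI", "GCWGC", "CWGC")

#' @rdname restriction_enzyme
#' @export
BfaI <- function() restriction_enzyme("BfaI", "CTAG", "TAG")

#' @export
print.mra_enzyme <- function(x, ...) {
  cat("enzyme", x$name, "recognition", x$recognition,
      "remnant", x$remnant, "\n")
  invisible(x)
}
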
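#' The Martin-number variable registry
#'
#' Returns the registry of the 15 standard linear craniometric variables used
#' by the pipeline: 7 vault measurements (plus the alternative inferior vault
#' breadth M11b used for Levantine material, where measurement methodology
#' differs) and 7 facial measurements. Each entry carries the Martin code, a
#' human-readable name, the skull element it belongs to, and its anatomical
#' definition.
#'
#' @return A data.frame with columns `martin_code`, `name`, `element`
#'   (`"vault"` or `"face"`) and `definition`, one row per code.
#' @examples
#' reg <- martin_registry()
#' subset(reg, element == "vault")$martin_code
#' @export
martin_registry <- function() {
  path <- system.file("extdata", "martin_registry.csv", package = "cranioshift",
                      mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(
    nrow(reg) == 15L,
    !anyDuplicated(reg$martin_code),
    all(reg$element %in% c("vault", "face"))
  )
  reg
}

#' Canonical variable sets for a cranial element
#'
#' The vault partition comprises M1, M5, M8, M9, M11, M12, M17; for the Levant
#' region M11b (biradicular breadth) replaces M11 (biauricular breadth) in the
#' same slot. The face partition comprises M40, M45, M48, M51, M52, M54, M55
#' for every region. Order is canonical so that loading tables and reports are
#' stable across runs.
#'
#' @param element `"vault"` or `"face"`.
#' @param region Optional region name; `"Levant"` triggers the M11b
#'   substitution for the vault.
#' @return Character vector of 7 Martin codes in canonical order.
#' @examples
#' partition_codes("vault")
#' partition_codes("vault", region = "Levant")
#' @export
partition_codes <- function(element = c("vault", "face"), region = NULL) {
  element <- match.arg(element)
  if (element == "face") {
    return(c("M40", "M45", "M48", "M51", "M52", "M54", "M55"))
  }
  codes <- c("M1", "M5", "M8", "M9", "M11", "M12", "M17")
  if (!is.null(region) && identical(as.character(region), "Levant")) {
    codes[codes == "M11"] <- "M11b"
  }
  codes
}
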
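#' Tissue class alphabet
#'
#' The five tissue classes seen during an esophageal pullback, in the fixed
#' anatomical order in which the withdrawing endoscope traverses them:
#' stomach (`St`), transition Z-line (`Tz`), Barrett (`B`), transition
#' squamous (`Ts`) and healthy squamous (`Sq`). All label columns in the
#' package are factors with these levels, and argmax ties are broken toward
#' the earlier class in this order.
#'
#' @return Character vector of the five class codes, in anatomical order.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() c("St", "Tz", "B", "Ts", "Sq")

#' Coerce labels to the tissue-class factor
#'
#' @param x Character or factor vector of class codes.
#' @return Factor with levels `tissue_classes()`.
#' @export
tissue_factor <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% tissue_classes())
  if (any(bad)) {
    stop("unknown tissue label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(tissue_classes(), collapse = ", "), ")")
  }
  factor(x, levels = tissue_classes())
}

# integer codes 1..5 in anatomical order
label_code <- function(x) as.integer(tissue_factor(x))
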
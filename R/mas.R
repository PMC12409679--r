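#' Modified Ashworth Scale levels covered by the grading pipeline
#'
#' The clinical MAS has six levels (0, 1, 1+, 2, 3, 4); grade 4 (rigid limb)
#' does not occur in the elbow-flexor cohort this pipeline targets, so the
#' grading model covers the five observed levels.
#'
#' @return Character vector of MAS labels in clinical order.
#' @export
#' @examples
#' mas_levels()
mas_levels <- function() c("0", "1", "1+", "2", "3")

#' Encode MAS labels as ordinals
#'
#' Maps the clinical labels to integers `"0"->0, "1"->1, "1+"->2, "2"->3,
#' "3"->4`, preserving the clinical ordering `0 < 1 < 1+ < 2 < 3`. The ordinal
#' is the variable entering Spearman correlations and the class label for
#' classification.
#'
#' @param label character vector of MAS labels.
#' @return Integer vector of ordinals 0-4.
#' @export
#' @examples
#' encode_mas(c("0", "1+", "3"))
encode_mas <- function(label) {
  label <- as.character(label)
  ord <- match(label, mas_levels()) - 1L
  if (anyNA(ord)) {
    bad <- unique(label[is.na(ord)])
    stop("unknown MAS label(s): ", paste(sQuote(bad), collapse = ", "),
         "; supported labels are ", paste(mas_levels(), collapse = ", "),
         call. = FALSE)
  }
  ord
}

#' Decode MAS ordinals back to clinical labels
#'
#' @param ordinal integer vector of ordinals 0-4.
#' @return Character vector of MAS labels.
#' @export
decode_mas <- function(ordinal) {
  ordinal <- as.integer(ordinal)
  if (anyNA(ordinal) || any(ordinal < 0L | ordinal > 4L)) {
    stop("MAS ordinals must be integers in 0-4", call. = FALSE)
  }
  mas_levels()[ordinal + 1L]
}
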
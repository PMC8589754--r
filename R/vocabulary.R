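#' Phase vocabulary
#'
#' An ordered set of class names with one designated background class.
#' Per-second label sequences throughout the package are integer vectors of
#' 1-based indices into `names`; the background class covers every second not
#' claimed by a surgical phase.
#'
#' @param names Character vector of unique, non-empty class names, in display
#'   order.
#' @param background_index 1-based index of the background ("Not a phase")
#'   class. Default 1.
#' @return A `phase_vocabulary` object.
#' @examples
#' phase_vocabulary(c("Not a phase", "Incision", "Closure"))
#' @export
phase_vocabulary <- function(names, background_index = 1L) {
  names <- as.character(names)
  if (length(names) == 0 || anyNA(names) || any(!nzchar(names))) {
    rlang::abort("vocabulary names must be non-empty strings")
  }
  if (anyDuplicated(names)) {
    rlang::abort("vocabulary names must be unique")
  }
  background_index <- as.integer(background_index)
  if (background_index < 1L || background_index > length(names)) {
    rlang::abort("background_index out of range")
  }
  structure(
    list(names = names, background_index = background_index),
    class = "phase_vocabulary"
  )
}

#' Default sleeve-gastrectomy phase vocabulary
#'
#' Nine classes: the background "Not a phase" class (P0) plus the eight
#' surgical phases of sleeve gastrectomy, in their conventional P0..P8 order.
#'
#' @return A `phase_vocabulary` with 9 classes, background first.
#' @export
sleeve_gastrectomy_vocab <- function() {
  phase_vocabulary(c(
    "Not a phase",
    "Ligation of short gastric vessels",
    "Gastric transection",
    "Bougie",
    "Oversew staple line",
    "Exploration/inspection",
    "Liver retraction",
    "Hiatal hernia repair",
    "Gastric band removal"
  ))
}

#' @export
print.phase_vocabulary <- function(x, ...) {
  tags <- paste0("P", seq_along(x$names) - 1L)
  bg <- ifelse(seq_along(x$names) == x$background_index, " [background]", "")
  cat("<phase_vocabulary> ", length(x$names), " classes\n", sep = "")
  cat(paste0("  ", tags, ": ", x$names, bg, collapse = "\n"), "\n")
  invisible(x)
}

n_classes <- function(vocab) length(vocab$names)

#' Number of surgical (non-background) phases
#'
#' @param vocab A [phase_vocabulary()].
#' @return Integer count of non-background classes.
#' @export
n_phases <- function(vocab) length(vocab$names) - 1L

surgical_indices <- function(vocab) {
  setdiff(seq_along(vocab$names), vocab$background_index)
}

#' Resolve phase names to class indices
#'
#' @param phase Character names or integer indices.
#' @param vocab A [phase_vocabulary()].
#' @return Integer 1-based class indices.
#' @export
phase_index <- function(phase, vocab) {
  if (is.numeric(phase)) {
    idx <- as.integer(phase)
    if (any(idx < 1L | idx > n_classes(vocab), na.rm = TRUE)) {
      rlang::abort("phase index out of range")
    }
    return(idx)
  }
  idx <- match(as.character(phase), vocab$names)
  if (anyNA(idx)) {
    bad <- unique(phase[is.na(idx)])
    rlang::abort(paste0(
      "unknown phase name(s): ", paste(bad, collapse = ", ")
    ), class = "pkfilter_parse_error")
  }
  idx
}
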
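#' Depressive-symptom scale descriptors
#'
#' The three self-report instruments used across the supported cohort designs:
#' the 8-item CES-D (scores 0--8, ELSA/HRS-style), the 10-item CES-D
#' (scores 0--30, CHARLS-style), and EURO-D (scores 0--12, SHARE-style).
#' Each scale carries the conventional screening threshold used to flag an
#' elevated-symptom ("high") visit: >= 3 for CES-D-8, >= 10 for CES-D-10 and
#' >= 4 for EURO-D.
#'
#' @param name One of `"CESD8"`, `"CESD10"`, `"EUROD"`.
#' @return An object of class `depression_scale`: a list with elements
#'   `name`, `min_score`, `max_score` and `high_threshold`.
#' @examples
#' depression_scale("CESD8")
#' @export
depression_scale <- function(name = c("CESD8", "CESD10", "EUROD")) {
  name <- match.arg(name)
  spec <- switch(name,
    CESD8  = list(min_score = 0L, max_score = 8L,  high_threshold = 3L),
    CESD10 = list(min_score = 0L, max_score = 30L, high_threshold = 10L),
    EUROD  = list(min_score = 0L, max_score = 12L, high_threshold = 4L)
  )
  out <- c(list(name = name), spec)
  class(out) <- "depression_scale"
  out
}

#' @export
print.depression_scale <- function(x, ...) {
  cat(sprintf("<depression_scale> %s: range %d-%d, screening threshold >= %d\n",
              x$name, x$min_score, x$max_score, x$high_threshold))
  invisible(x)
}

as_depression_scale <- function(x) {
  if (inherits(x, "depression_scale")) return(x)
  if (is.character(x) && length(x) == 1L) return(depression_scale(x))
  stop("`scale` must be a depression_scale object or a scale name")
}
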
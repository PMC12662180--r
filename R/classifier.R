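#' Education-stratified cognitive norms
#'
#' Per education stratum and cognitive domain, the mean and sample SD of the
#' baseline-wave population domain scores. Norms are computed on the
#' baseline wave only so incident decline does not contaminate them
#' (wave-specific norms are available via `wave`).
#'
#' @param panel Long panel with per-wave domain scores.
#' @param participants Participant-level data frame with `id` and
#'   `education`.
#' @param domains Character vector of domain column names in `panel`.
#' @param wave Wave used for norming (default 1, baseline).
#' @return Data frame: `education`, `domain`, `mean`, `sd`, `n`.
#' @export
compute_norms <- function(panel, participants,
                          domains = c("memory", "orientation", "executive"),
                          wave = 1L) {
  stopifnot(all(domains %in% names(panel)))
  base <- panel[panel$wave == wave, , drop = FALSE]
  edu <- participants$education[match(base$id, participants$id)]
  out <- do.call(rbind, lapply(levels(factor(edu)), function(e) {
    rows <- which(edu == e)
    if (length(rows) < 2L)
      stop(sprintf("education stratum '%s' has fewer than 2 participants", e))
    do.call(rbind, lapply(domains, function(d) {
      x <- base[[d]][rows]
      x <- x[!is.na(x)]
      if (length(x) < 2L)
        stop(sprintf("stratum '%s', domain '%s': fewer than 2 scores", e, d))
      s <- stats::sd(x)
      if (s == 0)
        stop(sprintf("stratum '%s', domain '%s': zero SD", e, d))
      data.frame(education = e, domain = d, mean = mean(x), sd = s,
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Cognitive impairment relative to education-stratified norms
#'
#' TRUE when any domain score is at or below the stratum mean minus 1.5
#' stratum SDs (boundary inclusive: a score exactly 1.5 SD below the mean is
#' impaired).
#'
#' @param scores Named numeric vector (or 1-row data frame) of domain
#'   scores.
#' @param norms Norms data frame from [compute_norms()] (or generating
#'   norms with the same columns).
#' @param stratum Education stratum label.
#' @param k SD multiplier (default 1.5).
#' @return Logical scalar.
#' @export
cognitive_impairment <- function(scores, norms, stratum, k = 1.5) {
  scores <- unlist(scores)
  nr <- norms[norms$education == stratum, , drop = FALSE]
  if (!nrow(nr)) stop("no norms for stratum ", stratum)
  hit <- FALSE
  for (d in names(scores)) {
    row <- nr[nr$domain == d, , drop = FALSE]
    if (!nrow(row)) next
    if (!is.na(scores[[d]]) && scores[[d]] <= row$mean - k * row$sd)
      hit <- TRUE
  }
  hit
}

#' Functional impairment from ADL difficulty count
#'
#' TRUE when the participant reports difficulty with at least one activity
#' of daily living.
#'
#' @param adl_difficulties Non-negative integer count(s).
#' @return Logical of the same length.
#' @export
functional_impairment <- function(adl_difficulties) {
  stopifnot(all(adl_difficulties >= 0, na.rm = TRUE))
  adl_difficulties >= 1
}

#' Harmonized algorithmic dementia classification
#'
#' Classifies each participant at each wave. Under the `"concurrence"` rule
#' (ELSA/SHARE/CHARLS-style), a wave is positive when cognitive impairment
#' (any domain at or below mean - 1.5 SD of its education stratum) and
#' functional impairment (>= 1 ADL difficulty) hold together. Under the
#' `"summary_score"` rule (HRS-style), a wave is positive when the 0--27
#' cognition composite (memory + executive) is at or below `summary_cut`
#' (default 6). A self-reported physician diagnosis at any wave also confers
#' positivity when `basis = "either"`. Status is absorbing: once positive,
#' positive at every later wave.
#'
#' @param panel Long panel with domain scores, `adl` and `self_report`.
#' @param participants Participant-level data with `id`, `education`.
#' @param norms Norms data frame (see [compute_norms()]).
#' @param rule `"concurrence"` or `"summary_score"`.
#' @param summary_cut Composite cut for the summary-score rule (default 6).
#' @param basis `"either"` (algorithmic or self-report), `"algorithmic"`, or
#'   `"self_report"`.
#' @param k SD multiplier for the impairment threshold (default 1.5).
#' @return Object of class `dementia_classification`: data frame with `id`,
#'   `first_positive_wave` (NA when never positive), `basis_first`, and one
#'   logical column `status_w<j>` per wave.
#' @export
classify_dementia <- function(panel, participants, norms = NULL,
                              rule = c("concurrence", "summary_score"),
                              summary_cut = 6L,
                              basis = c("either", "algorithmic", "self_report"),
                              k = 1.5) {
  rule <- match.arg(rule)
  basis <- match.arg(basis)
  waves <- sort(unique(panel$wave))

  if (rule == "concurrence") {
    if (is.null(norms)) stop("concurrence rule requires norms")
    edu <- as.character(participants$education[match(panel$id, participants$id)])
    key <- paste(edu, sep = "|")
    imp <- rep(FALSE, nrow(panel))
    for (d in intersect(unique(norms$domain), names(panel))) {
      thr <- norms$mean[match(paste(edu, d), paste(norms$education, norms$domain))] -
        k * norms$sd[match(paste(edu, d), paste(norms$education, norms$domain))]
      imp <- imp | (!is.na(panel[[d]]) & panel[[d]] <= thr)
    }
    algo <- imp & functional_impairment(panel$adl)
  } else {
    composite <- panel$memory + panel$executive
    if (any(composite < 0 | composite > 27, na.rm = TRUE))
      stop("summary composite out of the 0-27 range")
    algo <- !is.na(composite) & composite <= summary_cut
  }
  selfrep <- if ("self_report" %in% names(panel))
    panel$self_report %in% TRUE else rep(FALSE, nrow(panel))
  pos <- switch(basis,
                either = algo | selfrep,
                algorithmic = algo,
                self_report = selfrep)

  ids <- unique(panel$id)
  wide_pos <- matrix(FALSE, length(ids), length(waves),
                     dimnames = list(NULL, paste0("status_w", waves)))
  wide_algo <- wide_pos
  row_i <- match(panel$id, ids)
  col_i <- match(panel$wave, waves)
  wide_pos[cbind(row_i, col_i)] <- pos
  wide_algo[cbind(row_i, col_i)] <- algo
  # absorbing state
  for (j in seq_along(waves)[-1])
    wide_pos[, j] <- wide_pos[, j] | wide_pos[, j - 1]

  first_pos <- apply(wide_pos, 1, function(r) {
    i <- which(r)[1]
    if (is.na(i)) NA_integer_ else waves[i]
  })
  basis_first <- rep(NA_character_, length(ids))
  for (i in which(!is.na(first_pos))) {
    at_first <- panel$id == ids[i] & panel$wave == first_pos[i]
    a <- any(algo[at_first]); s <- any(selfrep[at_first])
    basis_first[i] <- if (a && s) "either" else if (a) "algorithmic" else "self_report"
  }

  out <- data.frame(id = ids, first_positive_wave = as.integer(first_pos),
                    basis_first = basis_first, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(wide_pos))
  class(out) <- c("dementia_classification", class(out))
  out
}

#' Lagged-analysis exclusion of early incident cases
#'
#' Removes participants first classified positive at the second study wave
#' (i.e. within the first inter-wave interval), the standard guard against
#' reverse causation from prodromal disease. All other records pass through
#' untouched.
#'
#' @param data Participant-level data frame containing
#'   `first_positive_wave`.
#' @param wave Wave whose incident cases are excluded (default 2).
#' @return The reduced data frame; attribute `n_excluded` gives the count
#'   removed.
#' @export
lagged_exclusion <- function(data, wave = 2L) {
  stopifnot("first_positive_wave" %in% names(data))
  drop <- !is.na(data$first_positive_wave) & data$first_positive_wave == wave
  out <- data[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}
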
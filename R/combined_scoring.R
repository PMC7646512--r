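#' Min-max normalize a per-kinase score vector
#'
#' Rescales raw scores for one site and one scorer over its candidate
#' kinase set to `[0, 1]` via `(x - min) / (max - min)`. A constant vector
#' (max == min) maps to all zeros. Order-preserving by construction and
#' invariant to adding a constant to all scores.
#'
#' @param raw named numeric vector (kinase_id -> raw score), length >= 1.
#' @return named numeric vector in `[0, 1]`.
#' @export
normalize_scores <- function(raw) {
  stopifnot(length(raw) >= 1L, is.numeric(raw))
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) return(stats::setNames(rep(0, length(raw)), names(raw)))
  (raw - lo) / (hi - lo)
}

#' Assemble and combine the three scorers for one site
#'
#' Normalizes each supplied raw score vector per scorer (min-max over that
#' scorer's candidates) and forms the additive combinations:
#' `SequenceScore = normPWM + normCBS` (range 0..2) and
#' `OverallScore = normKSP + SequenceScore` (range 0..3). By default the
#' candidate set is the intersection of the kinases scored by every
#' supplied scorer (the network typically knows more kinases than have
#' sequence models); `candidates = "union"` scores every kinase seen by
#' any scorer, treating the missing components as 0. Scorers not supplied
#' at all contribute 0 and are recorded in the `missing_scorers` attribute.
#'
#' @param ksp,pwm,cbs named numeric vectors of raw per-kinase scores; any
#'   may be NULL when that scorer is unavailable for the site.
#' @param candidates `"intersection"` or `"union"`.
#' @return a `score_vector`: data.table with columns `kinase_id`, raw and
#'   normalized columns per scorer, `sequence_score`, `overall_score`;
#'   attribute `missing_scorers` names the absent scorers.
#' @export
combine_scores <- function(ksp = NULL, pwm = NULL, cbs = NULL,
                           candidates = c("intersection", "union")) {
  candidates <- match.arg(candidates)
  supplied <- list(ksp = ksp, pwm = pwm, cbs = cbs)
  supplied <- supplied[!vapply(supplied, is.null, logical(1))]
  if (length(supplied) == 0L)
    stop("at least one scorer must be supplied")
  sets <- lapply(supplied, names)
  kin <- if (candidates == "intersection") Reduce(intersect, sets)
         else Reduce(union, sets)
  kin <- sort(kin)
  if (length(kin) == 0L)
    stop("no kinase is scored by all supplied scorers; ",
         "consider candidates = \"union\"")
  col <- function(which) {
    raw <- supplied[[which]]
    if (is.null(raw)) return(list(raw = rep(0, length(kin)),
                                  norm = rep(0, length(kin))))
    x <- stats::setNames(rep(0, length(kin)), kin)
    common <- intersect(kin, names(raw))
    x[common] <- raw[common]
    list(raw = as.numeric(x), norm = as.numeric(normalize_scores(x)))
  }
  k <- col("ksp"); p <- col("pwm"); cb <- col("cbs")
  out <- data.table::data.table(
    kinase_id = kin,
    ksp_raw = k$raw, ksp_norm = k$norm,
    pwm_raw = p$raw, pwm_norm = p$norm,
    cbs_raw = cb$raw, cbs_norm = cb$norm)
  out$sequence_score <- out$pwm_norm + out$cbs_norm
  out$overall_score <- out$ksp_norm + out$sequence_score
  missing <- setdiff(c("ksp", "pwm", "cbs"), names(supplied))
  data.table::setattr(out, "missing_scorers", missing)
  structure(out, class = c("score_vector", class(out)))
}

#' Rank kinases for one site under a chosen scoring mode
#'
#' @param scores a `score_vector` from [combine_scores()].
#' @param mode one of `"ksp"`, `"pwm"`, `"cbs"`, `"sequence"`, `"overall"`.
#' @param top_k maximum candidates.
#' @return data.table (`kinase_id`, `score`), descending, lexicographic
#'   tie-break.
#' @export
rank_kinases_overall <- function(scores,
                                 mode = c("overall", "sequence", "ksp",
                                          "pwm", "cbs"),
                                 top_k = 10L) {
  mode <- match.arg(mode)
  stopifnot(top_k >= 1L)
  colname <- switch(mode, ksp = "ksp_norm", pwm = "pwm_norm",
                    cbs = "cbs_norm", sequence = "sequence_score",
                    overall = "overall_score")
  if (mode %in% attr(scores, "missing_scorers"))
    stop("scorer '", mode, "' was not computed for this site")
  dt <- data.table::data.table(kinase_id = scores$kinase_id,
                               score = scores[[colname]])
  rank_candidates(dt, top_k)
}
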
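#' Fit the full kinase predictor from training data
#'
#' Convenience wrapper that builds every component from one pair table:
#' the integrated network and its bipartite affinity graph (network
#' scorer), the per-kinase position weight matrices and the
#' nearest-neighbour corpus (sequence scorers).
#'
#' @param pairs kinase-substrate pair table.
#' @param ppi optional PPI edge table merged into the network.
#' @param beta length-4 path-weight vector for the network score.
#' @param mode path semantics, `"simple"` or `"literal"`.
#' @param min_sites exclusive minimum distinct peptides for a kinase to
#'   get a sequence model; lower it on small synthetic corpora.
#' @param alpha PWM pseudocount.
#' @param background PWM background (`"pooled"`, `"uniform"` or vector).
#' @param k_fraction CBS neighbourhood fraction.
#' @return a `ksp_model` holding `network`, `affinity`, `pwms`, `corpus`
#'   and the fitting parameters.
#' @export
ksp_fit <- function(pairs, ppi = NULL, beta = ksp_default_beta(),
                    mode = "simple", min_sites = 15L, alpha = 0,
                    background = "pooled", k_fraction = 0.075) {
  net <- build_integrated_network(pairs, ppi)
  affinity <- build_affinity_graph(net, beta, mode)
  pwms <- train_pwms(pairs, min_sites = min_sites, alpha = alpha,
                     background = background)
  corpus <- build_cbs_corpus(pairs)
  structure(list(network = net, affinity = affinity, pwms = pwms,
                 corpus = corpus, beta = beta, mode = mode,
                 k_fraction = k_fraction),
            class = "ksp_model")
}

#' @export
print.ksp_model <- function(x, ...) {
  cat("<ksp_model>\n")
  print(x$network)
  print(x$affinity)
  cat(sprintf("  %d sequence models, corpus of %d peptides\n",
              length(x$pwms), nrow(x$corpus)))
  invisible(x)
}

model_raw_scores <- function(model, site) {
  kin_net <- model$affinity$kinases
  ksp <- NULL
  if (!is.null(site$substrate_id) &&
      site$substrate_id %in% model$affinity$proteins) {
    ksp <- stats::setNames(rep(0, length(kin_net)), kin_net)
    hits <- model$affinity$edges[
      model$affinity$edges$protein_id == site$substrate_id]
    ksp[hits$kinase_id] <- hits$score
  }
  kin_seq <- names(model$pwms)
  pwm <- stats::setNames(
    vapply(model$pwms, pwm_score, numeric(1), peptide = site$peptide),
    kin_seq)
  cbs_nb <- suppressWarnings(
    cbs_score(model$corpus, site$peptide, model$k_fraction))
  cbs <- stats::setNames(rep(0, length(kin_seq)), kin_seq)
  common <- intersect(kin_seq, names(cbs_nb))
  cbs[common] <- cbs_nb[common]
  list(ksp = ksp, pwm = pwm, cbs = cbs)
}

#' Score one phosphosite with every scorer and combine
#'
#' Computes raw network, PWM and CBS scores for the site, min-max
#' normalizes each over its candidate kinases and forms SequenceScore and
#' OverallScore. When the substrate protein is absent from the network,
#' the network scorer is dropped and the result carries
#' `attr(, "missing_scorers")` including `"ksp"` (sequence-only ranking
#' rather than failure).
#'
#' @param model a `ksp_model`.
#' @param site a `phosphosite` or a list/row with `substrate_id` and
#'   `peptide`.
#' @param candidates candidate-set policy, see [combine_scores()].
#' @return a `score_vector`.
#' @export
ksp_score_site <- function(model, site,
                           candidates = c("intersection", "union")) {
  raw <- model_raw_scores(model, site)
  combine_scores(ksp = raw$ksp, pwm = raw$pwm, cbs = raw$cbs,
                 candidates = match.arg(candidates))
}

#' Rank candidate kinases for one phosphosite
#'
#' @inheritParams ksp_score_site
#' @param mode scoring mode, see [rank_kinases_overall()].
#' @param top_k maximum candidates.
#' @return data.table (`kinase_id`, `score`).
#' @export
ksp_predict <- function(model, site, mode = "overall", top_k = 10L,
                        candidates = "intersection") {
  if (mode == "ksp") {
    return(rank_kinases_network(model$affinity, site, top_k))
  }
  sv <- ksp_score_site(model, site, candidates)
  rank_kinases_overall(sv, mode, top_k)
}

#' Model factory for the cross-validation harness
#'
#' Returns a `scorer` suitable for [kfold_topk_accuracy()]: called with a
#' training pair table it fits a [ksp_fit()] model and returns a function
#' mapping a test site row to its ordered candidate kinases.
#'
#' @param mode scoring mode passed to [ksp_predict()].
#' @param candidates candidate-set policy.
#' @param ... further arguments for [ksp_fit()] (e.g. `ppi`, `min_sites`).
#' @return function(train_pairs) -> function(site) -> data.table ranking.
#' @export
ksp_scorer <- function(mode = "overall", candidates = "intersection", ...) {
  force(mode); force(candidates)
  dots <- list(...)
  function(train_pairs) {
    model <- do.call(ksp_fit, c(list(pairs = train_pairs), dots))
    function(site) {
      n_kin <- max(length(model$pwms), length(model$affinity$kinases))
      ksp_predict(model, site, mode = mode, top_k = n_kin,
                  candidates = candidates)
    }
  }
}

#' Score a table of sites and emit the ranked prediction table
#'
#' @param model a `ksp_model`.
#' @param sites data.frame/data.table with `substrate_id` and `peptide`
#'   (and optionally `position` used for the site label).
#' @param mode scoring mode.
#' @param top_k candidates per site.
#' @param candidates candidate-set policy.
#' @return data.table with site_id, rank, kinase and all raw/normalized
#'   and combined scores.
#' @export
ksp_predict_table <- function(model, sites, mode = "overall", top_k = 10L,
                              candidates = "intersection") {
  out <- vector("list", NROW(sites))
  for (i in seq_len(NROW(sites))) {
    site <- take_rows(sites, i)
    site_id <- paste0(site$substrate_id,
                      if (!is.null(site$position)) paste0("_", site$position))
    sv <- ksp_score_site(model, site, candidates)
    rk <- rank_kinases_overall(sv, mode, top_k)
    sel <- data.table::as.data.table(sv)[match(rk$kinase_id, sv$kinase_id)]
    out[[i]] <- data.table::data.table(
      site_id = site_id, rank = seq_len(nrow(rk)), kinase = rk$kinase_id,
      sel[, c("ksp_raw", "ksp_norm", "pwm_raw", "pwm_norm", "cbs_raw",
              "cbs_norm", "sequence_score", "overall_score")],
      mode = mode)
  }
  data.table::rbindlist(out)
}
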
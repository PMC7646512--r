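peptide_chars <- function(peptide) {
  if (nchar(peptide) != WINDOW_LEN)
    stop("peptide must have exactly ", WINDOW_LEN, " characters")
  strsplit(toupper(peptide), "")[[1]]
}

#' Amino-acid background frequencies of a peptide set
#'
#' Pools the non-padding residues of all peptides; non-standard letters
#' (X, U, B, ...) are ignored. Used as the default background of
#' [build_pwm()] so the log-likelihoods reflect the compositional bias of
#' phosphosite flanks rather than a uniform proteome.
#'
#' @param peptides character vector of 15-mers.
#' @return named numeric vector over the 20 standard amino acids, summing
#'   to 1.
#' @export
pooled_background <- function(peptides) {
  ch <- unlist(strsplit(toupper(peptides), ""))
  ch <- ch[ch %in% AA20]
  if (length(ch) == 0L) return(uniform_background())
  tab <- table(factor(ch, levels = AA20))
  freqs <- as.numeric(tab) / sum(tab)
  # zero frequencies would put -Inf in every log-likelihood; smooth minimally
  if (any(freqs == 0)) {
    freqs <- (as.numeric(tab) + 0.5) / (sum(tab) + 10)
  }
  stats::setNames(freqs, AA20)
}

#' Uniform 1/20 amino-acid background
#' @return named numeric vector, each entry 0.05.
#' @export
uniform_background <- function() stats::setNames(rep(1 / 20, 20), AA20)

PWM_FLOOR <- -10

#' Build a position weight matrix from aligned site peptides
#'
#' Counts residue occurrences per position over the aligned 15-mers (the
#' position frequency matrix), converts to a profile by dividing by the
#' number of observations, and takes base-2 log likelihoods against the
#' background:
#' `M[k, j] = log2((count[k, j] + alpha) / ((N_j + 20 * alpha) * b[k]))`
#' where `N_j` counts peptides with a real (non-padding) residue at
#' position j. With `alpha = 0` an unobserved cell would be `log2(0)`;
#' such cells are floored at -10 so scores stay finite.
#'
#' @param peptides character vector of 15-mers (>= 1).
#' @param background named frequency vector over the 20 amino acids
#'   (default: pooled from `peptides`); must sum to 1.
#' @param alpha non-negative pseudocount added to every cell.
#' @param kinase_id optional label stored on the model.
#' @return a `pwm_model`: list with `matrix` (20 x 15 log2 likelihoods,
#'   rows = amino acids, columns = positions -7..+7), `background`,
#'   `alpha`, `n_sites`, `kinase_id`.
#' @export
build_pwm <- function(peptides, background = NULL, alpha = 0,
                      kinase_id = NA_character_) {
  if (length(peptides) == 0L) stop("cannot build a PWM from zero peptides")
  if (alpha < 0) stop("alpha must be non-negative")
  if (is.null(background)) background <- pooled_background(peptides)
  if (!all(AA20 %in% names(background)))
    stop("background must name all 20 standard amino acids")
  background <- background[AA20]
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  mat <- vapply(peptides, peptide_chars, character(WINDOW_LEN))
  counts <- matrix(0L, nrow = 20, ncol = WINDOW_LEN,
                   dimnames = list(AA20, as.character(-7:7)))
  for (j in seq_len(WINDOW_LEN)) {
    tab <- table(factor(mat[j, ], levels = AA20))
    counts[, j] <- as.integer(tab)
  }
  n_obs <- colSums(counts)  # padding and non-standard letters excluded
  m <- matrix(PWM_FLOOR, nrow = 20, ncol = WINDOW_LEN,
              dimnames = dimnames(counts))
  for (j in seq_len(WINDOW_LEN)) {
    denom <- (n_obs[j] + 20 * alpha) * background
    num <- counts[, j] + alpha
    ok <- num > 0 & denom > 0
    m[ok, j] <- log2(num[ok] / denom[ok])
  }
  structure(list(matrix = m, background = background, alpha = alpha,
                 n_sites = length(peptides), kinase_id = kinase_id),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model %s: N = %d sites, alpha = %g>\n",
              x$kinase_id, x$n_sites, x$alpha))
  invisible(x)
}

#' Score a peptide against a position weight matrix
#'
#' Sums the matrix entry of the residue observed at each of the 15
#' positions. Padding and non-standard residues contribute 0 at their
#' positions (they are skipped, not penalized).
#'
#' @param model a `pwm_model`.
#' @param peptide 15-mer.
#' @return numeric score.
#' @export
pwm_score <- function(model, peptide) {
  ch <- peptide_chars(peptide)
  idx <- match(ch, AA20)
  ok <- !is.na(idx)
  sum(model$matrix[cbind(idx[ok], which(ok))])
}

#' Train per-kinase PWMs from a pair table
#'
#' Applies the trainable-kinase filter, then fits one PWM per retained
#' kinase. With `background = "pooled"` a single background pooled over
#' all retained kinases' peptides is shared by every model.
#'
#' @param pairs pair table.
#' @param min_sites exclusive minimum distinct peptides per kinase.
#' @param alpha pseudocount.
#' @param background `"pooled"`, `"uniform"`, or a named frequency vector.
#' @return named list of `pwm_model`s.
#' @export
train_pwms <- function(pairs, min_sites = 15L, alpha = 0,
                       background = "pooled") {
  sites <- filter_trainable_kinases(pairs, min_sites)
  if (length(sites) == 0L)
    stop("no kinase has more than ", min_sites, " distinct site peptides")
  bg <- if (is.character(background)) {
    switch(match.arg(background, c("pooled", "uniform")),
           pooled = pooled_background(unlist(sites, use.names = FALSE)),
           uniform = uniform_background())
  } else background
  mapply(function(peps, kid) build_pwm(peps, bg, alpha, kinase_id = kid),
         sites, names(sites), SIMPLIFY = FALSE)
}

# ---- substitution matrices -------------------------------------------------

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comments, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path matrix file.
#' @return integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  rownames(m) <- vapply(rows, `[`, character(1), 1L)
  colnames(m) <- hdr
  if (!isTRUE(all.equal(m[rownames(m), rownames(m)],
                        t(m[rownames(m), rownames(m)]))))
    stop("substitution matrix is not symmetric: ", path)
  m
}

blosum_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#' @return integer matrix (NCBI BLOSUM62, half-bit scores).
#' @export
blosum62 <- function() {
  if (is.null(blosum_cache$m))
    blosum_cache$m <- read_substitution_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "kspnet",
                  mustWork = TRUE))
  blosum_cache$m
}

#' Substitution-matrix similarity of two site peptides
#'
#' Position-wise sum of substitution scores over the 15 aligned positions.
#' If either peptide has fewer than 7 real flanking residues on either side
#' (i.e. contains any padding character) the similarity is defined as 0.
#' Residues absent from the matrix contribute 0 at their position.
#'
#' @param s1,s2 15-mers.
#' @param matrix substitution matrix (default [blosum62()]).
#' @return integer-valued similarity score.
#' @export
blosum_similarity <- function(s1, s2, matrix = blosum62()) {
  c1 <- peptide_chars(s1)
  c2 <- peptide_chars(s2)
  if (any(c1 == PAD_CHAR) || any(c2 == PAD_CHAR)) return(0L)
  i <- match(c1, rownames(matrix))
  j <- match(c2, colnames(matrix))
  ok <- !is.na(i) & !is.na(j)
  as.integer(sum(matrix[cbind(i[ok], j[ok])]))
}

#' Build the nearest-neighbour training corpus for CBS scoring
#'
#' @param pairs pair table; peptides are deduplicated within each kinase.
#' @return a `cbs_corpus`: data.table with `peptide`, `kinase_id`.
#' @export
build_cbs_corpus <- function(pairs) {
  dt <- unique(data.table::as.data.table(pairs)[, c("peptide", "kinase_id")])
  data.table::setorder(dt, peptide, kinase_id)
  structure(dt, class = c("cbs_corpus", class(dt)))
}

cbs_k <- function(n, k_fraction) {
  # half-up rounding, never below 1
  max(1L, as.integer(floor(k_fraction * n + 0.5)))
}

#' Nearest-neighbour kinase scores for a query peptide (CBS)
#'
#' Finds the `k = max(1, round(k_fraction * corpus size))` corpus peptides
#' most similar to the query under [blosum_similarity()] and returns, per
#' kinase, the fraction of those neighbours it catalyzes. Ties at the
#' cut-off are broken lexicographically by (peptide, kinase_id) so the
#' neighbourhood is deterministic. A query with truncated flanks has
#' similarity 0 to everything; its neighbourhood is then decided purely by
#' the tie-break and a warning is emitted.
#'
#' @param corpus a `cbs_corpus`.
#' @param peptide query 15-mer.
#' @param k_fraction neighbourhood size as a fraction of the corpus
#'   (default 0.075, i.e. 7.5 percent).
#' @param matrix substitution matrix.
#' @return named numeric vector of per-kinase fractions in `[0, 1]`,
#'   covering the kinases present in the neighbourhood.
#' @export
cbs_score <- function(corpus, peptide, k_fraction = 0.075,
                      matrix = blosum62()) {
  n <- nrow(corpus)
  if (n == 0L) stop("empty CBS corpus")
  if (k_fraction <= 0 || k_fraction > 1)
    stop("k_fraction must be in (0, 1]")
  qc <- peptide_chars(peptide)
  if (any(qc == PAD_CHAR))
    warning("query peptide has truncated flanks; all similarities are 0")
  sims <- vapply(corpus$peptide, blosum_similarity, numeric(1),
                 s2 = peptide, matrix = matrix, USE.NAMES = FALSE)
  k <- cbs_k(n, k_fraction)
  ord <- order(-sims, corpus$peptide, corpus$kinase_id)
  nb <- corpus$kinase_id[ord[seq_len(k)]]
  tab <- table(nb)
  stats::setNames(as.numeric(tab) / k, names(tab))
}

#' Rank kinases for a query peptide by the two sequence scorers
#'
#' @param models named list of `pwm_model`s.
#' @param corpus a `cbs_corpus`.
#' @param peptide query 15-mer.
#' @param top_k maximum candidates per ranking.
#' @param k_fraction CBS neighbourhood fraction.
#' @return list with elements `pwm` and `cbs`, each a data.table
#'   (`kinase_id`, `score`) in descending score order, ties lexicographic.
#' @export
rank_kinases_sequence <- function(models, corpus, peptide, top_k = 10L,
                                  k_fraction = 0.075) {
  stopifnot(length(models) >= 1L, top_k >= 1L)
  pwm <- data.table::data.table(
    kinase_id = names(models),
    score = vapply(models, pwm_score, numeric(1), peptide = peptide))
  cbs <- cbs_score(corpus, peptide, k_fraction)
  cbs <- data.table::data.table(kinase_id = names(cbs),
                                score = as.numeric(cbs))
  list(pwm = rank_candidates(pwm, top_k),
       cbs = rank_candidates(cbs, top_k))
}

#' Write a PWM model as TSV plus a JSON sidecar
#'
#' The TSV holds the 20 x 15 matrix (rows = amino acids, columns =
#' positions -7..+7); `<path>.json` records kinase_id, n_sites, alpha and
#' the background frequencies.
#'
#' @param model a `pwm_model`.
#' @param path TSV output path.
#' @export
write_pwm <- function(model, path) {
  dt <- data.table::as.data.table(model$matrix, keep.rownames = "aa")
  data.table::fwrite(dt, path, sep = "\t")
  meta <- list(kinase_id = model$kinase_id, n_sites = model$n_sites,
               alpha = model$alpha, background = as.list(model$background))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a PWM model written by [write_pwm()]
#' @param path TSV path (expects `<path>.json` alongside).
#' @return a `pwm_model`.
#' @export
read_pwm <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  colnames(m) <- as.character(-7:7)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(matrix = m[AA20, , drop = FALSE],
                 background = unlist(meta$background)[AA20],
                 alpha = meta$alpha, n_sites = meta$n_sites,
                 kinase_id = meta$kinase_id),
            class = "pwm_model")
}
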
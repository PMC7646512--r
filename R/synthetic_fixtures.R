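# typical vertebrate amino-acid composition (approximate UniProt averages)
AA_COMPOSITION <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)

#' Specification for the synthetic benchmark generator
#'
#' Describes a world with planted structure: each substrate belongs to one
#' true kinase, kinase-substrate links carry the site counts, bystander
#' proteins are wired by preferential attachment (mimicking the heavy-tailed
#' degree distribution of real interaction networks), and each kinase
#' phosphorylates peptides drawn from its own position-specific motif.
#'
#' `motif_sharpness` controls how peaked the per-position residue
#' distributions are: each motif column is drawn from a Dirichlet with
#' concentration `20 * background / motif_sharpness`, so large values give
#' near-deterministic consensus motifs and values near zero give columns
#' indistinguishable from background.
#'
#' @param n_kinases number of kinases (default 20, so that a top-10 cut is
#'   a genuine cut).
#' @param n_substrates number of substrate proteins; the default gives
#'   roughly 1.5 sites per kinase-substrate pair, so held-out splits
#'   remove a realistic share of direct network edges.
#' @param n_bystanders number of proteins with PPI edges but no sites.
#' @param sites_per_kinase planted sites per kinase.
#' @param n_negatives number of non-phospho S/T/Y windows generated.
#' @param ppi_attachment edges added per node by preferential attachment.
#' @param attachment_power preferential-attachment exponent.
#' @param motif_sharpness Dirichlet peakedness (> 0), see above.
#' @param background amino-acid frequency vector (sums to 1).
#' @param seed integer seed; all generators are pure functions of the spec.
#' @return a `fixture_spec` (validated named list).
#' @export
fixture_spec <- function(n_kinases = 20L, n_substrates = 400L,
                         n_bystanders = 40L, sites_per_kinase = 30L,
                         n_negatives = 200L, ppi_attachment = 2L,
                         attachment_power = 1, motif_sharpness = 0.5,
                         background = AA_COMPOSITION, seed = 42L) {
  spec <- list(n_kinases = as.integer(n_kinases),
               n_substrates = as.integer(n_substrates),
               n_bystanders = as.integer(n_bystanders),
               sites_per_kinase = as.integer(sites_per_kinase),
               n_negatives = as.integer(n_negatives),
               ppi_attachment = as.integer(ppi_attachment),
               attachment_power = attachment_power,
               motif_sharpness = motif_sharpness,
               background = background[AA20] / sum(background[AA20]),
               seed = as.integer(seed))
  stopifnot(spec$n_kinases >= 1L, spec$n_substrates >= 1L,
            spec$n_bystanders >= 0L, spec$sites_per_kinase >= 1L,
            spec$motif_sharpness > 0, all(spec$background > 0),
            !anyNA(spec$background))
  structure(spec, class = "fixture_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

sample_motif <- function(spec) {
  conc <- 20 * spec$background / spec$motif_sharpness
  pfm <- vapply(seq_len(WINDOW_LEN), function(j) rdirichlet1(conc),
                numeric(20))
  rownames(pfm) <- AA20
  colnames(pfm) <- as.character(-7:7)
  pfm
}

sample_peptide <- function(pfm, centre) {
  ch <- vapply(seq_len(WINDOW_LEN), function(j) {
    sample(AA20, 1L, prob = pfm[, j])
  }, character(1))
  ch[8L] <- centre
  paste0(ch, collapse = "")
}

kinase_centre <- function() {
  # ~20% tyrosine kinases; serine favoured over threonine otherwise
  if (stats::runif(1) < 0.2) function() "Y"
  else function() sample(c("S", "T"), 1L, prob = c(0.7, 0.3))
}

#' Generate per-kinase motif peptides and non-phospho windows
#'
#' Draws one position frequency matrix per kinase (see [fixture_spec()]),
#' samples `sites_per_kinase` positive 15-mers per kinase from its motif
#' (centre fixed to the kinase's S/T/Y preference), and samples
#' `n_negatives` background 15-mers with an S/T/Y centre as the
#' non-phospho negative pool.
#'
#' @param spec a `fixture_spec`.
#' @return list with `positives` (named list kinase -> peptide vector),
#'   `negatives` (character vector) and `pfms` (named list of 20 x 15
#'   probability matrices).
#' @export
simulate_peptides <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, {
    kin <- sprintf("K%02d", seq_len(spec$n_kinases))
    pfms <- list(); positives <- list()
    for (k in kin) {
      pfm <- sample_motif(spec)
      centre <- kinase_centre()
      positives[[k]] <- vapply(seq_len(spec$sites_per_kinase), function(i) {
        sample_peptide(pfm, centre())
      }, character(1))
      pfms[[k]] <- pfm
    }
    negatives <- vapply(seq_len(spec$n_negatives), function(i) {
      ch <- sample(AA20, WINDOW_LEN, replace = TRUE,
                   prob = spec$background)
      ch[8L] <- sample(c("S", "T", "Y"), 1L, prob = c(0.5, 0.3, 0.2))
      paste0(ch, collapse = "")
    }, character(1))
    list(positives = positives, negatives = negatives, pfms = pfms)
  })
}

#' Generate a synthetic kinase-substrate network with planted links
#'
#' Assigns each substrate to one true kinase, distributes each kinase's
#' planted sites over its own substrates (distinct positions within a
#' substrate), and builds a PPI layer with two ingredients: (i) functional
#' modules - each substrate interacts with about two other substrates of
#' the same kinase, mimicking the complex/pathway clustering of real
#' interactomes that path-based affinity scores rely on; and (ii) a global
#' preferential-attachment background over all proteins, which keeps the
#' merged network connected and gives it the heavy-tailed degree
#' distribution of real networks. Site peptides are drawn from the
#' per-kinase motifs of [simulate_peptides()] with the same seed, so the
#' sequence and network signals agree.
#'
#' @param spec a `fixture_spec`.
#' @return list with `pairs` (pair table as read by
#'   [read_kinase_substrate_table()]), `ppi` (edge table), `truth`
#'   (data.table substrate_id, kinase_id), `peptides` (the
#'   [simulate_peptides()] output).
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  peps <- simulate_peptides(spec)
  with_seed(spec$seed + 2L, {
    kin <- sprintf("K%02d", seq_len(spec$n_kinases))
    subs <- sprintf("P%03d", seq_len(spec$n_substrates))
    bys <- if (spec$n_bystanders > 0)
      sprintf("B%03d", seq_len(spec$n_bystanders)) else character(0)
    # each substrate belongs to one kinase; every kinase gets >= 1 substrate
    owner <- sample(rep_len(kin, spec$n_substrates))
    truth <- data.table::data.table(substrate_id = subs, kinase_id = owner)
    rows <- list()
    for (k in kin) {
      mine <- subs[owner == k]
      assign_to <- sample(mine, spec$sites_per_kinase, replace = TRUE)
      pos <- integer(spec$sites_per_kinase)
      for (s in unique(assign_to)) {
        idx <- which(assign_to == s)
        pos[idx] <- sample(8:800, length(idx))
      }
      rows[[k]] <- data.table::data.table(
        kinase_id = k, substrate_id = assign_to, position = pos,
        residue = substr(peps$positives[[k]], 8L, 8L),
        peptide = peps$positives[[k]])
    }
    pairs <- data.table::rbindlist(rows)
    pairs <- pairs[!duplicated(pairs[, c("kinase_id", "substrate_id",
                                         "position")])]
    # substrates that drew no site stay in the PPI layer only
    truth <- truth[truth$substrate_id %in% pairs$substrate_id]
    nodes <- c(kin, subs, bys)
    g <- igraph::sample_pa(length(nodes), power = spec$attachment_power,
                           m = spec$ppi_attachment, directed = FALSE)
    igraph::V(g)$name <- sample(nodes)
    el <- igraph::as_edgelist(g)
    # functional modules: substrates of one kinase interact with each other
    mod <- list()
    for (k in kin) {
      mine <- subs[owner == k]
      if (length(mine) < 2L) next
      partners <- do.call(rbind, lapply(mine, function(s) {
        cbind(s, sample(setdiff(mine, s), min(2L, length(mine) - 1L)))
      }))
      mod[[k]] <- partners
    }
    el <- rbind(el, do.call(rbind, mod))
    keep <- el[, 1] != el[, 2]
    ppi <- unique(data.table::data.table(
      protein_a = pmin(el[keep, 1], el[keep, 2]),
      protein_b = pmax(el[keep, 1], el[keep, 2])))
    list(pairs = pairs, ppi = ppi, truth = truth, peptides = peps)
  })
}

#' Write a generated fixture to disk in the standard dialects
#'
#' Emits `pairs.tsv` (plain dialect), `ppi.tsv`, `truth.tsv` and
#' `negatives.txt` under `dir` so evaluation runs are self-verifying.
#'
#' @param fixture output of [simulate_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kinase_substrate_table(fixture$pairs, file.path(dir, "pairs.tsv"))
  data.table::fwrite(fixture$ppi, file.path(dir, "ppi.tsv"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t")
  writeLines(fixture$peptides$negatives, file.path(dir, "negatives.txt"))
  invisible(dir)
}
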
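#' @importFrom data.table fread fwrite data.table as.data.table setnames :=
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_CHAR <- "_"
WINDOW_FLANK <- 7L
WINDOW_LEN <- 15L

#' Construct a phosphosite record
#'
#' A phosphosite is one experimentally observed phosphorylated residue,
#' described by its substrate accession, 1-based position, residue (S/T/Y)
#' and the 15-mer window of +/- 7 flanking residues, padded with `_` where
#' the window runs past a protein terminus.
#'
#' @param substrate_id protein accession string.
#' @param position 1-based residue index.
#' @param residue one of "S", "T", "Y".
#' @param peptide 15-character window; centre character must equal `residue`.
#' @return a `phosphosite` object (named list).
#' @export
phosphosite <- function(substrate_id, position, residue, peptide) {
  peptide <- toupper(peptide)
  residue <- toupper(residue)
  stopifnot(is.character(substrate_id), length(substrate_id) == 1L)
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("position must be a 1-based integer index")
  if (!residue %in% c("S", "T", "Y"))
    stop("residue must be one of S, T, Y, got '", residue, "'")
  if (nchar(peptide) != WINDOW_LEN)
    stop("peptide must have exactly ", WINDOW_LEN, " characters")
  if (substr(peptide, 8L, 8L) != residue)
    stop("peptide centre '", substr(peptide, 8L, 8L),
         "' does not match residue '", residue, "'")
  ch <- strsplit(peptide, "")[[1]]
  pad <- ch == PAD_CHAR
  if (any(pad)) {
    # padding may only form a contiguous prefix and/or suffix
    core <- range(which(!pad))
    if (any(pad[core[1]:core[2]]))
      stop("padding '_' must be a contiguous prefix and/or suffix")
  }
  structure(list(substrate_id = substrate_id, position = position,
                 residue = residue, peptide = peptide),
            class = "phosphosite")
}

#' @export
print.phosphosite <- function(x, ...) {
  cat(sprintf("<phosphosite %s %s%d %s>\n",
              x$substrate_id, x$residue, x$position, x$peptide))
  invisible(x)
}

#' Extract the 15-mer window around a residue
#'
#' Returns the closed interval `[position - 7, position + 7]` of `sequence`,
#' padded with `_` where the window exceeds the sequence bounds. The centre
#' residue must be S, T or Y.
#'
#' @param sequence amino-acid string.
#' @param position 1-based index of the phosphorylated residue.
#' @return a 15-character peptide with the target residue at position 8.
#' @examples
#' extract_window("SAAAAAAAA", 1)   # "_______SAAAAAAA"
#' @export
extract_window <- function(sequence, position) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n)
    stop("position ", position, " outside sequence of length ", n)
  centre <- substr(sequence, position, position)
  if (!centre %in% c("S", "T", "Y"))
    stop("residue at position ", position, " is '", centre,
         "', expected S, T or Y")
  lo <- position - WINDOW_FLANK
  hi <- position + WINDOW_FLANK
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep(PAD_CHAR, left_pad), core, strrep(PAD_CHAR, right_pad))
}

# fread wrapper reading gzip through R's own connection support, so no
# optional dependency is needed for .gz input
fread_any <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    fread(text = readLines(con), ...)
  } else {
    fread(path, ...)
  }
}

parse_mod_rsd <- function(x) {
  # "S15" -> list(residue = "S", position = 15L)
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)$", x))[[1]]
  if (length(m) != 3L) return(NULL)
  list(residue = toupper(m[2]), position = as.integer(m[3]))
}

#' Read a kinase-substrate pair table
#'
#' Two tab-separated dialects are supported. `"psp"` follows the
#' PhosphoSitePlus convention with columns `KINASE`, `SUB_ACC_ID`,
#' `MOD_RSD` (e.g. "S15") and `SITE_+/-7_AA` (15-mer, modified residue in
#' lower case). `"plain"` is headerless `kinase<TAB>substrate<TAB>position
#' <TAB>peptide`. Gzip input is read transparently. Malformed rows (missing
#' fields, wrong peptide length, centre not S/T/Y) are skipped and counted;
#' exact duplicate (kinase, substrate, position) triples are removed.
#'
#' @param path file path (optionally gzip-compressed).
#' @param dialect `"psp"` or `"plain"`.
#' @return a `data.table` with columns `kinase_id`, `substrate_id`,
#'   `position`, `residue`, `peptide`; attributes `n_skipped` and
#'   `n_duplicates` record dropped rows.
#' @export
read_kinase_substrate_table <- function(path, dialect = c("psp", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "psp") {
    dt <- fread_any(path, sep = "\t", header = TRUE, colClasses = "character")
    need <- c("KINASE", "SUB_ACC_ID", "MOD_RSD", "SITE_+/-7_AA")
    if (!all(need %in% names(dt)))
      stop("psp dialect requires columns: ", paste(need, collapse = ", "))
    raw <- data.table(kinase_id = dt[["KINASE"]],
                      substrate_id = dt[["SUB_ACC_ID"]],
                      mod_rsd = dt[["MOD_RSD"]],
                      peptide = dt[["SITE_+/-7_AA"]])
  } else {
    dt <- fread_any(path, sep = "\t", header = FALSE, colClasses = "character")
    if (ncol(dt) < 4L) stop("plain dialect requires 4 tab-separated columns")
    raw <- data.table(kinase_id = dt[[1]], substrate_id = dt[[2]],
                      mod_rsd = paste0("?", dt[[3]]), peptide = dt[[4]],
                      position_plain = dt[[3]])
  }
  rows <- vector("list", nrow(raw))
  n_skip <- 0L
  for (i in seq_len(nrow(raw))) {
    r <- raw[i]
    pep <- r$peptide
    ok <- !is.na(r$kinase_id) && nzchar(r$kinase_id) &&
      !is.na(r$substrate_id) && nzchar(r$substrate_id) &&
      !is.na(pep) && nchar(pep) == WINDOW_LEN
    pos <- NA_integer_
    res <- NA_character_
    if (ok) {
      if (dialect == "psp") {
        mr <- parse_mod_rsd(r$mod_rsd)
        if (is.null(mr)) ok <- FALSE else { pos <- mr$position; res <- mr$residue }
      } else {
        pos <- suppressWarnings(as.integer(r$position_plain))
        if (is.na(pos) || pos < 1L) ok <- FALSE
        res <- toupper(substr(pep, 8L, 8L))
      }
    }
    if (ok) {
      centre <- toupper(substr(pep, 8L, 8L))
      ok <- centre %in% c("S", "T", "Y") && centre == res
    }
    if (!ok) { n_skip <- n_skip + 1L; next }
    rows[[i]] <- data.table(kinase_id = r$kinase_id,
                            substrate_id = r$substrate_id,
                            position = pos, residue = res,
                            peptide = toupper(pep))
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L)
    stop("no valid kinase-substrate rows in ", path,
         " (", n_skip, " skipped)")
  dup <- duplicated(out[, c("kinase_id", "substrate_id", "position")])
  n_dup <- sum(dup)
  out <- out[!dup]
  if (n_skip > 0L)
    message(n_skip, " malformed row(s) skipped while reading ", path)
  data.table::setattr(out, "n_skipped", n_skip)
  data.table::setattr(out, "n_duplicates", n_dup)
  out[]
}

#' Write a kinase-substrate pair table in the plain dialect
#'
#' @param pairs data.table as returned by [read_kinase_substrate_table()].
#' @param path output path (".gz" suffix compresses).
#' @export
write_kinase_substrate_table <- function(pairs, path) {
  fwrite(pairs[, c("kinase_id", "substrate_id", "position", "peptide")],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Expects two accession columns in a tab-separated file (HPRD-style),
#' with or without a header. Self-loops are dropped, edges are stored
#' undirected with `protein_a <= protein_b` lexicographically, and
#' duplicate edges are removed.
#'
#' @param path file path (optionally gzip-compressed).
#' @param header whether the first line is a header.
#' @return a `data.table` with columns `protein_a`, `protein_b`.
#' @export
read_ppi_table <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread_any(path, sep = "\t", header = header, colClasses = "character")
  if (ncol(dt) < 2L) stop("PPI table requires at least 2 columns")
  a <- dt[[1]]; b <- dt[[2]]
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- unique(data.table(protein_a = lo, protein_b = hi))
  if (nrow(out) == 0L) stop("no valid PPI edges in ", path)
  out[]
}

#' Read protein sequences from a FASTA file
#'
#' Minimal FASTA reader returning a named character vector keyed by the
#' first whitespace-delimited token of each header. Gzip supported.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0,
                 character(1), collapse = "")
  stats::setNames(toupper(seqs), ids)
}

#' Select kinases with enough distinct sites to train sequence models
#'
#' Keeps only kinases with strictly more than `min_sites` distinct site
#' peptides; within each kinase exact duplicate peptides are removed first.
#' The default threshold mirrors the "more than 15 p-sites" rule used when
#' fitting per-kinase motif models.
#'
#' @param pairs deduplicated pair table.
#' @param min_sites exclusive lower bound on the per-kinase site count.
#' @return named list mapping kinase_id to its character vector of peptides.
#' @export
filter_trainable_kinases <- function(pairs, min_sites = 15L) {
  peps <- lapply(split(pairs$peptide, pairs$kinase_id), unique)
  peps <- peps[vapply(peps, length, integer(1)) > min_sites]
  peps[order(names(peps))]
}
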
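#' Protease cleavage rules
#'
#' Trypsin cleaves C-terminal to K/R and, by the common search-engine
#' convention, not when the next residue is proline. Glu-C (V8, bicarbonate
#' conditions) cleaves C-terminal to E only; proline blocking is off by
#' default for Glu-C, matching common defaults. Both flags are exposed.
#'
#' @param name Enzyme label.
#' @param cleaves_after Character vector of residue letters.
#' @param blocked_by_next_proline Suppress cleavage before P?
#' @return An `enzyme_rule` object.
#' @export
enzyme_rule <- function(name, cleaves_after, blocked_by_next_proline = FALSE) {
  stopifnot(length(cleaves_after) >= 1L)
  structure(list(name = name, cleaves_after = cleaves_after,
                 blocked_by_next_proline = isTRUE(blocked_by_next_proline)),
            class = "enzyme_rule")
}

#' @rdname enzyme_rule
#' @export
enzyme_trypsin <- function(blocked_by_next_proline = TRUE)
  enzyme_rule("trypsin", c("K", "R"), blocked_by_next_proline)

#' @rdname enzyme_rule
#' @export
enzyme_glu_c <- function(blocked_by_next_proline = FALSE)
  enzyme_rule("glu-c", "E", blocked_by_next_proline)

#' Cleavage positions for a set of enzymes
#'
#' @param protein Protein sequence string.
#' @param rules List of [enzyme_rule()]s.
#' @return Sorted integer positions i such that a cut falls between
#'   residues i and i + 1 (the protein C-terminus is not included).
#' @keywords internal
cleavage_sites <- function(protein, rules) {
  s <- strsplit(protein, "")[[1]]
  n <- length(s)
  sites <- integer()
  for (r in rules) {
    hit <- which(s %in% r$cleaves_after)
    hit <- hit[hit < n]
    if (r$blocked_by_next_proline) hit <- hit[s[hit + 1L] != "P"]
    sites <- union(sites, hit)
  }
  sort(sites)
}

#' In-silico digestion with missed cleavages
#'
#' Digests a protein with one or more proteases applied together (the
#' dual Glu-C + trypsin digest is the default). The missed-cleavage budget
#' is shared over the union of both enzymes' cleavage sites.
#'
#' @param protein Protein sequence string (non-empty).
#' @param rules List of [enzyme_rule()]s.
#' @param max_missed Maximum number of internal cleavage sites retained.
#' @return A data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, ordered by `start` then `end`.
#' @examples
#' digest("TKPREEQYNSTYRVVSVK", max_missed = 2)
#' @export
digest <- function(protein, rules = list(enzyme_glu_c(), enzyme_trypsin()),
                   max_missed = 2L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) == 0L) stop("protein sequence must be non-empty")
  stopifnot(max_missed >= 0L)
  sites <- cleavage_sites(protein, rules)
  bounds <- c(0L, sites, nchar(protein))  # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j + 1L], j - i)
    }
  }
  m <- do.call(rbind, out)
  m <- unique(m)
  df <- data.frame(
    sequence = substring(protein, m[, 1], m[, 2]),
    start = m[, 1], end = m[, 2], missed_cleavages = m[, 3],
    stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Find N-glycosylation sequons
#'
#' Scans a protein for the N-X-S/T motif (X any residue except proline),
#' the consensus required for N-linked glycosylation.
#'
#' @param protein Protein sequence string.
#' @return Data frame with columns `position` (1-based Asn position) and
#'   `sequon` (the 3-residue motif).
#' @examples
#' find_sequons("EEQYNSTYR")  # position 5
#' @export
find_sequons <- function(protein) {
  s <- strsplit(protein, "")[[1]]
  n <- length(s)
  pos <- which(s == "N")
  pos <- pos[pos + 2L <= n]
  pos <- pos[s[pos + 1L] != "P" & s[pos + 2L] %in% c("S", "T")]
  data.frame(position = pos,
             sequon = vapply(pos, function(i) paste(s[i:(i + 2L)], collapse = ""), ""),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a plain (multi-record) amino-acid FASTA file.
#' @return Named character vector of sequences; names are the full
#'   description lines.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
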
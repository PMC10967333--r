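#' Protein sequence coverage
#'
#' Percentage of protein residues covered by the union of identified
#' peptide coordinate intervals.
#'
#' @param intervals Data frame with columns `start`, `end` (1-based
#'   inclusive), or a two-column matrix.
#' @param protein_length Protein length in residues.
#' @return Coverage in percent (0-100).
#' @examples
#' coverage(data.frame(start = c(1, 40), end = c(60, 100)), 100)  # 100
#' @export
coverage <- function(intervals, protein_length) {
  stopifnot(protein_length >= 1L)
  iv <- as.data.frame(intervals)
  if (!nrow(iv)) return(0)
  stopifnot(all(c("start", "end") %in% names(iv)))
  if (any(iv$start < 1L) || any(iv$end > protein_length) || any(iv$start > iv$end))
    stop("interval outside [1, protein_length]")
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  covered <- 0L; cur_s <- iv$start[1]; cur_e <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= cur_e + 1L) cur_e <- max(cur_e, iv$end[i])
    else { covered <- covered + (cur_e - cur_s + 1L); cur_s <- iv$start[i]; cur_e <- iv$end[i] }
  }
  covered <- covered + (cur_e - cur_s + 1L)
  100 * covered / protein_length
}

#' Run the full glycoproteomic pipeline
#'
#' Orchestrates triage, glycopeptide search, per-site glycoform
#' profiling, sequence coverage, and (when a deglycosylation run is
#' given) 18O site-occupancy quantification. All tabular outputs are
#' returned and, when `out_dir` is set, written as TSV with header rows.
#'
#' @param run Glycopeptide MS run ([ms_run()] or MGF path).
#' @param proteins Named character vector of sequences or FASTA path.
#' @param library A [glycan_library()].
#' @param config A [search_config()].
#' @param deglyco_run Optional 18O deglycosylation MS1 run (or MGF path).
#' @param occupancy_peptide,occupancy_site Deglycosylated peptide (Asn
#'   form) and its Asn position, for the occupancy computation.
#' @param out_dir Optional output directory for `gpsm.tsv`,
#'   `profile.tsv`, `coverage.tsv`, `occupancy.tsv`.
#' @return List with `gpsms`, `profiles` (one [glycoform_profile()] per
#'   glycosylation site), `coverage` (data frame), `occupancy` (an
#'   [occupancy_18O()] result or `NULL`).
#' @export
run_pipeline <- function(run, proteins, library = glycan_library(),
                         config = search_config(), deglyco_run = NULL,
                         occupancy_peptide = NULL, occupancy_site = NULL,
                         out_dir = NULL) {
  if (is.character(run)) run <- read_mgf(run)
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- read_fasta(proteins)
  gpsms <- search_run(run, proteins, library, config)
  glyco <- gpsms[gpsms$composition != "bare", , drop = FALSE]
  profiles <- list()
  for (site in sort(unique(glyco$protein_site))) {
    sub <- glyco[glyco$protein_site == site, , drop = FALSE]
    profiles[[as.character(site)]] <- glycoform_profile(sub, run)
  }
  cov <- do.call(rbind, lapply(names(proteins), function(nm) {
    ids <- gpsms[gpsms$protein == nm, c("start", "end"), drop = FALSE]
    data.frame(protein = nm,
               coverage = coverage(ids, nchar(proteins[[nm]])),
               n_peptides = length(unique(gpsms$peptide[gpsms$protein == nm])),
               stringsAsFactors = FALSE)
  }))
  occ <- NULL
  if (!is.null(deglyco_run)) {
    if (is.null(occupancy_peptide) || is.null(occupancy_site))
      stop("occupancy_peptide and occupancy_site are required with a deglyco run")
    occ <- occupancy_18O(deglyco_run, occupancy_peptide, occupancy_site)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, file)
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wr(gpsms, "gpsm.tsv")
    prof_df <- do.call(rbind, lapply(names(profiles), function(s) {
      p <- as.data.frame(profiles[[s]])
      if (nrow(p)) cbind(site = s, p) else NULL
    }))
    wr(prof_df %||NULL% data.frame(), "profile.tsv")
    wr(cov %||NULL% data.frame(), "coverage.tsv")
    if (!is.null(occ))
      wr(data.frame(peptide = occ$peptide, site = occ$site,
                    occupied = occ$occupied, quantifiable = occ$quantifiable),
         "occupancy.tsv")
  }
  list(gpsms = gpsms, profiles = profiles, coverage = cov, occupancy = occ)
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a
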
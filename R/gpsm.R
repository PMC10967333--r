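#' Search configuration
#'
#' Defaults follow the acquisition and search settings this package
#' emulates: 10 ppm precursor and 20 ppm fragment tolerance, 15 ppm
#' oxonium triage with two required hits, dual Glu-C + trypsin digestion
#' with up to two missed cleavages, fixed Cys carbamidomethylation, and
#' variable Met oxidation / protein N-terminal acetylation.
#'
#' @param ms1_tol_ppm Precursor tolerance (ppm).
#' @param ms2_tol_ppm Fragment tolerance (ppm).
#' @param triage Apply the oxonium filter before searching?
#' @param triage_tol_ppm,min_oxonium_hits Oxonium panel settings.
#' @param max_missed Missed-cleavage maximum.
#' @param enzymes List of [enzyme_rule()]s.
#' @param fixed_cys_carbamidomethyl Apply +57.02146 to every Cys?
#' @param variable_mods Search Met oxidation (up to `max_oxidation`) and
#'   N-terminal acetylation of protein N-terminal peptides?
#' @param max_oxidation Maximum simultaneous Met oxidations.
#' @param fragment_charges Fragment charge states considered.
#' @param max_y_remnants Depth of the Y-ion glycan remnant ladder.
#' @return A list of class `fcg_search_config`.
#' @export
search_config <- function(ms1_tol_ppm = 10, ms2_tol_ppm = 20, triage = TRUE,
                          triage_tol_ppm = 15, min_oxonium_hits = 2L,
                          max_missed = 2L,
                          enzymes = list(enzyme_glu_c(), enzyme_trypsin()),
                          fixed_cys_carbamidomethyl = TRUE,
                          variable_mods = TRUE, max_oxidation = 2L,
                          fragment_charges = c(1L, 2L), max_y_remnants = 8L) {
  structure(list(ms1_tol_ppm = ms1_tol_ppm, ms2_tol_ppm = ms2_tol_ppm,
                 triage = triage, triage_tol_ppm = triage_tol_ppm,
                 min_oxonium_hits = as.integer(min_oxonium_hits),
                 max_missed = as.integer(max_missed), enzymes = enzymes,
                 fixed_cys_carbamidomethyl = fixed_cys_carbamidomethyl,
                 variable_mods = variable_mods,
                 max_oxidation = as.integer(max_oxidation),
                 fragment_charges = as.integer(fragment_charges),
                 max_y_remnants = as.integer(max_y_remnants)),
            class = "fcg_search_config")
}

# serialize/deserialize a mods data.frame as "name@pos;name@pos"
.mods_to_string <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  paste(sprintf("%s@%d", mods$name, mods$position), collapse = ";")
}

.string_to_mods <- function(s) {
  if (is.na(s) || s == "") return(data.frame(position = integer(), name = character()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
  data.frame(position = vapply(parts, function(p) as.integer(p[2]), 0L),
             name = vapply(parts, `[[`, "", 1),
             stringsAsFactors = FALSE)
}

# modification variants of one digested peptide row
.mod_variants <- function(sequence, start, config) {
  s <- strsplit(sequence, "")[[1]]
  base <- data.frame(position = integer(), name = character())
  if (config$fixed_cys_carbamidomethyl) {
    cys <- which(s == "C")
    if (length(cys))
      base <- data.frame(position = cys, name = "carbamidomethyl")
  }
  variants <- list(base)
  if (config$variable_mods) {
    mets <- which(s == "M")
    oxsets <- list(integer())
    for (k in seq_len(min(length(mets), config$max_oxidation)))
      oxsets <- c(oxsets, utils::combn(mets, k, simplify = FALSE))
    nterm <- if (start == 1L) c(FALSE, TRUE) else FALSE
    variants <- list()
    for (ox in oxsets) for (ac in nterm) {
      m <- base
      if (length(ox)) m <- rbind(m, data.frame(position = ox, name = "oxidation"))
      if (ac) m <- rbind(m, data.frame(position = 1L, name = "acetyl"))
      variants[[length(variants) + 1L]] <- m
    }
  }
  variants
}

#' Build the glycopeptide candidate space for a peptide set
#'
#' Expands digested peptides into searchable candidates: each peptide's
#' modification variants, crossed with (for peptides bearing a sequon)
#' every library composition at every sequon site, plus the bare-peptide
#' candidate. Neutral masses are precomputed.
#'
#' @param peptides Data frame from [digest()] (columns `sequence`,
#'   `start`, `end`, and optionally `protein`).
#' @param library A [glycan_library()] data frame.
#' @param config A [search_config()].
#' @param constants Mass table.
#' @return Data frame with one row per candidate: peptide fields, `mods`
#'   string, `site` (peptide-relative, `NA` for bare), composition counts
#'   and string, and `neutral_mass`.
#' @export
candidate_space <- function(peptides, library = glycan_library(),
                            config = search_config(),
                            constants = mass_constants()) {
  rows <- list()
  if (!"protein" %in% names(peptides)) peptides$protein <- NA_character_
  for (i in seq_len(nrow(peptides))) {
    seqn <- peptides$sequence[i]
    seqs <- find_sequons(seqn)
    # a sequon whose S/T falls outside this peptide cannot be confirmed
    for (mods in .mod_variants(seqn, peptides$start[i], config)) {
      pep <- peptide(seqn, peptides$start[i], peptides$end[i], mods = mods,
                     missed_cleavages = peptides$missed_cleavages[i] %||% 0L)
      pmass <- peptide_mass(pep, constants)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = peptides$protein[i], sequence = seqn,
        start = peptides$start[i], end = peptides$end[i],
        mods = .mods_to_string(mods), site = NA_integer_,
        hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L,
        composition = "bare", neutral_mass = pmass,
        stringsAsFactors = FALSE)
      if (nrow(seqs)) {
        for (site in seqs$position) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein = peptides$protein[i], sequence = seqn,
            start = peptides$start[i], end = peptides$end[i],
            mods = .mods_to_string(mods), site = site,
            hexnac = library$hexnac, hex = library$hex,
            fuc = library$fuc, neuac = library$neuac,
            composition = library$composition,
            neutral_mass = pmass + library$mass,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidates matching one precursor
#'
#' Filters a candidate space (or builds one from `peptides`) to the
#' candidates whose theoretical `[M + zH]z+` m/z lies within `tol_ppm` of
#' the observed precursor.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param charge Precursor charge (>= 1).
#' @param peptides Data frame from [digest()], or a prebuilt
#'   [candidate_space()] (detected by its `neutral_mass` column).
#' @param library A [glycan_library()].
#' @param tol_ppm Precursor tolerance, ppm.
#' @param config,constants See [search_config()], [mass_constants()].
#' @return The matching rows, with `mz_theoretical` and `ppm` added.
#' @export
generate_candidates <- function(precursor_mz, charge, peptides,
                                library = glycan_library(), tol_ppm = 10,
                                config = search_config(),
                                constants = mass_constants()) {
  stopifnot(charge >= 1L)
  space <- if ("neutral_mass" %in% names(peptides)) peptides
           else candidate_space(peptides, library, config, constants)
  mz <- (space$neutral_mass + charge * constants$proton) / charge
  ppm <- (precursor_mz - mz) / mz * 1e6
  keep <- abs(ppm) <= tol_ppm
  out <- space[keep, , drop = FALSE]
  out$mz_theoretical <- mz[keep]
  out$ppm <- ppm[keep]
  rownames(out) <- NULL
  out
}

# glycan remnant ladder for the Y-ion series: chitobiose core first
# (HexNAc2), then the trimannosyl core (Hex3), then the remaining units
.y_ladder <- function(glycan, max_remnants = 8L) {
  g <- unclass(glycan)
  steps <- list()
  cur <- c(hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L)
  add <- function(unit, upto) {
    while (cur[[unit]] < upto) {
      cur[[unit]] <<- cur[[unit]] + 1L
      steps[[length(steps) + 1L]] <<- cur
    }
  }
  add("hexnac", min(2L, g[["hexnac"]]))
  add("hex", min(3L, g[["hex"]]))
  add("hexnac", g[["hexnac"]])
  add("hex", g[["hex"]])
  add("fuc", g[["fuc"]])
  add("neuac", g[["neuac"]])
  steps[seq_len(min(length(steps), max_remnants))]
}

#' Theoretical fragment ions of a glycopeptide
#'
#' Generates, for HCD spectra:
#' * the full b/y backbone ladders of the bare peptide (glycan lost);
#' * the Y series: intact peptide plus a growing glycan remnant, from Y0
#'   (bare peptide) through the chitobiose/trimannosyl core toward the
#'   full composition, truncated at `max_y_remnants` remnants;
#' * site-localizing glycosylated backbone ions: b/y fragments that span
#'   the glycosylation site retaining HexNAc1 or HexNAc2 (singly charged);
#' * oxonium (B-type) ions implied by the composition.
#'
#' @param gp An [glycopeptide()].
#' @param charges Charge states for b/y and Y ions.
#' @param max_y_remnants Y-ladder depth.
#' @param constants Mass table.
#' @return Data frame with columns `series` (`"b"`, `"y"`, `"Y"`, `"B"`),
#'   `index` (backbone position; for Y the remnant size; 0 for B),
#'   `remnant` (glycan remnant composition string, `""` if none),
#'   `charge`, `mz`, `spans_site`, `label`.
#' @export
theoretical_fragments <- function(gp, charges = c(1L, 2L), max_y_remnants = 8L,
                                  constants = mass_constants()) {
  stopifnot(inherits(gp, "fcg_glycopeptide"))
  pep <- gp$peptide
  s <- strsplit(pep$sequence, "")[[1]]
  n <- length(s)
  res <- constants$residues[s]
  moddelta <- numeric(n)
  if (nrow(pep$mods))
    moddelta[pep$mods$position] <- moddelta[pep$mods$position] +
      constants$modifications[pep$mods$name]
  prefix <- cumsum(res + moddelta)        # neutral b_i residue sums
  pr <- constants$proton; w <- constants$water
  hexnac <- constants$monosaccharides[["HexNAc"]]
  rows <- list()
  emit <- function(series, index, remnant, charge, neutral, spans_site, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, index = index, remnant = remnant, charge = charge,
      mz = (neutral + charge * pr) / charge, spans_site = spans_site,
      label = label, stringsAsFactors = FALSE)
  }
  if (n > 1L) {
    for (z in charges) {
      for (i in seq_len(n - 1L)) {
        emit("b", i, "", z, prefix[i], !is.na(gp$site) && i >= gp$site,
             sprintf("b%d^%d", i, z))
        j <- n - i                        # y_j = residues (i+1)..n
        emit("y", j, "", z, prefix[n] - prefix[i] + w,
             !is.na(gp$site) && i < gp$site, sprintf("y%d^%d", j, z))
      }
    }
    # site-localizing glycosylated backbone ions (singly charged)
    if (!is.na(gp$site) && gp$glycan[["hexnac"]] >= 1L) {
      kmax <- min(2L, gp$glycan[["hexnac"]])
      for (k in seq_len(kmax)) {
        remn <- format(glycan_composition(hexnac = k))
        for (i in gp$site:(n - 1L))
          emit("b", i, remn, 1L, prefix[i] + k * hexnac, TRUE,
               sprintf("b%d+HexNAc%d", i, k))
        for (i in seq_len(gp$site - 1L)) {
          j <- n - i
          emit("y", j, remn, 1L, prefix[n] - prefix[i] + w + k * hexnac, TRUE,
               sprintf("y%d+HexNAc%d", j, k))
        }
      }
    }
  }
  # Y series
  pepmass <- prefix[n] + w
  for (z in charges) emit("Y", 0L, "", z, pepmass, FALSE, sprintf("Y0^%d", z))
  if (sum(gp$glycan) > 0) {
    for (stepv in .y_ladder(gp$glycan, max_y_remnants)) {
      remn <- do.call(glycan_composition, as.list(stepv))
      for (z in charges)
        emit("Y", sum(stepv), format(remn), z, pepmass + glycan_mass(remn, constants),
             FALSE, sprintf("Y+%s^%d", format(remn), z))
    }
    # oxonium B ions implied by the composition
    g <- gp$glycan
    ox <- list()
    if (g[["hexnac"]] >= 1L) {
      hn <- glycan_composition(hexnac = 1)
      ox <- c(ox, list(c(oxonium_mz(hn, 0, constants), "HexNAc"),
                       c(oxonium_mz(hn, 1, constants), "HexNAc-H2O"),
                       c(oxonium_mz(hn, 2, constants), "HexNAc-2H2O"),
                       c(oxonium_mz(hn, 0, constants) - 66.031695, "HexNAc-CH6O3")))
      if (g[["hex"]] >= 1L)
        ox <- c(ox, list(c(oxonium_mz(glycan_composition(1, 1), 0, constants),
                           "HexNAcHex")))
    }
    if (g[["neuac"]] >= 1L) {
      na1 <- glycan_composition(neuac = 1)
      ox <- c(ox, list(c(oxonium_mz(na1, 0, constants), "NeuAc"),
                       c(oxonium_mz(na1, 1, constants), "NeuAc-H2O")))
    }
    for (o in ox)
      rows[[length(rows) + 1L]] <- data.frame(
        series = "B", index = 0L, remnant = "", charge = 1L,
        mz = as.numeric(o[1]), spans_site = FALSE, label = o[2],
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score a glycopeptide against an MS2 spectrum
#'
#' Deterministic 0-100 score built from three evidence channels matched
#' within `tol_ppm`:
#' * backbone: (matched distinct b/y ions) / (2 (n - 1)) x 50;
#' * glycan: 8 x min(matched Y remnants, 5) x (matched Y remnants /
#'   theoretical Y remnants) — the completeness weighting makes a
#'   candidate whose composition over- or under-shoots the true glycan
#'   score strictly below the true one even when their remnant ladders
#'   largely coincide;
#' * oxonium: +10 when at least two distinct oxonium ions match.
#'
#' `site_localized` is `TRUE` when at least one glycosylated backbone ion
#' spanning the site is matched (the b/Y1- and y/Y1-type evidence used to
#' pin a glycan to a specific sequon).
#'
#' @param spec An MS2 [spectrum()].
#' @param gp An [glycopeptide()].
#' @param tol_ppm Fragment tolerance (ppm).
#' @param charges,max_y_remnants See [theoretical_fragments()].
#' @param constants Mass table.
#' @return An object of class `fcg_gpsm`: list with `scan_id`,
#'   `glycopeptide`, `score`, `site_localized`, `precursor_ppm`,
#'   `matched` (data frame of matched fragments with observed m/z,
#'   intensity and ppm error).
#' @export
score_gpsm <- function(spec, gp, tol_ppm = 20, charges = c(1L, 2L),
                       max_y_remnants = 8L, constants = mass_constants()) {
  stopifnot(inherits(spec, "fcg_spectrum"))
  if (spec$ms_level != 2L) stop("GPSM scoring applies to MS2 spectra")
  frags <- theoretical_fragments(gp, charges, max_y_remnants, constants)
  obs <- lapply(frags$mz, function(m) match_peak(spec, m, tol_ppm))
  hit <- !vapply(obs, is.null, TRUE)
  matched <- frags[hit, , drop = FALSE]
  matched$obs_mz <- vapply(obs[hit], `[[`, 0, "mz")
  matched$intensity <- vapply(obs[hit], `[[`, 0, "intensity")
  matched$ppm <- vapply(obs[hit], `[[`, 0, "ppm")
  n <- nchar(gp$peptide$sequence)
  by_rows <- matched$series %in% c("b", "y") & matched$remnant == ""
  n_by <- length(unique(paste(matched$series, matched$index)[by_rows]))
  by_term <- if (n > 1L) n_by / (2 * (n - 1)) * 50 else 0
  th_y <- unique(frags$remnant[frags$series == "Y"])
  ob_y <- unique(matched$remnant[matched$series == "Y"])
  y_term <- if (length(th_y))
    8 * min(length(ob_y), 5) * (length(ob_y) / length(th_y)) else 0
  n_ox <- length(unique(matched$label[matched$series == "B"]))
  ox_term <- if (n_ox >= 2L) 10 else 0
  site_loc <- any(matched$series %in% c("b", "y") & matched$remnant != "" &
                    matched$spans_site)
  pmz <- glycopeptide_mz(gp, max(1L, spec$precursor_charge %||% 1L), constants)
  ppm <- if (!is.na(spec$precursor_mz)) (spec$precursor_mz - pmz) / pmz * 1e6
         else NA_real_
  structure(list(scan_id = spec$scan_id, glycopeptide = gp,
                 score = by_term + y_term + ox_term,
                 site_localized = site_loc, precursor_ppm = ppm,
                 matched = matched),
            class = "fcg_gpsm")
}

#' @export
print.fcg_gpsm <- function(x, ...) {
  cat(sprintf("<GPSM %s> %s + %s  score %.1f%s\n", x$scan_id,
              x$glycopeptide$peptide$sequence, format(x$glycopeptide$glycan),
              x$score, if (x$site_localized) " (site localized)" else ""))
  invisible(x)
}

#' Search a run for glycopeptide-spectrum matches
#'
#' For every (optionally oxonium-triaged) MS2 spectrum: generate
#' candidates by precursor mass, score each, and report the best match.
#' Ranking is by score, then smaller |precursor ppm|, then fewer glycan
#' residues, then lexicographic composition — a fully deterministic order.
#'
#' @param run An [ms_run()] or MGF path.
#' @param proteins Named character vector of protein sequences, or a
#'   FASTA path.
#' @param library A [glycan_library()].
#' @param config A [search_config()].
#' @param constants Mass table.
#' @return Data frame of best matches (one row per identified spectrum):
#'   scan, peptide and coordinates, mods, site (peptide and protein
#'   coordinates), composition, shorthand, class, charge, score,
#'   precursor ppm, site_localized, n_matched.
#' @export
search_run <- function(run, proteins, library = glycan_library(),
                       config = search_config(),
                       constants = mass_constants()) {
  if (is.character(run)) run <- read_mgf(run)
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- read_fasta(proteins)
  if (is.null(proteins) || !length(proteins)) stop("no protein sequences given")
  if (is.null(library) || !nrow(library)) stop("empty glycan library")
  peps <- do.call(rbind, lapply(names(proteins), function(nm) {
    d <- digest(proteins[[nm]], config$enzymes, config$max_missed)
    d$protein <- nm
    d
  }))
  space <- candidate_space(peps, library, config, constants)
  ms2 <- Filter(function(s) s$ms_level == 2L, run$spectra)
  if (config$triage) {
    panel <- oxonium_panel(config$triage_tol_ppm, config$min_oxonium_hits)
    keep <- vapply(ms2, function(s) is_glyco_spectrum(s, panel)$decision, TRUE)
    ms2 <- ms2[keep]
  }
  out <- list()
  for (sp in ms2) {
    z <- sp$precursor_charge
    zs <- if (is.na(z)) c(2L, 3L) else z
    cand <- do.call(rbind, lapply(zs, function(zz) {
      cc <- generate_candidates(sp$precursor_mz, zz, space, library,
                                config$ms1_tol_ppm, config, constants)
      if (nrow(cc)) cc$charge <- zz
      cc
    }))
    if (is.null(cand) || !nrow(cand)) next
    scored <- lapply(seq_len(nrow(cand)), function(i) {
      pep <- peptide(cand$sequence[i], cand$start[i], cand$end[i],
                     mods = .string_to_mods(cand$mods[i]))
      gp <- glycopeptide(pep, cand$site[i],
                         glycan_composition(cand$hexnac[i], cand$hex[i],
                                            cand$fuc[i], cand$neuac[i]))
      score_gpsm(sp, gp, config$ms2_tol_ppm, config$fragment_charges,
                 config$max_y_remnants, constants)
    })
    sc <- vapply(scored, `[[`, 0, "score")
    nsugar <- cand$hexnac + cand$hex + cand$fuc + cand$neuac
    best <- order(-sc, abs(cand$ppm), nsugar, cand$composition,
                  cand$sequence)[1]
    g <- scored[[best]]
    out[[length(out) + 1L]] <- data.frame(
      scan_id = sp$scan_id, protein = cand$protein[best],
      peptide = cand$sequence[best], start = cand$start[best],
      end = cand$end[best], mods = cand$mods[best],
      site = cand$site[best],
      protein_site = if (is.na(cand$site[best])) NA_integer_
                     else cand$start[best] + cand$site[best] - 1L,
      composition = cand$composition[best],
      shorthand = if (cand$composition[best] == "bare") ""
                  else composition_to_shorthand(g$glycopeptide$glycan, library),
      class = if (cand$composition[best] == "bare") ""
              else classify_glycan(g$glycopeptide$glycan),
      charge = cand$charge[best], precursor_mz = sp$precursor_mz,
      ppm = cand$ppm[best], score = g$score,
      site_localized = g$site_localized, n_matched = nrow(g$matched),
      rt = sp$rt, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scan_id = character(), protein = character(),
                      peptide = character(), start = integer(), end = integer(),
                      mods = character(), site = integer(),
                      protein_site = integer(), composition = character(),
                      shorthand = character(), class = character(),
                      charge = integer(), precursor_mz = numeric(),
                      ppm = numeric(), score = numeric(),
                      site_localized = logical(), n_matched = integer(),
                      rt = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
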
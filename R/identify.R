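# Transfer of bottom-up LC-MS/MS peptide identities onto IMS m/z values:
# monoisotopic mass arithmetic, charge conversion, tolerance matching with a
# lowest-mass-difference winner, and the >= 2 distinct peptides per protein
# acceptance rule.

#' Monoisotopic residue masses and related constants (Da)
#'
#' Standard monoisotopic residue masses of the 20 amino acids, plus water
#' (added once per peptide), the proton mass (for m/z <-> neutral mass
#' conversion) and the methionine-oxidation mass shift.
#'
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname RESIDUE_MASSES
#' @export
MASS_WATER <- 18.010565

#' @rdname RESIDUE_MASSES
#' @export
MASS_PROTON <- 1.007276

#' @rdname RESIDUE_MASSES
#' @export
MASS_OXIDATION <- 15.994915

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, plus `oxidized_met_count` times the
#' oxidation shift (variable Met oxidation). Additive over concatenation:
#' `mass(AB) = mass(A) + mass(B) - water`.
#'
#' @param sequence peptide string over the 20 standard one-letter residues
#' @param oxidized_met_count number of oxidized methionines (<= count of M)
#' @return neutral monoisotopic mass in Da
#' @export
monoisotopic_mass <- function(sequence, oxidized_met_count = 0) {
  stopifnot(length(sequence) == 1, nchar(sequence) >= 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(RESIDUE_MASSES))
  if (length(bad) > 0) {
    stop("monoisotopic_mass: invalid residue '", aa[bad[1]],
         "' at position ", bad[1])
  }
  if (oxidized_met_count > sum(aa == "M")) {
    stop("monoisotopic_mass: more oxidized methionines than M residues")
  }
  sum(RESIDUE_MASSES[aa]) + MASS_WATER + oxidized_met_count * MASS_OXIDATION
}

#' Convert an observed m/z to a neutral mass
#'
#' `neutral = mz * charge - charge * proton`. MALDI peptide ions are singly
#' protonated, so the default charge is 1.
#'
#' @param mz observed m/z
#' @param charge positive integer charge
#' @return neutral mass in Da
#' @export
mz_to_neutral <- function(mz, charge = 1) {
  out <- mz * charge - charge * MASS_PROTON
  if (any(out <= 0)) stop("mz_to_neutral: nonpositive neutral mass")
  out
}

#' Convert a neutral mass to m/z at a given charge
#' @param mass neutral mass (Da)
#' @param charge positive integer charge
#' @export
neutral_to_mz <- function(mass, charge = 1) {
  (mass + charge * MASS_PROTON) / charge
}

#' Relative mass error in parts per million
#' @param delta_da absolute mass difference (Da)
#' @param reference_mass reference neutral mass (Da), > 0
#' @export
ppm_error <- function(delta_da, reference_mass) {
  stopifnot(all(reference_mass > 0))
  delta_da / reference_mass * 1e6
}

#' Match IMS m/z values to an LC-MS/MS peptide list
#'
#' Every IMS marker m/z is converted to a neutral mass (charge 1) and compared
#' with the experimental neutral masses of the identification table. Peptides
#' with a mass difference strictly below `tolerance` are candidates; the
#' winner is the candidate with the lowest mass difference (ties broken by
#' lexicographically smaller sequence, logged), so permuting the table never
#' changes winners. Each IMS m/z maps to at most one peptide. A protein is
#' accepted only when at least two of its distinct peptide sequences are
#' matched by distinct IMS m/z values.
#'
#' @param marker_mzs numeric vector of IMS m/z values (observed, charge 1)
#' @param id_table a `peptide_id_table` (see [read_peptide_ids()])
#' @param tolerance maximum mass difference in Da (strict `<`, default 0.9)
#' @return a `match_report`: `matches` (one row per matched IMS m/z:
#'   `ims_mz_observed, ims_neutral_mass, matched_sequence, matched_protein,
#'   gene_name, description, lcms_mass, delta_da, delta_ppm, score`),
#'   `proteins` (per-protein summary with `n_matched_peptides`, `accepted`),
#'   `n_markers`, `n_matched`
#' @export
match_ims_to_lcms <- function(marker_mzs, id_table, tolerance = 0.9) {
  stopifnot(tolerance > 0)
  tab <- as.data.frame(id_table)
  if (nrow(tab) == 0) {
    warning("match_ims_to_lcms: empty identification table")
    return(structure(list(matches = data.frame(), proteins = data.frame(),
                          n_markers = length(marker_mzs), n_matched = 0L),
                     class = "match_report"))
  }
  rows <- lapply(sort(marker_mzs), function(mz) {
    neutral <- mz_to_neutral(mz)
    delta <- abs(neutral - tab$experimental_neutral_mass)
    cand <- which(delta < tolerance)
    if (length(cand) == 0) return(NULL)
    # lowest mass difference wins; ties by lower ppm, then sequence order
    ord <- order(delta[cand],
                 ppm_error(delta[cand], tab$experimental_neutral_mass[cand]),
                 tab$sequence[cand])
    if (length(cand) > 1 && abs(delta[cand[ord[1]]] - delta[cand[ord[2]]]) < 1e-12) {
      msg("match_ims_to_lcms: tie at m/z %.4f broken by sequence order", mz)
    }
    w <- cand[ord[1]]
    data.frame(
      ims_mz_observed = mz, ims_neutral_mass = neutral,
      matched_sequence = tab$sequence[w],
      matched_protein = tab$protein_accession[w],
      gene_name = tab$gene_name[w], description = tab$description[w],
      lcms_mass = tab$experimental_neutral_mass[w],
      delta_da = delta[w], delta_ppm = ppm_error(delta[w], tab$experimental_neutral_mass[w]),
      score = tab$score[w], stringsAsFactors = FALSE
    )
  })
  matches <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(matches)) {
    matches <- data.frame(ims_mz_observed = numeric(0))
  }
  proteins <- if (nrow(matches) > 0) {
    agg <- stats::aggregate(matched_sequence ~ matched_protein + gene_name,
                            data = matches,
                            FUN = function(s) length(unique(s)))
    names(agg)[3] <- "n_matched_peptides"
    agg$accepted <- agg$n_matched_peptides >= 2
    agg
  } else {
    data.frame(matched_protein = character(0), gene_name = character(0),
               n_matched_peptides = integer(0), accepted = logical(0))
  }
  structure(list(matches = matches, proteins = proteins,
                 n_markers = length(marker_mzs),
                 n_matched = nrow(matches)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: assigned %d out of %d m/z values to %d protein(s), %d accepted (>= 2 peptides)\n",
              x$n_matched, x$n_markers, nrow(x$proteins),
              sum(x$proteins$accepted)))
  invisible(x)
}

#' Build the identification report table
#'
#' One row per matched peptide of an accepted protein (>= 2 matched
#' peptides), in the published column order: IMS m/z observed, IMS neutral
#' mass, intensity ratios and ROC AUCs of the tam and tm group contrasts,
#' LC-MS/MS neutral mass, delta Da, delta ppm, score, sequence, gene name,
#' description. Ratios and AUCs come from the supplied marker tables.
#'
#' @param match_report a [match_ims_to_lcms()] result
#' @param marker_tables named list with elements `tam` and `tm`, each a
#'   `marker_table` from [discover_markers()] for the group contrast within
#'   that region
#' @param include_unaccepted keep peptides of proteins with a single matched
#'   peptide (default FALSE)
#' @return data.frame in report column order
#' @export
build_report <- function(match_report, marker_tables, include_unaccepted = FALSE) {
  m <- match_report$matches
  if (is.null(m) || nrow(m) == 0) {
    return(data.frame(
      ims_mz_observed = numeric(0), ims_neutral_mass = numeric(0),
      ratio_tam = numeric(0), ratio_tm = numeric(0),
      auc_tam = numeric(0), auc_tm = numeric(0),
      lcms_mass = numeric(0), delta_da = numeric(0), delta_ppm = numeric(0),
      score = numeric(0), sequence = character(0), gene_name = character(0),
      description = character(0)
    ))
  }
  stopifnot(all(c("tam", "tm") %in% names(marker_tables)))
  if (!include_unaccepted) {
    ok <- match_report$proteins$matched_protein[match_report$proteins$accepted]
    m <- m[m$matched_protein %in% ok, , drop = FALSE]
  }
  stat_of <- function(tabname, col, mz) {
    tab <- marker_tables[[tabname]]
    j <- which.min(abs(tab$mz - mz))
    if (abs(tab$mz[j] - mz) > 0.5) {
      stop("build_report: marker m/z ", mz, " absent from the '", tabname,
           "' marker table")
    }
    tab[[col]][j]
  }
  m <- m[order(m$matched_protein, m$ims_mz_observed), , drop = FALSE]
  out <- data.frame(
    ims_mz_observed = m$ims_mz_observed,
    ims_neutral_mass = m$ims_neutral_mass,
    ratio_tam = vapply(m$ims_mz_observed, function(z) stat_of("tam", "ratio", z), 0),
    ratio_tm = vapply(m$ims_mz_observed, function(z) stat_of("tm", "ratio", z), 0),
    auc_tam = vapply(m$ims_mz_observed, function(z) stat_of("tam", "auc", z), 0),
    auc_tm = vapply(m$ims_mz_observed, function(z) stat_of("tm", "auc", z), 0),
    lcms_mass = m$lcms_mass,
    delta_da = m$delta_da,
    delta_ppm = m$delta_ppm,
    score = m$score,
    sequence = m$matched_sequence,
    gene_name = m$gene_name,
    description = m$description,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
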
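#' Peptide-level label-free quantification table
#'
#' Validates the peptide schema used by the proteomic normalizations:
#' `peptide` (id), `protein` (protein/isoform assignment), `specific`
#' (logical: isoform-specific peptide), `assigned` (logical: PV assigned to
#' this protein), `pv` (peak volume, >= 0), `dataset` (sample x region id).
#'
#' @param df A data frame.
#' @return The validated data frame, classed `peptide_table`.
#' @export
peptide_table <- function(df) {
  need <- c("peptide", "protein", "specific", "assigned", "pv", "dataset")
  if (!all(need %in% names(df))) {
    stop("peptide table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$pv < 0)) stop("peak volumes must be >= 0", call. = FALSE)
  structure(df, class = c("peptide_table", "data.frame"))
}

#' Protein abundance from isoform-specific peptide peak volumes
#'
#' The abundance estimate for one protein is the sum of all assigned,
#' protein-isoform-specific peak volumes divided by the number of
#' MS-accessible isoform-specific amino acids (a user-supplied per-protein
#' constant; the in-silico digestion producing it is upstream of this
#' package).
#'
#' @param peptides A [peptide_table()] (rows for one protein; other rows are
#'   ignored if `protein` is given).
#' @param accessible_aa MS-accessible isoform-specific amino-acid count, > 0.
#' @param protein Optional protein name to filter on.
#' @return Abundance value (peak volume per amino acid).
#' @export
abundance_norm_spec <- function(peptides, accessible_aa, protein = NULL) {
  peptides <- peptide_table(as.data.frame(peptides))
  if (accessible_aa <= 0) stop("accessible_aa must be > 0", call. = FALSE)
  if (!is.null(protein)) peptides <- peptides[peptides$protein == protein, ]
  keep <- peptides$specific & peptides$assigned
  sum(peptides$pv[keep]) / accessible_aa
}

#' Per-protein abundance table
#'
#' Applies [abundance_norm_spec()] to every protein in a peptide table.
#'
#' @param peptides A [peptide_table()].
#' @param accessible_aa Named numeric vector: MS-accessible isoform-specific
#'   amino-acid counts per protein.
#' @return A data frame of class `protein_abundance`: `protein`, `abundance`.
#' @export
protein_abundance_table <- function(peptides, accessible_aa) {
  peptides <- peptide_table(as.data.frame(peptides))
  prots <- unique(peptides$protein)
  missing <- setdiff(prots, names(accessible_aa))
  if (length(missing)) {
    stop("missing accessible amino-acid counts for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ab <- vapply(prots, function(p)
    abundance_norm_spec(peptides, accessible_aa[[p]], protein = p), numeric(1))
  structure(data.frame(protein = prots, abundance = unname(ab)),
            class = c("protein_abundance", "data.frame"))
}

#' Normalize protein abundances to the Kv4 tetramer
#'
#' Divides every protein's abundance by `(sum of Kv4 abundances) / 4`, so that
#' the normalized abundances of the pore-forming subunits (Kv4.2 + Kv4.3) sum
#' to exactly 4 — one channel core. Scale-invariant and idempotent.
#'
#' @param table A [protein_abundance_table()] output (columns `protein`,
#'   `abundance`).
#' @param kv4_subunits Names of the pore-forming subunits.
#' @return The table with an added `normalized` column (tetramer units).
#' @export
tetramer_normalize <- function(table, kv4_subunits = c("Kv4.2", "Kv4.3")) {
  stopifnot(all(c("protein", "abundance") %in% names(table)))
  kv4 <- table$abundance[table$protein %in% kv4_subunits]
  if (!length(kv4) || sum(kv4) <= 0) {
    stop("no positive Kv4 subunit abundance; cannot normalize", call. = FALSE)
  }
  factor <- sum(kv4) / 4
  table$normalized <- table$abundance / factor
  table
}

#' Relative isoform abundance from unique-peptide profiles
#'
#' For each isoform-unique peptide, peak volumes are first normalized to their
#' maximum across all datasets (within one region), yielding relative peptide
#' profiles in `[0, 1]`; group abundances are the mean profile value over each
#' group's samples, and the result is reported relative to the reference group
#' (reference rescaled to exactly 1). All-zero peptides are excluded with a
#' warning.
#'
#' @param profiles Data frame: `peptide`, `dataset`, `pv`.
#' @param groups Named character vector mapping dataset id to group label.
#' @param ref Reference group label (set to 1), default `"CTRL"`.
#' @return An object of class `isoform_profile`: `profiles` (with a
#'   `norm_pv` column), `group_means`, `relative` (reference = 1).
#' @export
relative_isoform_abundance <- function(profiles, groups, ref = "CTRL") {
  stopifnot(all(c("peptide", "dataset", "pv") %in% names(profiles)))
  if (any(profiles$pv < 0)) stop("peak volumes must be >= 0", call. = FALSE)
  if (!all(profiles$dataset %in% names(groups))) {
    stop("every dataset needs a group label", call. = FALSE)
  }
  if (!ref %in% groups) stop("reference group absent from groups", call. = FALSE)
  keep <- vapply(split(profiles$pv, profiles$peptide), max, numeric(1)) > 0
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    warning("excluding all-zero peptide(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    profiles <- profiles[!profiles$peptide %in% dropped, ]
  }
  if (!nrow(profiles)) stop("no usable peptides", call. = FALSE)
  mx <- tapply(profiles$pv, profiles$peptide, max)
  profiles$norm_pv <- profiles$pv / mx[as.character(profiles$peptide)]
  grp <- groups[as.character(profiles$dataset)]
  gm <- tapply(profiles$norm_pv, grp, mean)
  rel <- gm / gm[[ref]]
  structure(list(profiles = profiles,
                 group_means = gm,
                 relative = rel), class = "isoform_profile")
}
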
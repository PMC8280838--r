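#' The 20 standard amino acids (one-letter codes)
#' @export
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' TMT condition labels in canonical order
#'
#' The ten conditions of the starvation time-course TMT 10-plex:
#' wild type (WT) and Ulk1/2 double-knockout (DKO) cells starved for 0,
#' 10, 30 or 60 minutes, or starved 60 min then refed 60 min (RF).
#' Profile vectors, matrices and tables throughout the package keep this
#' order: all WT time points first, then all DKO time points. The order
#' matters because reference-profile correlations are computed over the
#' concatenated WT and DKO segments.
#'
#' @return Character vector of length 10.
#' @export
tmt_conditions <- function() {
  paste(rep(c("WT", "DKO"), each = 5), c("0", "10", "30", "60", "RF"), sep = "_")
}

#' Column dialect for phosphosite tables
#'
#' Maps each canonical column name used by the package to the aliases
#' accepted in input files, so that MaxQuant-flavoured exports and the
#' package's own synthetic tables both parse. Matching is
#' case-insensitive. Supply a modified copy to [read_phosphosite_table()]
#' to parse other spellings.
#'
#' @return Named list: canonical name -> character vector of accepted
#'   header spellings (the canonical name itself is always accepted).
#' @export
default_dialect <- function() {
  list(
    site_id           = c("site_id", "Site ID"),
    gene              = c("gene", "Gene names", "Gene name"),
    protein           = c("protein", "Protein", "Proteins", "Leading proteins"),
    residue           = c("residue", "Amino acid"),
    position          = c("position", "Position"),
    window            = c("window", "Sequence window"),
    localization_prob = c("localization_prob", "Localization prob")
  )
}

silac_ratio_columns <- function(experiments = 1:3) {
  c(
    paste0("ratio_fwd_exp", experiments),
    paste0("ratio_rev_exp", experiments),
    paste0("control_exp", experiments)
  )
}

tmt_columns <- function() paste0("tmt_", tmt_conditions())

make_site_id <- function(gene, residue, position) {
  paste0(gene, "_", residue, position)
}

#' Read a phosphosite table
#'
#' Reads a tab-delimited phosphosite table (one row per localized
#' phosphorylation event) and validates every row against the site
#' invariants: a 15-character ±7 sequence window whose centre matches the
#' phosphoacceptor residue (S, T or Y), a 1-based positive position, and
#' a localization probability in \[0, 1\]. Rows failing any invariant are
#' collected into a rejects table with the reason that fired — they are
#' reported, never silently dropped. Multiplicity variants of the same
#' site (equal gene, position and residue) are collapsed to the
#' best-localized record, so downstream joins on `site_id` coincide with
#' joins on (gene, position, residue).
#'
#' Quantitative columns are carried through untouched when present:
#' `ratio_fwd_exp1..3` / `ratio_rev_exp1..3` (log2 DKO/WT SILAC ratios,
#' the reverse orientation already reciprocal-corrected at export),
#' `control_exp1..3` (log2 WT/WT label-swap controls) and
#' `tmt_WT_0` ... `tmt_DKO_RF` (raw TMT reporter intensities).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Column-name alias map, see [default_dialect()].
#' @return An object of class `phosphosite_table`: a list with elements
#'   `sites` (validated tibble) and `rejects` (tibble with columns
#'   `row`, `site_id`, `reason`).
#' @export
read_phosphosite_table <- function(path, dialect = default_dialect()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- map_dialect_names(names(raw), dialect)

  mandatory <- c("gene", "residue", "position", "window", "localization_prob")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "mandatory column(s) missing from ", path, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"protein" %in% names(raw)) raw$protein <- raw$gene
  if (!"site_id" %in% names(raw)) {
    raw$site_id <- make_site_id(raw$gene, raw$residue, raw$position)
  }
  validate_phosphosite_rows(raw)
}

map_dialect_names <- function(nms, dialect) {
  for (canonical in names(dialect)) {
    hits <- tolower(nms) %in% tolower(dialect[[canonical]])
    nms[hits] <- canonical
  }
  nms
}

validate_phosphosite_rows <- function(raw) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }

  flag(!raw$residue %in% c("S", "T", "Y"), "invalid residue")
  flag(nchar(raw$window) != 15, "window length")
  centre <- substr(raw$window, 8, 8)
  flag(nchar(raw$window) == 15 & centre != raw$residue, "window centre mismatch")
  pos <- suppressWarnings(as.numeric(raw$position))
  flag(is.na(pos) | pos < 1 | pos != round(pos), "invalid position")
  lp <- suppressWarnings(as.numeric(raw$localization_prob))
  flag(is.na(lp) | lp < 0 | lp > 1, "localization probability out of range")

  bad_window_chars <- nchar(raw$window) == 15 &
    !grepl(paste0("^[", paste(AMINO_ACIDS, collapse = ""), "_]+$"), raw$window)
  flag(bad_window_chars, "window has non-amino-acid characters")

  rejects <- tibble::tibble(
    row = which(!is.na(reason)),
    site_id = raw$site_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  sites <- raw[is.na(reason), , drop = FALSE]
  sites$position <- as.integer(sites$position)

  # collapse multiplicity variants of one phosphorylation event to the
  # best-localized record; site identity is (gene, position, residue)
  sites <- sites %>%
    dplyr::arrange(
      gene, position, residue,
      dplyr::desc(localization_prob), site_id
    ) %>%
    dplyr::distinct(gene, position, residue, .keep_all = TRUE) %>%
    dplyr::arrange(site_id)
  if (anyDuplicated(sites$site_id) > 0) {
    dup <- sites$site_id[duplicated(sites$site_id)]
    abort(paste0(
      "site_id duplicated across distinct (gene, position, residue) keys: ",
      paste(unique(dup), collapse = ", ")
    ))
  }

  structure(
    list(sites = tibble::as_tibble(sites), rejects = rejects),
    class = "phosphosite_table"
  )
}

#' @export
print.phosphosite_table <- function(x, ...) {
  cat("<phosphosite_table>\n")
  cat("  sites:  ", nrow(x$sites), "\n")
  cat("  rejects:", nrow(x$rejects), "\n")
  invisible(x)
}

#' Filter sites on phosphosite localization probability
#'
#' Retains sites whose localization probability is at least `min_prob`.
#' The default 0.75 is the usual class-I site convention for
#' search-engine phosphosite tables.
#'
#' @param sites Tibble of sites (needs a `localization_prob` column), or
#'   a `phosphosite_table` (its `sites` element is filtered).
#' @param min_prob Minimum localization probability, in \[0, 1\].
#' @return Filtered tibble of sites.
#' @export
apply_localization_filter <- function(sites, min_prob = 0.75) {
  if (!is.numeric(min_prob) || length(min_prob) != 1 ||
      is.na(min_prob) || min_prob < 0 || min_prob > 1) {
    abort("min_prob must be a single number in [0, 1]")
  }
  if (inherits(sites, "phosphosite_table")) sites <- sites$sites
  dplyr::filter(sites, localization_prob >= min_prob)
}

#' Write records to a tab-delimited file
#'
#' Deterministic, lossless TSV output: fixed column order (as given),
#' UTF-8, no quoting surprises; an empty collection yields a header-only
#' file. `write_results` followed by [read_phosphosite_table()] (for
#' site tables) round-trips all fields.
#'
#' @param records A data frame / tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two tab-separated symbol columns; lines starting with `#` are
#' comments. Symbols are uppercase-normalized, self-loops dropped and
#' duplicate unordered pairs collapsed.
#'
#' @param path Path to the edge-list file.
#' @return Tibble with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("from", "to"), comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  # tolerate a header row spelling out the column names
  if (nrow(raw) > 0 && tolower(raw$from[1]) %in% c("from", "protein_a")) {
    raw <- raw[-1, , drop = FALSE]
  }
  raw %>%
    dplyr::mutate(from = toupper(from), to = toupper(to)) %>%
    dplyr::filter(from != to) %>%
    dplyr::mutate(
      a = pmin(from, to), b = pmax(from, to)
    ) %>%
    dplyr::distinct(.data$a, .data$b) %>%
    dplyr::transmute(from = .data$a, to = .data$b)
}

#' Read an ortholog window-pair table
#'
#' Tab-delimited with columns `site_id`, `window` (screen species) and
#' `human_window`, both 15-mers aligned on the phosphoacceptor. Used by
#' the conservation filter.
#'
#' @param path Path to the table.
#' @return Tibble with the three columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "window", "human_window")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("ortholog table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(tab[need])
}
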
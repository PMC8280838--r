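#' Cross-reference the SILAC and TMT screens
#'
#' Joins the combined SILAC depletion calls with the TMT triage tiers on
#' site identity and applies the default shortlist rule: a site is
#' shortlisted when it is depleted in the SILAC screen AND reaches a TMT
#' tier (`primary` or `similarity_only`), OR is on the manual-inclusion
#' curation list (sites of biological interest detected in one screen
#' only). Manual exclusions override everything and carry their reason.
#' Every decision records the rule that fired, so membership is
#' reproducible from the output alone.
#'
#' @param silac_calls Tibble from [silac_depletion_calls()] (optionally
#'   through [flag_protein_level_change()]).
#' @param tmt_tiers Tibble from [assign_tiers()].
#' @param mode Join mode: `"outer"` (default), `"inner"` or `"left"`
#'   (left = SILAC side).
#' @param curation Optional list with elements `include` and `exclude`,
#'   each a data frame with columns `site_id` and `reason`.
#' @param accepted_tiers TMT tiers accepted by the shortlist rule.
#' @return Tibble of joined entries with logical `shortlisted` and
#'   character `rule` columns.
#' @export
crossref <- function(silac_calls, tmt_tiers,
                     mode = c("outer", "inner", "left"),
                     curation = NULL,
                     accepted_tiers = c("primary", "similarity_only")) {
  mode <- match.arg(mode)
  for (nm in c("silac_calls", "tmt_tiers")) {
    tab <- get(nm)
    if (anyDuplicated(tab$site_id) > 0) {
      abort(paste0("duplicate site_id key(s) in ", nm))
    }
  }
  join <- switch(mode,
    outer = dplyr::full_join,
    inner = dplyr::inner_join,
    left  = dplyr::left_join
  )
  entries <- join(silac_calls, tmt_tiers, by = "site_id")

  inc <- curation$include
  exc <- curation$exclude
  entries$manual_include <- entries$site_id %in% inc$site_id
  entries$manual_exclude <- entries$site_id %in% exc$site_id

  depleted <- !is.na(entries$combined_depleted) & entries$combined_depleted
  tiered <- !is.na(entries$tier) & entries$tier %in% accepted_tiers
  entries %>%
    dplyr::mutate(
      shortlisted = (depleted & tiered | manual_include) & !manual_exclude,
      rule = dplyr::case_when(
        manual_exclude ~ paste0(
          "manual_exclude: ",
          exc$reason[match(site_id, exc$site_id)]
        ),
        depleted & tiered ~ "silac_depleted+tmt_tier",
        manual_include ~ paste0(
          "manual_include: ",
          inc$reason[match(site_id, inc$site_id)]
        ),
        TRUE ~ "below_threshold"
      )
    )
}

#' Cross-species conservation of a phosphosite window
#'
#' Fractional identity between two 15-mer windows aligned on the
#' phosphoacceptor; positions where either window carries the terminal
#' pad character `_` are excluded from both numerator and denominator.
#' Symmetric in its two arguments.
#'
#' @param window_a,window_b Character vectors of 15-mer windows.
#' @return Numeric vector of identities in \[0, 1\].
#' @export
conservation_identity <- function(window_a, window_b) {
  if (any(nchar(window_a) != 15) || any(nchar(window_b) != 15)) {
    abort("windows must be exactly 15 characters")
  }
  purrr::map2_dbl(window_a, window_b, function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    use <- ca != "_" & cb != "_"
    if (!any(use)) return(NA_real_)
    mean(ca[use] == cb[use])
  })
}

#' Conservation filter against the human ortholog window
#'
#' Candidate substrates from the murine screens are kept only when the
#' surrounding sequence is conserved in human: the window identity must
#' reach `min_identity` and the human window must retain S or T at the
#' phosphoacceptor (otherwise the site cannot exist in human and is
#' dropped regardless of identity).
#'
#' @param window Screen-species 15-mer window(s).
#' @param human_window Human ortholog window(s), positionally aligned on
#'   the phosphoacceptor.
#' @param min_identity Minimum fractional identity to keep.
#' @return Tibble with columns `identity` and logical `keep`.
#' @export
conservation_filter <- function(window, human_window, min_identity = 0.6) {
  identity <- conservation_identity(window, human_window)
  centre_ok <- substr(human_window, 8, 8) %in% c("S", "T")
  tibble::tibble(
    identity = identity,
    keep = centre_ok & !is.na(identity) & identity >= min_identity
  )
}

#' Shortest-path distance to the ULK kinases in a PPI network
#'
#' Unweighted (breadth-first) shortest-path distance from each target
#' protein to the nearest anchor in a protein-protein interaction edge
#' list. Used as supporting annotation — proteins within 2 nodes of
#' ULK1/ULK2 are plausible direct substrates — never as a hard filter.
#' Targets (or anchors) absent from the graph get `Inf`.
#'
#' @param edges Edge-list tibble (`from`, `to`), see [read_edge_list()].
#' @param targets Character vector of protein symbols (case-insensitive).
#' @param anchors Anchor protein symbols.
#' @return Named numeric vector of distances (may be `Inf`).
#' @export
ppi_distance <- function(edges, targets, anchors = c("ULK1", "ULK2")) {
  targets_uc <- toupper(targets)
  anchors <- toupper(anchors)
  g <- igraph::graph_from_data_frame(
    data.frame(from = toupper(edges$from), to = toupper(edges$to)),
    directed = FALSE
  )
  nodes <- igraph::V(g)$name
  anchors_in <- intersect(anchors, nodes)
  out <- rep(Inf, length(targets))
  names(out) <- targets
  if (length(anchors_in) == 0) return(out)
  present <- targets_uc %in% nodes
  if (any(present)) {
    d <- igraph::distances(g, v = targets_uc[present], to = anchors_in)
    out[present] <- apply(d, 1, min)
  }
  out
}

#' Design peptide-array variants for a shortlisted site
#'
#' Emits the up-to-four 15-mer peptides arrayed per site for in vitro
#' kinase triage: the wild-type window (`WT`); the single phosphomutant
#' with the central phosphoacceptor changed to alanine (`single_SA`);
#' the total phosphomutant with every serine/threonine changed to
#' alanine (`total_STA`), emitted only when the window carries S/T
#' beyond the centre (otherwise it would duplicate `single_SA`); and the
#' murine window (`murine`) when it differs from the human one.
#'
#' @param window 15-mer window with S or T at the centre.
#' @param murine_window Optional 15-mer ortholog window.
#' @return Tibble with columns `label` and `sequence`.
#' @export
design_peptide_variants <- function(window, murine_window = NULL) {
  if (nchar(window) != 15) abort("window must be exactly 15 characters")
  centre <- substr(window, 8, 8)
  if (!centre %in% c("S", "T")) {
    abort("window centre must be a serine or threonine phosphoacceptor")
  }
  single <- window
  substr(single, 8, 8) <- "A"
  variants <- tibble::tibble(label = "WT", sequence = window) %>%
    dplyr::add_row(label = "single_SA", sequence = single)
  flanks <- paste0(substr(window, 1, 7), substr(window, 9, 15))
  if (grepl("[ST]", flanks)) {
    variants <- dplyr::add_row(
      variants,
      label = "total_STA", sequence = gsub("[ST]", "A", window)
    )
  }
  if (!is.null(murine_window) && !is.na(murine_window) &&
      murine_window != window) {
    if (nchar(murine_window) != 15) {
      abort("murine_window must be exactly 15 characters")
    }
    variants <- dplyr::add_row(
      variants, label = "murine", sequence = murine_window
    )
  }
  variants
}

#' Write the shortlist with its audit trail
#'
#' Writes the cross-referenced entries as a TSV sorted by `site_id`,
#' every row carrying the inclusion/exclusion rule that fired. Rerunning
#' on identical inputs produces byte-identical output.
#'
#' @param entries Tibble from [crossref()] (possibly with annotation
#'   columns added).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_shortlist <- function(entries, path) {
  out <- dplyr::arrange(entries, site_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
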
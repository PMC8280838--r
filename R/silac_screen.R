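#' SILAC depletion-screen thresholds
#'
#' Bundle of the thresholds governing the SILAC depletion screen.
#' Defaults reproduce the screen definition: a site counts as depleted in
#' an experiment when its log2 DKO/WT ratio is strictly below −1.5 in
#' both labelling orientations, sites showing label-dependent enrichment
#' (|log2 WT/WT| strictly above 0.5 in any control mix) are excluded,
#' and depletion in at least 1 of the 3 independent experiments is
#' required for the combined call.
#'
#' @param depletion_log2 Per-experiment log2 DKO/WT cutoff (negative).
#' @param control_band Half-width of the accepted WT/WT control band.
#' @param combine_rule `"both_orientations"` (forward AND reverse each
#'   below the cutoff — the stricter reading) or
#'   `"mean_of_orientations"` (the fwd/rev average below the cutoff).
#' @param min_experiments Number of experiments (1–3) that must call a
#'   site depleted for the combined call.
#' @return A `silac_thresholds` list.
#' @export
silac_thresholds <- function(depletion_log2 = -1.5,
                             control_band = 0.5,
                             combine_rule = c("both_orientations",
                                              "mean_of_orientations"),
                             min_experiments = 1L) {
  combine_rule <- match.arg(combine_rule)
  if (!is.numeric(depletion_log2) || depletion_log2 >= 0) {
    abort("depletion_log2 must be negative")
  }
  if (!is.numeric(control_band) || control_band <= 0) {
    abort("control_band must be positive")
  }
  min_experiments <- as.integer(min_experiments)
  if (!min_experiments %in% 1:3) abort("min_experiments must be 1, 2 or 3")
  structure(
    list(
      depletion_log2 = depletion_log2,
      control_band = control_band,
      combine_rule = combine_rule,
      min_experiments = min_experiments
    ),
    class = "silac_thresholds"
  )
}

#' Per-experiment depletion call from a forward/reverse ratio pair
#'
#' Vectorized over sites. Both orientations report log2 DKO/WT (the
#' reverse orientation is reciprocal-corrected at ingestion). Under
#' `both_orientations` a site is depleted when forward AND reverse are
#' strictly below the cutoff; under `mean_of_orientations` when their
#' mean is. A missing orientation yields `"incomplete"`.
#'
#' @param fwd,rev Numeric vectors of log2 DKO/WT ratios.
#' @param thresholds A [silac_thresholds()] object.
#' @return Character vector: `"depleted"`, `"not_depleted"` or
#'   `"incomplete"`.
#' @export
call_depletion <- function(fwd, rev, thresholds = silac_thresholds()) {
  stopifnot(length(fwd) == length(rev))
  t0 <- thresholds$depletion_log2
  depleted <- switch(thresholds$combine_rule,
    both_orientations = fwd < t0 & rev < t0,
    mean_of_orientations = (fwd + rev) / 2 < t0
  )
  out <- ifelse(depleted, "depleted", "not_depleted")
  out[is.na(fwd) | is.na(rev)] <- "incomplete"
  out
}

#' Flag label-dependent enrichment from WT/WT control mixes
#'
#' A site is label-biased when any of its WT/WT control log2 ratios
#' falls strictly outside the band \[−control_band, +control_band\]:
#' a true WT/WT mix should show no change, so such sites owe their
#' SILAC ratio (at least partly) to the label, not the genotype.
#' With no controls observed the site cannot be excluded (returns FALSE).
#'
#' @param controls Numeric vector (one site) or matrix/data frame with
#'   one row per site of log2 WT/WT control ratios; NAs are ignored.
#' @param thresholds A [silac_thresholds()] object.
#' @return Logical vector, one element per site.
#' @export
flag_label_bias <- function(controls, thresholds = silac_thresholds()) {
  band <- thresholds$control_band
  if (is.null(dim(controls))) {
    return(isTRUE(any(abs(controls) > band, na.rm = TRUE)))
  }
  m <- as.matrix(controls)
  apply(m, 1, function(x) isTRUE(any(abs(x) > band, na.rm = TRUE)))
}

#' Combined depletion calls across experiments and controls
#'
#' Runs the full SILAC screen on a wide site table carrying columns
#' `ratio_fwd_exp1..3`, `ratio_rev_exp1..3` and `control_exp1..3`
#' (any subset of experiments may be present). The combined call is:
#' depleted in at least `min_experiments` experiments AND not
#' label-biased.
#'
#' @param sites Site tibble (e.g. `read_phosphosite_table(...)$sites`).
#' @param thresholds A [silac_thresholds()] object.
#' @param experiments Integer vector of experiment numbers to use.
#' @return Tibble with one row per site: `site_id`, `gene`, per-
#'   experiment call columns `exp1..exp3`, `n_depleted`, `label_biased`,
#'   `combined_depleted`.
#' @export
silac_depletion_calls <- function(sites, thresholds = silac_thresholds(),
                                  experiments = 1:3) {
  calls <- tibble::tibble(site_id = sites$site_id, gene = sites$gene)
  n_depleted <- integer(nrow(sites))
  for (e in experiments) {
    fcol <- paste0("ratio_fwd_exp", e)
    rcol <- paste0("ratio_rev_exp", e)
    if (!all(c(fcol, rcol) %in% names(sites))) {
      calls[[paste0("exp", e)]] <- "incomplete"
      next
    }
    call_e <- call_depletion(sites[[fcol]], sites[[rcol]], thresholds)
    calls[[paste0("exp", e)]] <- call_e
    n_depleted <- n_depleted + (call_e == "depleted")
  }
  ctrl_cols <- intersect(paste0("control_exp", experiments), names(sites))
  if (length(ctrl_cols) > 0) {
    calls$label_biased <- flag_label_bias(sites[ctrl_cols], thresholds)
  } else {
    calls$label_biased <- FALSE
  }
  calls$n_depleted <- n_depleted
  calls$combined_depleted <-
    n_depleted >= thresholds$min_experiments & !calls$label_biased
  calls
}

#' Flag proteins whose sites are depleted en bloc
#'
#' When (nearly) every detected site of a protein is depleted, and the
#' sequence contexts are unrelated, the signal is more plausibly a
#' change in protein abundance than a coordinated loss of
#' kinase-dependent phosphorylation. Such proteins are flagged for
#' caution; their sites are annotated, never removed.
#'
#' @param calls Output of [silac_depletion_calls()] (needs `gene` and
#'   `combined_depleted`).
#' @param min_sites Minimum number of detected sites on the protein for
#'   the flag to be considered.
#' @param min_fraction Minimum fraction of the protein's sites that must
#'   be depleted.
#' @return `calls` with a logical `protein_level_flag` column added.
#' @export
flag_protein_level_change <- function(calls, min_sites = 3,
                                      min_fraction = 0.8) {
  per_gene <- calls %>%
    dplyr::group_by(gene) %>%
    dplyr::summarise(
      n_sites = dplyr::n(),
      frac_depleted = mean(combined_depleted),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      protein_level_flag = n_sites >= min_sites & frac_depleted >= min_fraction
    )
  calls %>%
    dplyr::left_join(
      per_gene[c("gene", "protein_level_flag")],
      by = "gene"
    )
}

#' Forward-vs-reverse scatter table for one experiment
#'
#' Returns the per-site (forward, reverse) log2 ratio pairs with a
#' quadrant label drawn relative to the depletion cutoff and its mirror:
#' `lower_left` (both orientations below `depletion_log2` — the depleted
#' quadrant, consistent with [call_depletion()] under the
#' both-orientations rule), `upper_right` (both above
#' `-depletion_log2`, the enriched quadrant), `upper_left`,
#' `lower_right`, or `centre`.
#'
#' @param sites Site tibble with the SILAC ratio columns.
#' @param experiment Experiment number (1–3).
#' @param thresholds A [silac_thresholds()] object.
#' @return Tibble `site_id`, `fwd`, `rev`, `quadrant`.
#' @export
scatter_table <- function(sites, experiment,
                          thresholds = silac_thresholds()) {
  fcol <- paste0("ratio_fwd_exp", experiment)
  rcol <- paste0("ratio_rev_exp", experiment)
  if (!all(c(fcol, rcol) %in% names(sites))) {
    abort(paste0("no SILAC ratio columns for experiment ", experiment))
  }
  lo <- thresholds$depletion_log2
  hi <- -thresholds$depletion_log2
  fwd <- sites[[fcol]]
  rev <- sites[[rcol]]
  quadrant <- dplyr::case_when(
    is.na(fwd) | is.na(rev) ~ NA_character_,
    fwd < lo & rev < lo ~ "lower_left",
    fwd > hi & rev > hi ~ "upper_right",
    fwd < lo & rev > hi ~ "upper_left",
    fwd > hi & rev < lo ~ "lower_right",
    TRUE ~ "centre"
  )
  tibble::tibble(site_id = sites$site_id, fwd = fwd, rev = rev,
                 quadrant = quadrant)
}
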
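#' Extract the TMT intensity matrix from a site table
#'
#' @param sites Site tibble with columns `tmt_WT_0` ... `tmt_DKO_RF`.
#' @return Numeric matrix, rows named by `site_id`, columns by
#'   [tmt_conditions()] in canonical order.
#' @export
as_tmt_matrix <- function(sites) {
  cols <- tmt_columns()
  missing <- setdiff(cols, names(sites))
  if (length(missing) > 0) {
    abort(paste0("missing TMT column(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(sites[cols])
  rownames(m) <- sites$site_id
  colnames(m) <- tmt_conditions()
  m
}

#' Retain only profiles quantified in all 10 conditions
#'
#' A usable time-course profile needs a positive reporter intensity in
#' every one of the 10 genotype-by-time conditions; profiles with
#' missing, zero or negative entries are removed.
#'
#' @param profiles TMT intensity matrix (see [as_tmt_matrix()]).
#' @return The matrix restricted to complete rows.
#' @export
complete_profiles_only <- function(profiles) {
  ok <- apply(profiles, 1, function(x) all(is.finite(x)) && all(x > 0))
  profiles[ok, , drop = FALSE]
}

#' Normalize TMT time-course profiles
#'
#' Three modes on the raw reporter intensities:
#' \describe{
#'   \item{`log10_raw`}{`log10(intensity)` — the scale on which the
#'     triage contrasts are defined.}
#'   \item{`anchored_to_DKO0`}{`log10(intensity) - log10(intensity(DKO, 0 min))`
#'     per profile, so every profile is 0 at DKO 0 min — the scale used
#'     for profile plots and clustering.}
#'   \item{`relative_log2`}{`log2(intensity / mean-over-10-conditions(intensity))`
#'     — the heat-map scale; for each profile the 2^values average to 1
#'     exactly.}
#' }
#'
#' @param profiles TMT intensity matrix with complete positive rows.
#' @param mode Normalization mode.
#' @return Numeric matrix of normalized values with attribute `mode`.
#' @export
normalize_profiles <- function(profiles,
                               mode = c("log10_raw", "anchored_to_DKO0",
                                        "relative_log2")) {
  mode <- match.arg(mode)
  bad <- which(!(is.finite(profiles) & profiles > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "non-positive or missing intensity at site ",
      rownames(profiles)[bad[1, 1]] %||% bad[1, 1],
      ", condition ", colnames(profiles)[bad[1, 2]]
    ))
  }
  out <- switch(mode,
    log10_raw = log10(profiles),
    anchored_to_DKO0 = log10(profiles) - log10(profiles[, "DKO_0"]),
    relative_log2 = log2(profiles / rowMeans(profiles))
  )
  attr(out, "mode") <- mode
  out
}

#' Triage contrast variables and reference-profile similarity
#'
#' Computes, per profile, the three contrasts used to triage the TMT
#' time course plus similarity to a reference profile:
#' \describe{
#'   \item{v1}{WT 60 min − WT 0 min: phosphorylation gained over 60 min
#'     starvation in WT cells.}
#'   \item{v2}{WT 60 min − DKO 60 min: phosphorylation lost in DKO
#'     relative to WT at 60 min starvation.}
#'   \item{v3}{WT 60 min − WT refed: phosphorylation reversed on
#'     refeeding in WT cells.}
#'   \item{v4}{Pearson correlation with the reference profile (the
#'     known substrate Prkab2 S38 by default) over the 10 conditions in
#'     canonical order.}
#' }
#' v1–v3 are in log10(TMT enrichment) units; they are identical in
#' `log10_raw` and `anchored_to_DKO0` modes since the anchor cancels.
#'
#' @param normalized Normalized profile matrix (`log10_raw` or
#'   `anchored_to_DKO0` mode).
#' @param reference Either a `site_id` present in `normalized`, or a
#'   numeric length-10 vector of normalized values in canonical
#'   condition order. Must not be constant.
#' @return Tibble `site_id`, `v1`, `v2`, `v3`, `v4`.
#' @export
triage_variables <- function(normalized, reference) {
  if (is.character(reference)) {
    if (!reference %in% rownames(normalized)) {
      abort(paste0("reference profile '", reference,
                   "' not found in the normalized table"))
    }
    reference <- normalized[reference, ]
  }
  reference <- as.numeric(reference)
  if (length(reference) != 10) abort("reference profile must have 10 values")
  if (sd(reference) == 0) {
    abort("reference profile is constant; similarity undefined")
  }
  tibble::tibble(
    site_id = rownames(normalized),
    v1 = unname(normalized[, "WT_60"] - normalized[, "WT_0"]),
    v2 = unname(normalized[, "WT_60"] - normalized[, "DKO_60"]),
    v3 = unname(normalized[, "WT_60"] - normalized[, "WT_RF"]),
    v4 = unname(apply(normalized, 1, function(x) {
      if (sd(x) == 0) NA_real_ else cor(x, reference)
    }))
  )
}

#' Assign triage tiers from the contrast variables
#'
#' `primary` when all three contrasts pass their thresholds
#' (`v1 >= theta1 & v2 >= theta2 & v3 >= theta3`) — the stringent tier,
#' given precedence when shortlisting; otherwise `similarity_only` when
#' the reference correlation is strictly above `r_min`; otherwise
#' `none`. Thresholds default to 0.1 log10 units per contrast
#' (about a 26% intensity change) and `r_min = 0.7`.
#'
#' @param vars Tibble from [triage_variables()].
#' @param theta1,theta2,theta3 Contrast thresholds, log10 units.
#' @param r_min Reference-correlation threshold (strict `>`).
#' @return `vars` with a `tier` column added; the thresholds used are
#'   recorded in the `thresholds` attribute.
#' @export
assign_tiers <- function(vars, theta1 = 0.1, theta2 = 0.1, theta3 = 0.1,
                         r_min = 0.7) {
  primary <- vars$v1 >= theta1 & vars$v2 >= theta2 & vars$v3 >= theta3
  primary[is.na(primary)] <- FALSE
  similar <- !primary & !is.na(vars$v4) & vars$v4 > r_min
  out <- dplyr::mutate(vars, tier = dplyr::case_when(
    primary ~ "primary",
    similar ~ "similarity_only",
    TRUE ~ "none"
  ))
  attr(out, "thresholds") <-
    list(theta1 = theta1, theta2 = theta2, theta3 = theta3, r_min = r_min)
  out
}

#' Select the most variable profiles
#'
#' Top `n` profiles by variance of the normalized values across the 10
#' conditions, with deterministic tie-breaking by `site_id`.
#'
#' @param normalized Normalized profile matrix.
#' @param n Number of profiles to keep.
#' @return The matrix restricted to the selected rows.
#' @export
select_most_variable <- function(normalized, n) {
  v <- apply(normalized, 1, var)
  ord <- order(-v, rownames(normalized))
  normalized[ord[seq_len(min(n, nrow(normalized)))], , drop = FALSE]
}

#' Correlation clustering of time-course profiles
#'
#' Hierarchical agglomerative clustering of profiles under the
#' correlation distance `1 - Pearson(profile_i, profile_j)` with average
#' linkage, cutting the tree at `k` clusters. Profiles with (numerically)
#' zero variance have no defined correlation and are assigned to a
#' dedicated `"flat"` cluster, excluded from the distance computation.
#' Cluster labels are canonicalized by order of first appearance over
#' sites sorted by `site_id`, so the labelling is invariant under input
#' row permutation.
#'
#' @param normalized Normalized profile matrix.
#' @param k Number of clusters (in addition to `"flat"` if present).
#' @param flat_tol Standard-deviation tolerance below which a profile is
#'   considered flat.
#' @return List with `labels` (tibble `site_id`, `cluster`) and
#'   `cluster_means` (matrix: per-cluster mean profile over the 10
#'   conditions, covering the WT and DKO segments).
#' @export
correlation_cluster <- function(normalized, k = 6, flat_tol = 1e-10) {
  sds <- apply(normalized, 1, sd)
  flat <- sds <= flat_tol
  varying <- normalized[!flat, , drop = FALSE]
  if (nrow(varying) < k) {
    abort(paste0("need at least k = ", k, " non-flat profiles, have ",
                 nrow(varying)))
  }
  # sort rows first so hclust tie-breaks do not depend on input order
  varying <- varying[order(rownames(varying)), , drop = FALSE]
  d <- as.dist(1 - cor(t(varying)))
  raw_labels <- cutree(hclust(d, method = "average"), k = k)
  canonical <- match(raw_labels, unique(raw_labels))
  labels <- tibble::tibble(
    site_id = c(rownames(varying), rownames(normalized)[flat]),
    cluster = c(paste0("C", canonical),
                rep("flat", sum(flat)))
  ) %>% dplyr::arrange(site_id)
  means <- do.call(rbind, lapply(split(labels$site_id, labels$cluster),
    function(ids) colMeans(normalized[ids, , drop = FALSE])
  ))
  list(labels = labels, cluster_means = means)
}
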
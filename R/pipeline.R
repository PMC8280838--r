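#' Pipeline configuration
#'
#' Nested configuration for the end-to-end screen: every threshold any
#' stage consumes appears here and is serialized into the run log, so a
#' run is reproducible from its outputs. `read_pipeline_config()` loads
#' a YAML file and validates it against this structure; unknown keys are
#' rejected.
#'
#' @param localization_min_prob Minimum phosphosite localization
#'   probability.
#' @param silac List of [silac_thresholds()] arguments plus
#'   `protein_level_min_sites` / `protein_level_min_fraction` for the
#'   protein-level-change flag.
#' @param motif Consensus-motif notation string (see [parse_motif()]).
#' @param tmt List: contrast thresholds `theta1..theta3`, correlation
#'   cutoff `r_min`, `reference_site`, clustering `k`, and optional
#'   `n_most_variable` (NULL = cluster all complete profiles).
#' @param shortlist List: conservation `min_identity`, curation
#'   `include` / `exclude` site-id + reason tables (as lists of
#'   two-element lists in YAML).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(localization_min_prob = 0.75,
                            silac = list(),
                            motif = format_motif(ulk1_motif()),
                            tmt = list(),
                            shortlist = list()) {
  defaults <- list(
    localization_min_prob = localization_min_prob,
    silac = list(
      depletion_log2 = -1.5,
      control_band = 0.5,
      combine_rule = "both_orientations",
      min_experiments = 1L,
      protein_level_min_sites = 3,
      protein_level_min_fraction = 0.8
    ),
    motif = motif,
    tmt = list(
      theta1 = 0.1, theta2 = 0.1, theta3 = 0.1,
      r_min = 0.7,
      reference_site = "Prkab2_S38",
      k = 6L,
      n_most_variable = NULL
    ),
    shortlist = list(
      min_identity = 0.6,
      include = NULL,
      exclude = NULL
    )
  )
  cfg <- merge_config(defaults, list(silac = silac, tmt = tmt,
                                     shortlist = shortlist))
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) {
      abort(paste0("unknown configuration key: ", path, key))
    }
    if (is.list(defaults[[key]]) && is.list(overrides[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      paste0(path, key, "."))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("localization_min_prob", "silac", "motif", "tmt", "shortlist")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

curation_tables <- function(cfg) {
  as_tab <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    tibble::tibble(
      site_id = vapply(x, function(e) as.character(e$site_id), character(1)),
      reason = vapply(x, function(e) as.character(e$reason %||% ""),
                      character(1))
    )
  }
  list(include = as_tab(cfg$shortlist$include),
       exclude = as_tab(cfg$shortlist$exclude))
}

#' Run the full triage pipeline
#'
#' Wires the stages end to end: read and validate the site table,
#' localization filter, SILAC depletion calls with label-bias exclusion
#' and protein-level flags, consensus-motif annotation and depleted-set
#' enrichment logo, TMT completeness filter, normalisation, contrast +
#' similarity triage and correlation clustering, cross-referencing into
#' the shortlist with conservation and PPI annotation, and
#' peptide-array variant design for every shortlisted site. All inputs
#' are checked before any output is written; identical inputs and
#' configuration yield byte-identical outputs.
#'
#' Files written to `out_dir`: `rejects.tsv`, `depletion_calls.tsv`,
#' `motif_matches.tsv`, `enrichment_matrix.tsv`, `tmt_tiers.tsv`,
#' `clusters.tsv`, `shortlist.tsv`, `peptide_variants.tsv` and
#' `run_config.yaml` (the full configuration, its hash and the package
#' version).
#'
#' @param sites_path Phosphosite table (TSV, see
#'   [read_phosphosite_table()]).
#' @param out_dir Output directory (created if needed).
#' @param ppi_path Optional PPI edge list (TSV).
#' @param orthologs_path Optional ortholog window-pair table (TSV).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_all <- function(sites_path, out_dir,
                    ppi_path = NULL, orthologs_path = NULL,
                    config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(sites_path, ppi_path, orthologs_path)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }

  table <- read_phosphosite_table(sites_path)
  sites <- apply_localization_filter(table$sites,
                                     config$localization_min_prob)

  thr <- silac_thresholds(
    depletion_log2 = config$silac$depletion_log2,
    control_band = config$silac$control_band,
    combine_rule = config$silac$combine_rule,
    min_experiments = config$silac$min_experiments
  )
  calls <- silac_depletion_calls(sites, thr) %>%
    flag_protein_level_change(
      min_sites = config$silac$protein_level_min_sites,
      min_fraction = config$silac$protein_level_min_fraction
    )

  motif <- parse_motif(config$motif)
  motif_tab <- tibble::tibble(
    site_id = sites$site_id,
    motif_match = motif_match(motif, sites$window)
  )
  depleted_windows <- sites$window[calls$combined_depleted]
  logo <- if (length(depleted_windows) > 0) {
    enrichment_matrix(depleted_windows, sites$window)
  } else NULL

  profiles <- complete_profiles_only(as_tmt_matrix(sites))
  normalized <- normalize_profiles(profiles, "anchored_to_DKO0")
  tiers <- triage_variables(normalized, config$tmt$reference_site) %>%
    assign_tiers(
      theta1 = config$tmt$theta1, theta2 = config$tmt$theta2,
      theta3 = config$tmt$theta3, r_min = config$tmt$r_min
    )
  to_cluster <- if (!is.null(config$tmt$n_most_variable)) {
    select_most_variable(normalized, config$tmt$n_most_variable)
  } else normalized
  clusters <- correlation_cluster(to_cluster, k = config$tmt$k)

  entries <- crossref(calls, tiers, mode = "outer",
                      curation = curation_tables(config))
  if (!is.null(orthologs_path)) {
    orth <- read_ortholog_table(orthologs_path)
    cons <- conservation_filter(orth$window, orth$human_window,
                                config$shortlist$min_identity)
    orth$conservation_identity <- cons$identity
    orth$conserved <- cons$keep
    entries <- entries %>%
      dplyr::left_join(
        orth[c("site_id", "conservation_identity", "conserved")],
        by = "site_id"
      ) %>%
      dplyr::mutate(
        rule = ifelse(shortlisted & !is.na(conserved) & !conserved,
                      "dropped: low conservation in H. sapiens", rule),
        shortlisted = shortlisted & (is.na(conserved) | conserved)
      )
  }
  if (!is.null(ppi_path)) {
    edges <- read_edge_list(ppi_path)
    gene_of <- setNames(sites$gene, sites$site_id)
    entries$ppi_distance <-
      unname(ppi_distance(edges, gene_of[entries$site_id]))
  }

  shortlisted <- entries[entries$shortlisted, , drop = FALSE]
  window_of <- setNames(sites$window, sites$site_id)
  peptides <- purrr::map_dfr(shortlisted$site_id, function(id) {
    w <- window_of[[id]]
    if (is.null(w) || is.na(w) || !substr(w, 8, 8) %in% c("S", "T")) {
      return(NULL)
    }
    dplyr::mutate(design_peptide_variants(w), site_id = id,
                  .before = 1)
  })
  if (nrow(peptides) == 0) {
    peptides <- tibble::tibble(site_id = character(), label = character(),
                               sequence = character())
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    rejects = file.path(out_dir, "rejects.tsv"),
    depletion_calls = file.path(out_dir, "depletion_calls.tsv"),
    motif_matches = file.path(out_dir, "motif_matches.tsv"),
    enrichment_matrix = file.path(out_dir, "enrichment_matrix.tsv"),
    tmt_tiers = file.path(out_dir, "tmt_tiers.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    shortlist = file.path(out_dir, "shortlist.tsv"),
    peptide_variants = file.path(out_dir, "peptide_variants.tsv"),
    run_config = file.path(out_dir, "run_config.yaml")
  )
  write_results(table$rejects, paths$rejects)
  write_results(calls, paths$depletion_calls)
  write_results(motif_tab, paths$motif_matches)
  if (!is.null(logo)) {
    logo_tab <- tibble::as_tibble(unclass(logo), rownames = "residue")
    write_results(logo_tab, paths$enrichment_matrix)
  }
  write_results(tiers, paths$tmt_tiers)
  write_results(clusters$labels, paths$clusters)
  emit_shortlist(entries, paths$shortlist)
  write_results(peptides, paths$peptide_variants)

  provenance <- list(
    package = "phosphotriage",
    version = as.character(utils::packageVersion("phosphotriage")),
    config_hash = rlang::hash(unclass(config)),
    config = strip_nulls(unclass(config))
  )
  yaml::write_yaml(provenance, paths$run_config)

  invisible(list(
    sites = sites, rejects = table$rejects, calls = calls,
    motif_matches = motif_tab, tiers = tiers, clusters = clusters,
    entries = entries, peptides = peptides, paths = paths
  ))
}

strip_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, strip_nulls)
  x[!vapply(x, is.null, logical(1))]
}
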
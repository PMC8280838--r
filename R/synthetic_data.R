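#' Configuration for the synthetic-screen generator
#'
#' Defines the conditions of a simulated paired SILAC + TMT substrate
#' screen with known ground truth. Defaults emulate the real screens'
#' regime: thousands of proteins with a handful of localized sites each,
#' roughly 5 true kinase substrates per 1,000 sites, strong depletion of
#' substrate sites in the knockout (log2 DKO/WT centred on −2.5,
#' truncated at −1.8 so a planted "depleted" site genuinely sits below
#' the −1.5 screen cutoff), a Prkab2-S38-like substrate time course
#' (WT phosphorylation rising over 60 min starvation, partially reversed
#' on refeeding, DKO flat at a lower baseline), plus the two confounder
#' classes the pipeline must reject: label-bias artifacts visible in the
#' WT/WT controls, and protein-level changers (whole proteins shifted en
#' bloc with non-motif, poorly conserved windows). A configurable slice
#' of the background is proline-directed (+1 P windows with
#' starvation-responsive but genotype-independent dynamics).
#'
#' @param n_proteins Number of simulated proteins.
#' @param sites_per_protein_lambda Sites per protein are
#'   `1 + Poisson(lambda)`.
#' @param true_substrate_rate Fraction of sites planted as true
#'   substrates (ignored when `n_true_substrates` is given).
#' @param n_true_substrates Optional absolute count of true substrates.
#' @param substrate_effect_mean,substrate_effect_sd Log2 DKO/WT depletion
#'   effect distribution (normal, truncated above at
#'   `substrate_effect_cap`).
#' @param substrate_effect_cap Upper truncation of planted depletion
#'   effects (log2).
#' @param tmt_dynamics List: `starvation_rise` (log10 increments at 0,
#'   10, 30, 60 min), `refeed_level` (log10 above baseline after
#'   refeeding) and `dko_deficit` (log10 deficit of the flat DKO
#'   segment).
#' @param fraction_label_bias,fraction_protein_level,fraction_proline_background
#'   Fractions of sites in the respective confounder/background classes.
#' @param noise_sd_silac Per-orientation, per-experiment SILAC noise sd
#'   (log2); control WT/WT ratios get noise at 0.3 x this sd.
#' @param noise_sd_tmt Per-condition TMT noise sd (log10).
#' @param fraction_incomplete_tmt Fraction of sites missing at least one
#'   TMT condition.
#' @param ppi_within2_fraction Fraction of true-substrate proteins
#'   placed within 2 edges of ULK1/ULK2 in the simulated PPI network.
#' @param motif Consensus motif used to build substrate windows.
#' @param seed Integer seed; fully determines the output.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_proteins = 2000,
                             sites_per_protein_lambda = 1.5,
                             true_substrate_rate = 0.005,
                             n_true_substrates = NULL,
                             substrate_effect_mean = -2.5,
                             substrate_effect_sd = 0.4,
                             substrate_effect_cap = -1.8,
                             tmt_dynamics = list(
                               starvation_rise = c(0, 0.15, 0.30, 0.45),
                               refeed_level = 0.10,
                               dko_deficit = 0.50
                             ),
                             fraction_label_bias = 0.01,
                             fraction_protein_level = 0.01,
                             fraction_proline_background = 0.15,
                             noise_sd_silac = 0.4,
                             noise_sd_tmt = 0.05,
                             fraction_incomplete_tmt = 0.03,
                             ppi_within2_fraction = 0.6,
                             motif = ulk1_motif(),
                             seed = 1L) {
  cfg <- as.list(environment())
  fractions <- true_substrate_rate + fraction_label_bias +
    fraction_protein_level + fraction_proline_background
  if (fractions > 1) abort("class fractions sum to more than 1")
  if (noise_sd_silac < 0 || noise_sd_tmt < 0) abort("noise sd must be >= 0")
  if (substrate_effect_cap >= 0) abort("substrate_effect_cap must be negative")
  stopifnot(length(tmt_dynamics$starvation_rise) == 4)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

rnorm_trunc_upper <- function(n, mean, sd, upper) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x > upper)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

sample_window <- function(n, motif = NULL, center = NULL,
                          force = list(), avoid_motif_at = NULL) {
  # 15 x n character matrix, uniform over the 20 amino acids
  m <- matrix(sample(AMINO_ACIDS, 15 * n, replace = TRUE), nrow = 15)
  m[8, ] <- sample(c("S", "T"), n, replace = TRUE)
  if (!is.null(motif)) {
    for (i in seq_along(motif$positions)) {
      p <- motif$positions[i]
      a <- motif$allowed[[i]]
      f <- motif$forbidden[[i]]
      pool <- if (length(a) > 0) a else setdiff(AMINO_ACIDS, f)
      if (p == 0) pool <- intersect(pool, c("S", "T"))
      m[8 + p, ] <- sample(pool, n, replace = TRUE)
    }
  }
  if (!is.null(center)) m[8, ] <- center
  for (p in names(force)) {
    m[8 + as.integer(p), ] <- force[[p]]
  }
  if (!is.null(avoid_motif_at)) {
    # plant a violation of the given motif at one constrained position
    m[8 + avoid_motif_at$position, ] <- avoid_motif_at$residue
  }
  apply(m, 2, paste, collapse = "")
}

#' Generate a synthetic paired SILAC + TMT screen
#'
#' Builds a complete screen: a wide phosphosite table with SILAC ratio
#' columns (3 experiments, forward/reverse orientations sharing the
#' per-site effect, plus WT/WT controls) and TMT reporter intensities
#' (10 conditions), an ortholog window-pair table, a PPI edge list
#' anchored on ULK1/ULK2, and the planted per-site ground-truth classes.
#' A noiseless control site `Prkab2_S38` carrying the exact reference
#' dynamics is always included (class `true_substrate`), mirroring the
#' role of the known substrate in the real screen.
#'
#' Class construction: `true_substrate` sites get motif-conforming
#' windows, shared truncated-normal log2 depletion in both orientations
#' of all experiments, and the substrate time course; `label_bias` sites
#' look depleted but carry a planted |log2 WT/WT| > 0.7 artifact in one
#' control; `protein_level` sites share a protein (4 sites each), a
#' common depletion offset, non-motif windows and divergent human
#' orthologs; `proline_background` sites have +1 P windows and
#' genotype-independent, starvation-suppressed dynamics (the behaviour
#' of proline-directed mTOR/CDK-type phosphorylation, which falls during
#' starvation and recovers on refeeding in WT and DKO cells alike);
#' `null` sites are centred noise.
#'
#' @param config A [generator_config()].
#' @return List with elements `sites` (wide tibble), `orthologs`,
#'   `ppi` (edge tibble), `truth` (tibble `site_id`, `class`).
#' @export
generate_screen <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_screen_impl(config))
}

generate_screen_impl <- function(cfg) {
  n_per_protein <- 1 + stats::rpois(cfg$n_proteins, cfg$sites_per_protein_lambda)
  gene <- sprintf("Prot%04d", seq_len(cfg$n_proteins))

  # protein-level changers are planted at protein granularity, 4 sites each
  n_sites_planned <- sum(n_per_protein)
  n_pl_proteins <- max(0L, round(cfg$fraction_protein_level * n_sites_planned / 4))
  pl_proteins <- utils::head(seq_len(cfg$n_proteins), n_pl_proteins)
  n_per_protein[pl_proteins] <- 4L

  sites <- tibble::tibble(
    gene = rep(gene, n_per_protein),
    protein = rep(sprintf("ACC%04d", seq_len(cfg$n_proteins)), n_per_protein)
  )
  n <- nrow(sites)
  sites$position <- unlist(lapply(n_per_protein, function(k) {
    sort(sample(10:900, k))
  }))

  cls <- rep("null", n)
  cls[sites$gene %in% gene[pl_proteins]] <- "protein_level"
  free <- which(cls == "null")
  n_true <- cfg$n_true_substrates %||% round(cfg$true_substrate_rate * n)
  n_bias <- round(cfg$fraction_label_bias * n)
  n_pro <- round(cfg$fraction_proline_background * n)
  picks <- sample(free, n_true + n_bias + n_pro)
  cls[picks[seq_len(n_true)]] <- "true_substrate"
  cls[picks[n_true + seq_len(n_bias)]] <- "label_bias"
  cls[picks[n_true + n_bias + seq_len(n_pro)]] <- "proline_background"

  # windows per class
  window <- character(n)
  for (k in unique(cls)) {
    idx <- which(cls == k)
    window[idx] <- switch(k,
      true_substrate = sample_window(length(idx), motif = cfg$motif),
      proline_background = sample_window(length(idx),
        force = list("1" = "P")),
      protein_level = sample_window(length(idx),
        avoid_motif_at = list(position = -2, residue = "P")),
      sample_window(length(idx))
    )
  }
  sites$residue <- substr(window, 8, 8)
  sites$window <- window
  sites$localization_prob <- round(runif(n, 0.76, 1), 4)
  sites$site_id <- make_site_id(sites$gene, sites$residue, sites$position)

  # per-site depletion effect shared by both orientations and experiments
  effect <- numeric(n)
  is_dep <- cls %in% c("true_substrate", "label_bias")
  effect[is_dep] <- rnorm_trunc_upper(
    sum(is_dep), cfg$substrate_effect_mean, cfg$substrate_effect_sd,
    cfg$substrate_effect_cap
  )
  for (g in gene[pl_proteins]) {
    effect[sites$gene == g] <- rnorm_trunc_upper(
      1, -2.2, 0.3, cfg$substrate_effect_cap
    )
  }
  for (e in 1:3) {
    sites[[paste0("ratio_fwd_exp", e)]] <-
      round(effect + rnorm(n, 0, cfg$noise_sd_silac), 4)
    sites[[paste0("ratio_rev_exp", e)]] <-
      round(effect + rnorm(n, 0, cfg$noise_sd_silac), 4)
    sites[[paste0("control_exp", e)]] <-
      round(rnorm(n, 0, 0.3 * cfg$noise_sd_silac), 4)
  }
  # plant the label-bias artifact in one randomly chosen control each
  bias_idx <- which(cls == "label_bias")
  if (length(bias_idx) > 0) {
    which_ctrl <- sample(1:3, length(bias_idx), replace = TRUE)
    magnitude <- round(sample(c(-1, 1), length(bias_idx), replace = TRUE) *
      runif(length(bias_idx), 0.7, 1.2), 4)
    for (e in 1:3) {
      sel <- bias_idx[which_ctrl == e]
      sites[[paste0("control_exp", e)]][sel] <- magnitude[which_ctrl == e]
    }
  }

  # TMT time course on the log10 scale, then exponentiated
  baseline <- rnorm(n, 4.3, 0.4)
  dyn <- cfg$tmt_dynamics
  wt_shape <- c(dyn$starvation_rise, dyn$refeed_level)
  log_prof <- matrix(baseline, nrow = n, ncol = 10)
  colnames(log_prof) <- tmt_conditions()
  tru <- cls == "true_substrate"
  pro <- cls == "proline_background"
  log_prof[tru, 1:5] <- log_prof[tru, 1:5] +
    matrix(wt_shape, sum(tru), 5, byrow = TRUE)
  log_prof[tru, 6:10] <- log_prof[tru, 6:10] - dyn$dko_deficit
  # proline-directed background: mTOR/CDK-driven, suppressed by starvation
  # and restored on refeeding, identically in both genotypes
  log_prof[pro, 1:5] <- log_prof[pro, 1:5] -
    matrix(wt_shape, sum(pro), 5, byrow = TRUE)
  log_prof[pro, 6:10] <- log_prof[pro, 6:10] -
    matrix(wt_shape, sum(pro), 5, byrow = TRUE)
  log_prof <- log_prof + matrix(rnorm(n * 10, 0, cfg$noise_sd_tmt), n, 10)
  intensities <- round(10^log_prof, 3)
  incomplete <- sample(n, round(cfg$fraction_incomplete_tmt * n))
  if (length(incomplete) > 0) {
    drop_cond <- sample(1:10, length(incomplete), replace = TRUE)
    intensities[cbind(incomplete, drop_cond)] <- NA_real_
  }
  colnames(intensities) <- tmt_columns()
  sites <- dplyr::bind_cols(sites, tibble::as_tibble(intensities))

  # append the noiseless Prkab2 S38 reference site
  ref <- reference_profile(cfg)
  ref_row <- tibble::tibble(
    gene = "Prkab2", protein = "PRKAB2", position = 38L, residue = "S",
    window = sample_window(1, motif = cfg$motif, center = "S"),
    localization_prob = 1, site_id = "Prkab2_S38"
  )
  for (e in 1:3) {
    ref_row[[paste0("ratio_fwd_exp", e)]] <- cfg$substrate_effect_mean
    ref_row[[paste0("ratio_rev_exp", e)]] <- cfg$substrate_effect_mean
    ref_row[[paste0("control_exp", e)]] <- 0
  }
  ref_row <- dplyr::bind_cols(
    ref_row,
    tibble::as_tibble(as.list(setNames(ref$intensity, tmt_columns())))
  )
  sites <- dplyr::bind_rows(sites, ref_row)
  cls <- c(cls, "true_substrate")

  truth <- tibble::tibble(site_id = sites$site_id, class = cls)

  # ortholog windows: conserved except for protein-level changers and a
  # sliver of the background
  divergent <- cls == "protein_level" |
    (cls == "null" & runif(length(cls)) < 0.05)
  human_window <- sites$window
  if (any(divergent)) {
    human_window[divergent] <- vapply(
      sites$window[divergent], scramble_window, character(1)
    )
  }
  orthologs <- tibble::tibble(
    site_id = sites$site_id,
    window = sites$window,
    human_window = human_window
  )

  ppi <- build_ppi(sites, cls, cfg$ppi_within2_fraction)

  sites <- dplyr::select(
    sites, site_id, gene, protein, residue, position, window,
    localization_prob, dplyr::everything()
  )
  list(sites = sites, orthologs = orthologs, ppi = ppi, truth = truth)
}

scramble_window <- function(w) {
  ch <- strsplit(w, "")[[1]]
  pos <- setdiff(seq_len(15), 8)
  swap <- sample(pos, 8)
  ch[swap] <- sample(setdiff(AMINO_ACIDS, ch[swap]), length(swap),
                     replace = TRUE)
  paste(ch, collapse = "")
}

build_ppi <- function(sites, cls, within2_fraction) {
  adaptors <- sprintf("ADAPT%02d", 1:8)
  edges <- tibble::tibble(
    from = c(rep("ULK1", 4), rep("ULK2", 4)),
    to = adaptors
  )
  far <- sprintf("FARNODE%02d", 1:5)
  chain <- tibble::tibble(
    from = c(adaptors[1], far[-length(far)]),
    to = far
  )
  sub_genes <- unique(toupper(sites$gene[cls == "true_substrate"]))
  near <- runif(length(sub_genes)) < within2_fraction
  sub_edges <- tibble::tibble(
    from = ifelse(near,
      sample(c("ULK1", "ULK2", adaptors), length(sub_genes), replace = TRUE),
      sample(far[-1], length(sub_genes), replace = TRUE)
    ),
    to = sub_genes
  )
  bg_genes <- unique(toupper(sites$gene[cls == "null"]))
  bg_genes <- utils::head(bg_genes, 30)
  bg_edges <- tibble::tibble(
    from = sample(far[-1], length(bg_genes), replace = TRUE),
    to = bg_genes
  )
  dplyr::bind_rows(edges, chain, sub_edges, bg_edges)
}

#' The planted reference (Prkab2-S38-like) time-course profile
#'
#' The exact, noise-free substrate dynamic the generator plants: WT
#' phosphorylation rises monotonically from 0 to 60 min of starvation,
#' drops back towards baseline on refeeding, and the DKO segment is flat
#' at a lower baseline.
#'
#' @param config A [generator_config()].
#' @return Tibble with columns `condition` (in canonical order) and
#'   `intensity`.
#' @export
reference_profile <- function(config = generator_config()) {
  dyn <- config$tmt_dynamics
  b <- 4.3
  log10_values <- c(
    b + c(dyn$starvation_rise, dyn$refeed_level),
    rep(b - dyn$dko_deficit, 5)
  )
  tibble::tibble(
    condition = tmt_conditions(),
    intensity = round(10^log10_values, 3)
  )
}
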
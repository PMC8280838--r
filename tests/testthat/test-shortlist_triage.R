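make_calls <- function(ids, depleted) {
  tibble::tibble(site_id = ids, gene = sub("_.*", "", ids),
                 combined_depleted = depleted)
}
make_tiers <- function(ids, tier) {
  tibble::tibble(site_id = ids, tier = tier)
}

test_that("cross-referencing applies the shortlist rule with manual
           curation", {
  calls <- make_calls(c("A_S1", "B_S2", "C_S3", "D_S4"),
                      c(TRUE, TRUE, FALSE, TRUE))
  tiers <- make_tiers(c("A_S1", "C_S3", "D_S4"),
                      c("primary", "primary", "none"))
  curation <- list(
    include = tibble::tibble(site_id = "B_S2",
                             reason = "SILAC-only, biological interest"),
    exclude = NULL
  )
  entries <- crossref(calls, tiers, curation = curation)
  get <- function(id) entries$shortlisted[entries$site_id == id]
  expect_true(get("A_S1"))   # depleted + primary tier
  expect_true(get("B_S2"))   # absent from TMT, manually included
  expect_false(get("C_S3"))  # tier without depletion
  expect_false(get("D_S4"))  # depleted but tier none
  expect_match(entries$rule[entries$site_id == "B_S2"], "manual_include")

  # manual exclusion dominates and carries its reason
  curation$exclude <- tibble::tibble(site_id = "A_S1",
                                     reason = "clear false positive")
  entries2 <- crossref(calls, tiers, curation = curation)
  expect_false(entries2$shortlisted[entries2$site_id == "A_S1"])
  expect_match(entries2$rule[entries2$site_id == "A_S1"],
               "clear false positive")

  expect_error(
    crossref(make_calls(c("A_S1", "A_S1"), c(TRUE, TRUE)), tiers),
    "duplicate"
  )
})

test_that("inner-mode cross-referencing is symmetric in table order", {
  calls <- make_calls(c("A_S1", "B_S2", "C_S3"), c(TRUE, FALSE, TRUE))
  tiers <- make_tiers(c("B_S2", "C_S3", "D_S4"),
                      c("primary", "similarity_only", "primary"))
  inner <- crossref(calls, tiers, mode = "inner")
  expect_setequal(inner$site_id, c("B_S2", "C_S3"))
  expect_equal(inner$shortlisted[inner$site_id == "C_S3"], TRUE)
  # swapping the join direction yields the same key set
  flipped <- dplyr::inner_join(tiers, calls, by = "site_id")
  expect_setequal(inner$site_id, flipped$site_id)
})

test_that("conservation identity and filter follow the window rules", {
  w <- "NVNEEWKSMFGSLDC"
  expect_equal(conservation_identity(w, w), 1)
  res <- conservation_filter(w, w)
  expect_true(res$keep)

  # human centre not S/T drops the site regardless of identity
  human <- w
  substr(human, 8, 8) <- "A"
  expect_false(conservation_filter(w, human)$keep)

  # 6/15 mismatches -> identity 0.6
  div <- w
  substr(div, 1, 6) <- "GGGGGG"  # positions 1-6 differ from NVNEEW
  expect_equal(conservation_identity(w, div), 9 / 15)
  expect_true(conservation_filter(w, div, min_identity = 0.6)$keep)
  expect_false(conservation_filter(w, div, min_identity = 0.61)$keep)

  # symmetry, and pad positions excluded from both sides of the ratio
  expect_equal(conservation_identity(w, div), conservation_identity(div, w))
  padded_a <- "____AWKSMFGSLDC"
  padded_b <- "____CWKSMFGSLDC"
  expect_equal(conservation_identity(padded_a, padded_b), 10 / 11)

  expect_error(conservation_identity(w, "SHORT"), "15")
})

test_that("PPI distances are breadth-first and match a brute-force oracle", {
  edges <- tibble::tibble(
    from = c("ULK1", "ATG13", "FIP200", "X1", "X2"),
    to = c("ATG13", "FIP200", "X1", "X2", "X3")
  )
  d <- ppi_distance(edges, c("ATG13", "FIP200", "X1", "X2", "ABSENT"))
  expect_equal(unname(d), c(1, 2, 3, 4, Inf))

  withr::with_seed(41, {
    nodes <- c("ULK1", "ULK2", sprintf("N%02d", 1:30))
    rnd <- tibble::tibble(
      from = sample(nodes, 60, replace = TRUE),
      to = sample(nodes, 60, replace = TRUE)
    )
    rnd <- rnd[rnd$from != rnd$to, ]
  })
  targets <- setdiff(nodes, c("ULK1", "ULK2"))
  got <- ppi_distance(rnd, targets)
  oracle <- vapply(targets, function(t) {
    bfs_distance_oracle(rnd, t, c("ULK1", "ULK2"))
  }, numeric(1))
  expect_equal(unname(got), unname(oracle))

  # anchors absent from the graph make every distance infinite
  no_anchor <- tibble::tibble(from = "A", to = "B")
  expect_equal(unname(ppi_distance(no_anchor, c("A", "B"))), c(Inf, Inf))
})

test_that("peptide-variant design emits WT, mutants and murine forms", {
  # centre S, no other S/T: total phosphomutant would duplicate single_SA
  w_simple <- "AAAAAAASAAAAAAA"
  v <- design_peptide_variants(w_simple)
  expect_equal(v$label, c("WT", "single_SA"))
  expect_equal(v$sequence[2], "AAAAAAAAAAAAAAA")

  # centre S plus two threonines and a divergent murine window: 4 variants
  w_rich <- "TAAAAAASAATAAAA"
  murine <- "TAAAAAASAATAAAC"
  v <- design_peptide_variants(w_rich, murine)
  expect_equal(v$label, c("WT", "single_SA", "total_STA", "murine"))
  expect_equal(v$sequence[v$label == "single_SA"], "TAAAAAAAAATAAAA")
  expect_false(grepl("[ST]", v$sequence[v$label == "total_STA"]))
  expect_equal(v$sequence[v$label == "murine"], murine)

  # an identical murine window is redundant
  v <- design_peptide_variants(w_rich, w_rich)
  expect_equal(v$label, c("WT", "single_SA", "total_STA"))

  # total phosphomutants never retain any S/T, on random windows
  withr::with_seed(42, windows <- random_windows(50))
  substr(windows, 8, 8) <- "S"
  for (w in windows) {
    v <- design_peptide_variants(w)
    if ("total_STA" %in% v$label) {
      expect_false(grepl("[ST]", v$sequence[v$label == "total_STA"]))
    }
  }

  expect_error(design_peptide_variants("AAAAAAAYAAAAAAA"), "phosphoacceptor")
})

test_that("shortlist emission is deterministic and auditable", {
  calls <- make_calls(c("E_S5", "A_S1", "C_S3"), c(TRUE, TRUE, FALSE))
  tiers <- make_tiers(c("A_S1", "C_S3", "E_S5"),
                      c("primary", "none", "similarity_only"))
  entries <- crossref(calls, tiers)
  expect_true(all(nchar(entries$rule) > 0))

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  emit_shortlist(entries, p1)
  emit_shortlist(entries[sample(nrow(entries)), ], p2)
  expect_identical(readLines(p1), readLines(p2))

  p3 <- withr::local_tempfile(fileext = ".tsv")
  emit_shortlist(entries[0, ], p3)
  expect_length(readLines(p3), 1)
})

test_that("shortlist membership is monotone in conservation and tier set", {
  withr::with_seed(43, {
    ids <- sprintf("G%02d_S%d", 1:40, 1:40)
    calls <- make_calls(ids, sample(c(TRUE, FALSE), 40, replace = TRUE))
    tiers <- make_tiers(ids, sample(c("primary", "similarity_only", "none"),
                                    40, replace = TRUE))
  })
  strict <- crossref(calls, tiers, accepted_tiers = "primary")
  loose <- crossref(calls, tiers)
  expect_true(all(strict$site_id[strict$shortlisted] %in%
                    loose$site_id[loose$shortlisted]))
})
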
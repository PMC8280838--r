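# Shared fixture builders; everything is generated in code at test time.

# A minimal hand-written site table with quantitative columns.
toy_sites <- function() {
  tibble::tibble(
    site_id = c("Atg13_S355", "Prkab2_S38", "Sorbs2_S100"),
    gene = c("Atg13", "Prkab2", "Sorbs2"),
    protein = c("ATG13", "PRKAB2", "SORBS2"),
    residue = c("S", "S", "S"),
    position = c(355L, 38L, 100L),
    window = c("AAAALAASYYAAAAA", "AAAAQAASIMAAAAA", "PPPPPPPSPPPPPPP"),
    localization_prob = c(0.99, 0.95, 0.80),
    ratio_fwd_exp1 = c(-2.0, -2.5, -0.1),
    ratio_rev_exp1 = c(-1.8, -2.2, 0.2),
    ratio_fwd_exp2 = c(-1.9, -2.4, 0.0),
    ratio_rev_exp2 = c(-2.1, -2.6, -0.3),
    ratio_fwd_exp3 = c(-0.4, -2.0, 0.1),
    ratio_rev_exp3 = c(-0.2, -1.9, 0.0),
    control_exp1 = c(0.1, 0.0, 0.9),
    control_exp2 = c(-0.2, 0.1, 0.0),
    control_exp3 = c(0.0, -0.1, 0.1)
  )
}

# Random 15-mer windows over the amino-acid alphabet.
random_windows <- function(n, alphabet = phosphotriage::AMINO_ACIDS) {
  vapply(
    seq_len(n),
    function(i) paste(sample(alphabet, 15, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Independent regular-expression oracle for the full ULK1 consensus:
# applies the per-position character classes to the central 6-mer
# (window positions -3..+2). Forbidden-only positions use a negated
# class, so the pad character passes there and nowhere else.
ulk1_regex_oracle <- function(windows) {
  grepl("^[MLQF][^P][^P][ST][YIMSFVW][YSHIWM]$", substr(windows, 5, 10))
}

# Breadth-first shortest-path oracle on a small edge list.
bfs_distance_oracle <- function(edges, target, anchors) {
  nodes <- unique(c(edges$from, edges$to, anchors))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  if (!target %in% nodes) return(Inf)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  frontier <- intersect(anchors, nodes)
  dist[frontier] <- 0
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  unname(dist[target])
}

# A TMT matrix of n random positive profiles.
random_tmt_profiles <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(10^rnorm(n * 10, 4, 0.5), nrow = n,
                dimnames = list(sprintf("site%04d", seq_len(n)),
                                tmt_conditions()))
    m
  })
}
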
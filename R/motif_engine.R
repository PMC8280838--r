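#' Parse a kinase consensus-motif notation
#'
#' The grammar mirrors the conventional rendering of positional-scanning
#' motifs: positions are separated by `-`; at each position conforming
#' residues appear in square brackets (`[M/L/Q/F]`), non-conforming
#' residues in braces (`{P}`), and the two group types may be juxtaposed
#' at one position (`[Y/I/M/S/F/V/W]{P}`, read as a conjunction: must be
#' one of the allowed residues and must not be forbidden). A bare `.`
#' denotes an unconstrained position. Unicode hyphen/minus characters
#' are accepted as separators.
#'
#' The phosphoacceptor position (position 0) is located automatically as
#' the unique position whose allowed set is non-empty and contained in
#' \{S, T\}; pass `anchor` (1-based position index in the notation) when
#' that rule is ambiguous. A motif with no position-0 group is an error.
#'
#' The ULK1 consensus motif, spanning positions −3 to +2, is available
#' pre-parsed as [ulk1_motif()].
#'
#' @param notation Motif string.
#' @param anchor Optional 1-based index of the phosphoacceptor position.
#' @return A `kinase_motif`: list with integer `positions` and parallel
#'   lists `allowed` and `forbidden` of residue character vectors.
#' @export
parse_motif <- function(notation, anchor = NULL) {
  txt <- gsub("[‐‒–−‑]", "-", notation)
  txt <- gsub("\\s", "", txt)
  if (nchar(txt) == 0) abort("empty motif notation")
  tokens <- strsplit(txt, "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0 || any(tokens == "")) {
    abort("malformed motif notation: empty position between separators")
  }
  parse_group_set <- function(token) {
    if (token == ".") {
      return(list(allowed = character(0), forbidden = character(0)))
    }
    groups <- regmatches(token, gregexpr(
      "\\[([A-Za-z/]*)\\]|\\{([A-Za-z/]*)\\}", token
    ))[[1]]
    if (length(groups) == 0 || sum(nchar(groups)) != nchar(token)) {
      abort(paste0("malformed motif position token: '", token, "'"))
    }
    allowed <- character(0)
    forbidden <- character(0)
    for (g in groups) {
      body <- substr(g, 2, nchar(g) - 1)
      res <- toupper(strsplit(body, "/", fixed = TRUE)[[1]])
      res <- res[res != ""]
      bad <- setdiff(res, AMINO_ACIDS)
      if (length(bad) > 0) {
        abort(paste0("unknown residue letter(s) in motif: ",
                     paste(bad, collapse = ", ")))
      }
      if (startsWith(g, "[")) allowed <- union(allowed, res)
      else forbidden <- union(forbidden, res)
    }
    if (length(intersect(allowed, forbidden)) > 0) {
      abort("motif position with residue both allowed and forbidden")
    }
    list(allowed = allowed, forbidden = forbidden)
  }
  parsed <- lapply(tokens, parse_group_set)
  allowed <- lapply(parsed, `[[`, "allowed")
  forbidden <- lapply(parsed, `[[`, "forbidden")

  if (is.null(anchor)) {
    candidates <- which(vapply(
      allowed,
      function(a) length(a) > 0 && all(a %in% c("S", "T")),
      logical(1)
    ))
    if (length(candidates) == 0) {
      abort("motif has no phosphoacceptor (position-0) group [S], [T] or [S/T]")
    }
    if (length(candidates) > 1) {
      abort("ambiguous phosphoacceptor position; supply `anchor`")
    }
    anchor <- candidates
  }
  anchor <- as.integer(anchor)
  if (anchor < 1 || anchor > length(tokens)) abort("anchor out of range")
  positions <- seq_along(tokens) - anchor
  if (anyNA(match(0, positions))) abort("anchor does not map to position 0")
  if (max(abs(positions)) > 7) abort("motif positions must lie within -7..+7")

  structure(
    list(positions = positions, allowed = allowed, forbidden = forbidden),
    class = "kinase_motif"
  )
}

#' Serialize a motif back to its notation
#'
#' Inverse of [parse_motif()] up to residue ordering inside groups
#' (residues are emitted in the parsed order).
#'
#' @param motif A `kinase_motif`.
#' @return Motif notation string.
#' @export
format_motif <- function(motif) {
  stopifnot(inherits(motif, "kinase_motif"))
  tok <- vapply(seq_along(motif$positions), function(i) {
    a <- motif$allowed[[i]]
    f <- motif$forbidden[[i]]
    s <- ""
    if (length(a) > 0) s <- paste0(s, "[", paste(a, collapse = "/"), "]")
    if (length(f) > 0) s <- paste0(s, "{", paste(f, collapse = "/"), "}")
    if (s == "") s <- "."
    s
  }, character(1))
  paste(tok, collapse = "-")
}

#' @export
print.kinase_motif <- function(x, ...) {
  cat("<kinase_motif> ", format_motif(x), "\n", sep = "")
  cat("  positions: ", paste(x$positions, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' The ULK1 consensus motif
#'
#' The ULK1 substrate consensus derived from positional-scanning peptide
#' library data, spanning positions −3 to +2 around the phosphoacceptor:
#' `[M/L/Q/F]-{P}-{P}-[S/T]-[Y/I/M/S/F/V/W]{P}-[Y/S/H/I/W/M]{P}`.
#' `ulk1_motif_simplified()` is the coarser rendering requiring
#' hydrophobic residues at −3, +1 and +2 (Φ = A/V/L/I/M/F/W/Y).
#'
#' @return A `kinase_motif`.
#' @export
ulk1_motif <- function() {
  parse_motif("[M/L/Q/F]-{P}-{P}-[S/T]-[Y/I/M/S/F/V/W]{P}-[Y/S/H/I/W/M]{P}")
}

#' @rdname ulk1_motif
#' @export
ulk1_motif_simplified <- function() {
  phi <- "[A/V/L/I/M/F/W/Y]"
  parse_motif(paste0(phi, "-.-.-[S/T]-", phi, "-", phi))
}

#' Match a motif against 15-mer sequence windows
#'
#' A window matches when, at every motif position, the residue is in the
#' allowed set (or the allowed set is empty) and not in the forbidden
#' set. The terminal pad character `_` never satisfies a non-empty
#' allowed set but does pass a forbidden-only position. Window index 8
#' is the phosphoacceptor (motif position 0).
#'
#' @param motif A `kinase_motif`.
#' @param windows Character vector of 15-character windows.
#' @return Logical vector.
#' @export
motif_match <- function(motif, windows) {
  per_pos <- motif_match_positions(motif, windows)
  if (is.null(dim(per_pos))) all(per_pos) else apply(per_pos, 1, all)
}

#' @rdname motif_match
#' @param simplify Return a vector when a single window is given.
#' @return For `motif_match_positions`: a logical matrix (windows x
#'   motif positions, columns named by signed position) of per-position
#'   pass/fail, or a named vector for a single window.
#' @export
motif_match_positions <- function(motif, windows, simplify = TRUE) {
  stopifnot(inherits(motif, "kinase_motif"))
  if (any(nchar(windows) != 15)) {
    abort("all windows must be exactly 15 characters")
  }
  out <- matrix(
    NA, nrow = length(windows), ncol = length(motif$positions),
    dimnames = list(NULL, as.character(motif$positions))
  )
  for (i in seq_along(motif$positions)) {
    idx <- 8 + motif$positions[i]
    ch <- substr(windows, idx, idx)
    a <- motif$allowed[[i]]
    f <- motif$forbidden[[i]]
    out[, i] <- if (length(a) > 0) ch %in% a else !(ch %in% f)
  }
  if (simplify && length(windows) == 1) out[1, ] else out
}

#' Expected motif-match rate under a uniform residue background
#'
#' Analytic probability that a random window matches the motif, with
#' every position drawn uniformly from the 20 amino acids
#' (`center_st = FALSE`) or with the centre residue drawn uniformly
#' from \{S, T\} as in a phosphosite table (`center_st = TRUE`).
#'
#' @param motif A `kinase_motif`.
#' @param center_st Condition on the centre being S or T.
#' @return Probability in \[0, 1\].
#' @export
analytic_match_probability <- function(motif, center_st = FALSE) {
  p <- 1
  for (i in seq_along(motif$positions)) {
    a <- motif$allowed[[i]]
    f <- motif$forbidden[[i]]
    if (motif$positions[i] == 0 && center_st) {
      p <- p * (if (length(a) > 0) length(intersect(a, c("S", "T"))) / 2
                else (2 - length(intersect(f, c("S", "T")))) / 2)
    } else {
      p <- p * (if (length(a) > 0) length(a) / 20
                else (20 - length(f)) / 20)
    }
  }
  p
}

#' Positional amino-acid enrichment matrix (consensus logo)
#'
#' log2 relative enrichment of each amino acid at each window position
#' −7..+7 (centre excluded) in a foreground site set versus a background
#' set: `value(a, p) = log2((f_fg(a,p) + eps) / (f_bg(a,p) + eps))`,
#' where the `f` are per-column residue frequencies with pad characters
#' excluded from the counts. The default background in a screen is the
#' full set of detected sites. Swapping foreground and background flips
#' the sign of every cell.
#'
#' @param foreground,background Character vectors of 15-mer windows.
#' @param pseudocount Frequency pseudocount `eps` (> 0) keeping values
#'   finite.
#' @return 20 x 14 numeric matrix (rows amino acids, columns signed
#'   positions), class `enrichment_matrix`.
#' @export
enrichment_matrix <- function(foreground, background, pseudocount = 0.01) {
  if (length(foreground) == 0) abort("empty foreground window set")
  if (length(background) == 0) abort("empty background window set")
  if (pseudocount <= 0) abort("pseudocount must be positive")
  positions <- setdiff(-7:7, 0)
  freq <- function(windows) {
    m <- matrix(0, nrow = 20, ncol = length(positions),
                dimnames = list(AMINO_ACIDS, as.character(positions)))
    for (j in seq_along(positions)) {
      idx <- 8 + positions[j]
      ch <- substr(windows, idx, idx)
      ch <- ch[ch %in% AMINO_ACIDS]  # pads excluded per column
      if (length(ch) > 0) {
        tab <- table(factor(ch, levels = AMINO_ACIDS))
        m[, j] <- as.numeric(tab) / length(ch)
      }
    }
    m
  }
  out <- log2((freq(foreground) + pseudocount) /
              (freq(background) + pseudocount))
  class(out) <- c("enrichment_matrix", class(out))
  out
}

#' Partition sites by proline at position +1
#'
#' Proline-directed kinases (CDKs, MAPKs, mTOR-adjacent kinases)
#' dominate many depleted-site sets; separating windows with and without
#' +1 proline reveals their contribution to a consensus logo.
#'
#' @param x Character vector of 15-mer windows, or a tibble with a
#'   `window` column.
#' @return Named list `with_p1_proline`, `without_p1_proline`
#'   partitioning the input.
#' @export
split_by_plus1_proline <- function(x) {
  windows <- if (is.data.frame(x)) x$window else x
  if (any(nchar(windows) != 15)) {
    abort("all windows must be exactly 15 characters")
  }
  has_p <- substr(windows, 9, 9) == "P"
  if (is.data.frame(x)) {
    list(with_p1_proline = x[has_p, , drop = FALSE],
         without_p1_proline = x[!has_p, , drop = FALSE])
  } else {
    list(with_p1_proline = windows[has_p],
         without_p1_proline = windows[!has_p])
  }
}
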
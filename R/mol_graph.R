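# Molecular graphs from SMILES.
#
# SMILES parsing, canonicalisation and hydrogen addition are delegated to
# Open Babel (through ChemmineOB); this file turns the resulting V2000
# molfile blocks into light heavy-atom graphs used by the fingerprint and
# property code. Open Babel stops emitting output at the first invalid
# SMILES in a batch, so conversion is retried past each failure and the
# offending inputs are reported as drops.

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53, Se = 34, As = 33, Li = 3, Na = 11, K = 19,
  Mg = 12, Ca = 20, Fe = 26, Zn = 30
)

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904,
  I = 126.904, Se = 78.971, As = 74.922, Li = 6.94, Na = 22.99,
  K = 39.098, Mg = 24.305, Ca = 40.078, Fe = 55.845, Zn = 65.38
)

ob_convert <- function(from, to, source, add_h = FALSE) {
  suppressWarnings(if (add_h)
    ChemmineOB::convertFormat(from, to, source = source,
                              options = data.frame(names = "h", args = ""))
  else ChemmineOB::convertFormat(from, to, source = source))
}

# Parse one V2000 molfile block (as emitted by Open Babel with explicit
# hydrogens) into a heavy-atom graph.
parse_v2000 <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) return(NULL)
  atom_lines <- lines[4L + seq_len(natoms)]
  elem <- vapply(atom_lines, function(l) trimws(substr(l, 32L, 34L)), "",
                 USE.NAMES = FALSE)
  charge <- integer(natoms)
  if (nbonds > 0L) {
    bond_lines <- lines[4L + natoms + seq_len(nbonds)]
    ba <- as.integer(substr(bond_lines, 1L, 3L))
    bb <- as.integer(substr(bond_lines, 4L, 6L))
    bo <- as.integer(substr(bond_lines, 7L, 9L))
  } else {
    ba <- bb <- bo <- integer(0)
  }
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
    npair <- toks[1L]
    for (k in seq_len(npair)) charge[toks[2L * k]] <- toks[2L * k + 1L]
  }

  heavy <- which(elem != "H")
  idx <- integer(natoms)
  idx[heavy] <- seq_along(heavy)
  n <- length(heavy)
  n_h <- integer(n)
  keep <- logical(length(ba))
  for (k in seq_along(ba)) {
    a <- ba[k]; b <- bb[k]
    ah <- elem[a] == "H"; bh <- elem[b] == "H"
    if (ah && !bh) n_h[idx[b]] <- n_h[idx[b]] + 1L
    else if (bh && !ah) n_h[idx[a]] <- n_h[idx[a]] + 1L
    else if (!ah && !bh) keep[k] <- TRUE
  }
  bonds <- data.frame(a = idx[ba[keep]], b = idx[bb[keep]],
                      order = bo[keep])

  ring_bond <- logical(nrow(bonds))
  n_comp <- if (n > 0L) 1L else 0L
  if (n > 0L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(bonds) > 0L)
      g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
    n_comp <- igraph::count_components(g)
    if (nrow(bonds) > 0L) {
      br <- as.integer(igraph::bridges(g))
      ring_bond <- !(seq_len(nrow(bonds)) %in% br)
    }
  }
  ring_atom <- logical(n)
  if (any(ring_bond))
    ring_atom[unique(c(bonds$a[ring_bond], bonds$b[ring_bond]))] <- TRUE

  degree <- integer(n)
  if (nrow(bonds) > 0L) {
    tb <- table(factor(c(bonds$a, bonds$b), levels = seq_len(n)))
    degree <- as.integer(tb)
  }

  list(
    elem = elem[heavy],
    charge = charge[heavy],
    n_h = n_h,
    degree = degree,
    bonds = bonds,
    ring_bond = ring_bond,
    ring_atom = ring_atom,
    n_heavy = n,
    n_atoms_total = natoms,
    n_rings = nrow(bonds) - n + n_comp
  )
}

split_sdf_blocks <- function(text) {
  blocks <- strsplit(text, "$$$$\n", fixed = TRUE)[[1]]
  blocks[nzchar(trimws(blocks))]
}

#' Build heavy-atom molecular graphs from SMILES
#'
#' Converts SMILES strings to explicit-hydrogen structures with Open Babel
#' and derives, for each molecule, a heavy-atom graph: elements, formal
#' charges, attached hydrogen counts, bond list with orders, ring
#' membership and a smallest-set-of-rings count. Unparseable SMILES are
#' dropped and reported rather than raising an error.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound identifiers (defaults to names or positions).
#' @return A list with elements \code{graphs} (named list of molecular
#'   graphs, \code{NULL} for dropped inputs omitted) and \code{dropped}
#'   (character vector of ids that failed to parse).
#' @export
smiles_to_graphs <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  graphs <- vector("list", length(smiles))
  names(graphs) <- ids
  parsed <- logical(length(smiles))
  remaining <- seq_along(smiles)
  dropped <- integer(0)
  while (length(remaining) > 0L) {
    src <- paste(paste(smiles[remaining], remaining), collapse = "\n")
    out <- ob_convert("SMI", "SDF", src, add_h = TRUE)
    blocks <- split_sdf_blocks(out)
    got <- integer(0)
    for (bl in blocks) {
      title <- suppressWarnings(
        as.integer(trimws(strsplit(bl, "\n", fixed = TRUE)[[1]][1L])))
      if (is.na(title) || !(title %in% remaining)) next
      gr <- parse_v2000(bl)
      if (!is.null(gr)) {
        graphs[[title]] <- gr
        parsed[title] <- TRUE
        got <- c(got, title)
      }
    }
    miss <- setdiff(remaining, got)
    if (length(miss) == 0L) break
    if (length(got) == 0L) { dropped <- c(dropped, miss); break }
    first_bad <- min(miss)
    dropped <- c(dropped, first_bad)
    remaining <- setdiff(miss, first_bad)
  }
  list(graphs = graphs[parsed], dropped = ids[sort(dropped)])
}

#' Canonicalise SMILES strings
#'
#' Returns the Open Babel canonical SMILES for each input, so that
#' alternative spellings of the same molecule map to one representative
#' string. Unparseable inputs come back as \code{NA}.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, \code{NA} where parsing
#'   failed.
#' @export
canonical_smiles <- function(smiles) {
  res <- rep(NA_character_, length(smiles))
  remaining <- seq_along(smiles)
  while (length(remaining) > 0L) {
    src <- paste(paste(smiles[remaining], remaining), collapse = "\n")
    out <- ob_convert("SMI", "CAN", src)
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    got <- integer(0)
    for (l in lines) {
      toks <- strsplit(trimws(l), "\t|\\s+")[[1]]
      if (length(toks) < 2L) next
      pos <- suppressWarnings(as.integer(toks[length(toks)]))
      if (is.na(pos) || !(pos %in% remaining)) next
      res[pos] <- toks[1L]
      got <- c(got, pos)
    }
    miss <- setdiff(remaining, got)
    if (length(miss) == 0L) break
    if (length(got) == 0L) break
    remaining <- setdiff(miss, min(miss))
  }
  res
}
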
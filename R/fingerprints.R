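# Hashed binary molecular fingerprints.
#
# Two generators are built in: circular (Morgan-style) fingerprints
# parameterised by radius, and path-based (layered-style) fingerprints
# parameterised by minimum/maximum path length, both folded to a fixed
# bit width. Precomputed 881-bit PubChem fingerprint tables are ingested
# rather than regenerated (the bit definitions are tool-specific).
# Inputs are canonicalised before graph construction so every spelling
# of a molecule yields an identical bit vector.

HASH_MOD <- 2147483629  # large prime < 2^31; arithmetic stays exact in doubles

hash_mix <- function(h, x) (h * 31 + x) %% HASH_MOD

hash_seq <- function(xs) {
  h <- 7
  for (x in xs) h <- hash_mix(h, x)
  h
}

#' Fingerprint specification
#'
#' Describes how a binary molecular fingerprint is generated: the hashing
#' scheme (\code{"morgan"} circular environments, \code{"layered"}
#' bond paths, or \code{"pubchem881-external"} for precomputed 881-bit
#' PubChem tables), and its parameters.
#'
#' @param kind one of \code{"morgan"}, \code{"layered"},
#'   \code{"pubchem881-external"}.
#' @param radius circular-environment radius (Morgan; default 2).
#' @param nbits folded bit width (default 2048; fixed to 881 for
#'   external PubChem tables).
#' @param min_path,max_path bond-path length bounds (layered; defaults
#'   1 and 9).
#' @return An object of class \code{fingerprint_spec}.
#' @export
fingerprint_spec <- function(kind = c("morgan", "layered", "pubchem881-external"),
                             radius = 2L, nbits = 2048L,
                             min_path = 1L, max_path = 9L) {
  kind <- match.arg(kind)
  if (kind == "pubchem881-external") nbits <- 881L
  stopifnot(nbits > 0L, radius >= 0L, min_path >= 1L,
            min_path <= max_path)
  structure(list(kind = kind, radius = as.integer(radius),
                 nbits = as.integer(nbits),
                 min_path = as.integer(min_path),
                 max_path = as.integer(max_path)),
            class = "fingerprint_spec")
}

#' @export
print.fingerprint_spec <- function(x, ...) {
  cat("Fingerprint spec:", x$kind, "\n")
  if (x$kind == "morgan")
    cat("  radius", x$radius, ", ", x$nbits, "bits\n")
  else if (x$kind == "layered")
    cat("  paths", x$min_path, "-", x$max_path, ", ", x$nbits, "bits\n")
  else cat("  width 881 (external table)\n")
  invisible(x)
}

# Circular fingerprint bit positions for one molecular graph.
morgan_bits <- function(gr, radius, nbits) {
  n <- gr$n_heavy
  z <- unname(ATOMIC_NUMBER[gr$elem])
  z[is.na(z)] <- 0
  h <- vapply(seq_len(n), function(i)
    hash_seq(c(z[i], gr$degree[i], gr$n_h[i], gr$charge[i],
               as.integer(gr$ring_atom[i]))), 0)
  nbr <- vector("list", n)
  if (nrow(gr$bonds) > 0L) {
    for (k in seq_len(nrow(gr$bonds))) {
      a <- gr$bonds$a[k]; b <- gr$bonds$b[k]; o <- gr$bonds$order[k]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  all_h <- h
  for (r in seq_len(radius)) {
    h_new <- h
    for (i in seq_len(n)) {
      nb <- nbr[[i]]
      if (is.null(nb)) { h_new[i] <- hash_mix(h[i], r); next }
      pair <- h[nb[, 1L]] * 8 + nb[, 2L]
      h_new[i] <- hash_seq(c(r, h[i], sort(pair)))
    }
    h <- h_new
    all_h <- c(all_h, h)
  }
  unique(all_h %% nbits) + 1L
}

# Path-based fingerprint bit positions (simple paths of min..max bonds).
layered_bits <- function(gr, min_path, max_path, nbits) {
  n <- gr$n_heavy
  z <- unname(ATOMIC_NUMBER[gr$elem])
  z[is.na(z)] <- 0
  if (nrow(gr$bonds) == 0L) {
    if (min_path > 1L) return(integer(0))
    return(unique(vapply(z, function(x) hash_seq(c(x)), 0) %% nbits) + 1L)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(gr$bonds$a, gr$bonds$b))
  om <- matrix(0L, n, n)
  for (k in seq_len(nrow(gr$bonds))) {
    om[gr$bonds$a[k], gr$bonds$b[k]] <- gr$bonds$order[k]
    om[gr$bonds$b[k], gr$bonds$a[k]] <- gr$bonds$order[k]
  }
  all_paths <- list()
  for (v in seq_len(n)) {
    paths <- igraph::all_simple_paths(g, from = v, cutoff = max_path)
    for (p in paths) {
      vs <- as.integer(p)
      if (length(vs) - 1L >= min_path) all_paths[[length(all_paths) + 1L]] <- vs
    }
  }
  if (length(all_paths) == 0L) return(integer(0))
  # each undirected path is enumerated once per direction; keep one
  keys <- vapply(all_paths, function(vs) {
    kf <- paste(vs, collapse = ",")
    kr <- paste(rev(vs), collapse = ",")
    if (kf <= kr) kf else kr
  }, "")
  all_paths <- all_paths[!duplicated(keys)]
  hashes <- vapply(all_paths, function(vs) {
    nb <- length(vs) - 1L
    lab_f <- numeric(2L * length(vs) - 1L)
    lab_f[seq(1L, by = 2L, length.out = length(vs))] <- z[vs]
    lab_f[seq(2L, by = 2L, length.out = nb)] <-
      om[cbind(vs[-length(vs)], vs[-1L])]
    lab_r <- rev(lab_f)
    lab <- if (paste(lab_f, collapse = ",") <=
               paste(lab_r, collapse = ",")) lab_f else lab_r
    hash_seq(c(nb, lab))
  }, 0)
  unique(hashes %% nbits) + 1L
}

#' Generate binary fingerprints for a set of molecules
#'
#' Computes hashed binary fingerprints (per \code{\link{fingerprint_spec}})
#' for each SMILES and returns a compounds-by-bits 0/1 matrix. SMILES are
#' canonicalised first, so the output is invariant to the spelling of the
#' input. Unparseable molecules are dropped with a warning; their ids are
#' recorded in the \code{"dropped"} attribute.
#'
#' @param smiles character vector of SMILES, or a data.frame with
#'   \code{id} and \code{smiles} columns.
#' @param spec a \code{\link{fingerprint_spec}} (external PubChem tables
#'   cannot be generated; see \code{\link{read_padel_fingerprints}}).
#' @param ids row identifiers.
#' @return Integer 0/1 matrix with compound ids as rownames and bit names
#'   \code{FP1..FPn} as colnames; attribute \code{"dropped"} lists ids
#'   that failed to parse.
#' @export
featurize <- function(smiles, spec = fingerprint_spec("morgan"), ids = NULL) {
  if (is.data.frame(smiles)) {
    ids <- as.character(smiles$id)
    smiles <- as.character(smiles$smiles)
  }
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  if (spec$kind == "pubchem881-external")
    stop("external 881-bit PubChem fingerprints cannot be generated; ",
         "load them with read_padel_fingerprints()")
  can <- canonical_smiles(smiles)
  ok <- !is.na(can)
  gg <- smiles_to_graphs(can[ok], ids[ok])
  kept <- names(gg$graphs)
  mat <- matrix(0L, length(kept), spec$nbits,
                dimnames = list(kept, paste0("FP", seq_len(spec$nbits))))
  for (i in seq_along(kept)) {
    gr <- gg$graphs[[i]]
    bits <- if (spec$kind == "morgan")
      morgan_bits(gr, spec$radius, spec$nbits)
    else layered_bits(gr, spec$min_path, spec$max_path, spec$nbits)
    mat[i, bits] <- 1L
  }
  dropped <- c(ids[!ok], gg$dropped)
  if (length(dropped) > 0L)
    warning(length(dropped), " molecule(s) could not be parsed and were dropped")
  attr(mat, "dropped") <- dropped
  attr(mat, "spec") <- spec
  mat
}
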
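# Physicochemical properties and drug-likeness rule filters.
#
# MW, Wildman-Crippen logP (WLOGP), molar refractivity, TPSA and
# H-bond-donor counts come from Open Babel's property engine; atom,
# ring and rotatable-bond counts from the package's molecular graphs.
# MLOGP is a truncated Moriguchi-type topological estimate (dominant
# carbon/halogen and N,O terms plus proximity, unsaturation,
# quaternary-N, nitro and alkane corrections); it serves the Lipinski
# MLOGP <= 4.15 bound, not high-accuracy logP prediction.

HALOGEN_WEIGHT <- c(F = 0.5, Cl = 1.0, Br = 1.5, I = 2.0)

moriguchi_logp <- function(gr) {
  elem <- gr$elem
  cx <- sum(elem == "C") +
    sum(unname(HALOGEN_WEIGHT[elem[elem %in% names(HALOGEN_WEIGHT)]]))
  no <- sum(elem %in% c("N", "O"))
  # proximity: N/O pairs bonded (2) or one atom apart (1)
  prx <- 0
  if (nrow(gr$bonds) > 0L) {
    is_no <- elem %in% c("N", "O")
    adj <- vector("list", gr$n_heavy)
    for (k in seq_len(nrow(gr$bonds))) {
      a <- gr$bonds$a[k]; b <- gr$bonds$b[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      if (is_no[a] && is_no[b]) prx <- prx + 2
    }
    for (v in seq_len(gr$n_heavy)) {
      nb <- adj[[v]]
      nno <- sum(is_no[nb])
      if (nno >= 2) prx <- prx + choose(nno, 2) * 1
    }
  }
  ub <- sum(gr$bonds$order >= 2)
  qn <- sum(elem == "N" & (gr$degree + gr$n_h > 3 | gr$charge > 0))
  no2 <- 0
  if (nrow(gr$bonds) > 0L) {
    for (v in which(elem == "N")) {
      ox <- 0
      for (k in seq_len(nrow(gr$bonds))) {
        w <- if (gr$bonds$a[k] == v) gr$bonds$b[k] else
          if (gr$bonds$b[k] == v) gr$bonds$a[k] else next
        if (elem[w] == "O" && gr$degree[w] == 1L) ox <- ox + 1
      }
      if (ox >= 2) no2 <- no2 + 1
    }
  }
  alk <- as.numeric(all(elem == "C") && all(gr$bonds$order == 1L) &&
                      gr$n_rings == 0L)
  rng <- as.numeric(gr$n_rings > 0L)
  -1.014 + 1.244 * cx^0.6 - 1.017 * no^0.9 + 0.406 * prx -
    0.145 * ub^0.8 - 3.684 * qn + 0.474 * no2 + 0.912 * alk - 0.392 * rng
}

count_rotatable_bonds <- function(gr) {
  if (nrow(gr$bonds) == 0L) return(0L)
  elem <- gr$elem
  # C double-bonded to a terminal O: amide carbon candidates
  carbonyl_c <- unique(c(
    gr$bonds$a[gr$bonds$order == 2L & elem[gr$bonds$b] == "O" &
                 gr$degree[gr$bonds$b] == 1L],
    gr$bonds$b[gr$bonds$order == 2L & elem[gr$bonds$a] == "O" &
                 gr$degree[gr$bonds$a] == 1L]))
  carbonyl_c <- carbonyl_c[elem[carbonyl_c] == "C"]
  n <- 0L
  for (k in seq_len(nrow(gr$bonds))) {
    if (gr$bonds$order[k] != 1L || gr$ring_bond[k]) next
    a <- gr$bonds$a[k]; b <- gr$bonds$b[k]
    if (gr$degree[a] < 2L || gr$degree[b] < 2L) next
    amide <- (a %in% carbonyl_c && elem[b] == "N") ||
      (b %in% carbonyl_c && elem[a] == "N")
    if (amide) next
    n <- n + 1L
  }
  n
}

#' Compute physicochemical properties
#'
#' Returns, per compound: molecular weight (g/mol), WLOGP (atom-additive
#' Wildman-Crippen logP), MLOGP (topological Moriguchi-type logP), TPSA
#' (A^2), H-bond donors and acceptors (Lipinski counting: OH/NH donors,
#' N+O acceptors), rotatable bonds (non-ring single bonds between
#' non-terminal heavy atoms, amides excluded), molar refractivity, atom
#' counts and ring count.
#'
#' @param smiles character vector of SMILES, or data.frame with
#'   \code{id}/\code{smiles}.
#' @param ids compound identifiers.
#' @return data.frame, one row per parseable compound, with columns
#'   \code{id}, \code{mw}, \code{wlogp}, \code{mlogp}, \code{tpsa},
#'   \code{hbd}, \code{hba}, \code{rotb}, \code{mr}, \code{total_atoms},
#'   \code{heavy_atoms}, \code{rings}, \code{carbons},
#'   \code{heteroatoms}. Unparseable ids are in attribute
#'   \code{"dropped"}.
#' @export
compute_mol_props <- function(smiles, ids = NULL) {
  if (is.data.frame(smiles)) {
    ids <- as.character(smiles$id)
    smiles <- as.character(smiles$smiles)
  }
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  gg <- smiles_to_graphs(smiles, ids)
  kept <- names(gg$graphs)
  keep_idx <- match(kept, ids)

  src <- paste(paste(smiles[keep_idx], seq_along(keep_idx)), collapse = "\n")
  props <- ChemmineOB::forEachMol("SMILES", src,
                                  function(m) ChemmineOB::prop_OB(m))
  pdf <- do.call(rbind, props)

  rows <- lapply(seq_along(kept), function(i) {
    gr <- gg$graphs[[i]]
    p <- pdf[i, ]
    data.frame(
      id = kept[i],
      mw = p$MW,
      wlogp = p$logP,
      mlogp = moriguchi_logp(gr),
      tpsa = p$TPSA,
      hbd = p$HBD,
      hba = sum(gr$elem %in% c("N", "O")),
      rotb = count_rotatable_bonds(gr),
      mr = p$MR,
      total_atoms = gr$n_atoms_total,
      heavy_atoms = gr$n_heavy,
      rings = gr$n_rings,
      carbons = sum(gr$elem == "C"),
      heteroatoms = sum(!gr$elem %in% c("C", "H")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- gg$dropped
  out
}

#' Apply the five drug-likeness rule filters
#'
#' Evaluates Lipinski, Ghose, Veber, Egan and Muegge rules on a property
#' row (as returned by \code{\link{compute_mol_props}}):
#' \itemize{
#'   \item Lipinski: pass with at most one violation of MW <= 500,
#'     MLOGP <= 4.15, HBD <= 5, HBA <= 10.
#'   \item Ghose: 160 <= MW <= 480, -0.4 <= WLOGP <= 5.6,
#'     40 <= MR <= 130, 20 <= total atoms <= 70.
#'   \item Veber: rotatable bonds <= 10 and TPSA <= 140.
#'   \item Egan: WLOGP <= 5.88 and TPSA <= 131.6.
#'   \item Muegge: 200 <= MW <= 600, -2 <= WLOGP <= 5, TPSA <= 150,
#'     rings <= 7, carbons > 4, heteroatoms > 1, rotatable bonds <= 15,
#'     HBA <= 10, HBD <= 5 (all conditions required; the original XLOGP3
#'     bound is approximated by WLOGP).
#' }
#'
#' @param props single-row data.frame or named list of properties.
#' @return named list of rule results; each has \code{filter},
#'   \code{pass} and \code{violations} (data.frame of failed
#'   \code{condition} / \code{observed}).
#' @export
apply_rule_filters <- function(props) {
  p <- as.list(props)
  check <- function(cond, label, observed) {
    if (cond) NULL else data.frame(condition = label, observed = observed,
                                   stringsAsFactors = FALSE)
  }
  lip <- do.call(rbind, list(
    check(p$mw <= 500, "MW <= 500", p$mw),
    check(p$mlogp <= 4.15, "MLOGP <= 4.15", p$mlogp),
    check(p$hbd <= 5, "HBD <= 5", p$hbd),
    check(p$hba <= 10, "HBA <= 10", p$hba)))
  gho <- do.call(rbind, list(
    check(p$mw >= 160 && p$mw <= 480, "160 <= MW <= 480", p$mw),
    check(p$wlogp >= -0.4 && p$wlogp <= 5.6, "-0.4 <= WLOGP <= 5.6",
          p$wlogp),
    check(p$mr >= 40 && p$mr <= 130, "40 <= MR <= 130", p$mr),
    check(p$total_atoms >= 20 && p$total_atoms <= 70,
          "20 <= atoms <= 70", p$total_atoms)))
  veb <- do.call(rbind, list(
    check(p$rotb <= 10, "ROTB <= 10", p$rotb),
    check(p$tpsa <= 140, "TPSA <= 140", p$tpsa)))
  ega <- do.call(rbind, list(
    check(p$wlogp <= 5.88, "WLOGP <= 5.88", p$wlogp),
    check(p$tpsa <= 131.6, "TPSA <= 131.6", p$tpsa)))
  mue <- do.call(rbind, list(
    check(p$mw >= 200 && p$mw <= 600, "200 <= MW <= 600", p$mw),
    check(p$wlogp >= -2 && p$wlogp <= 5, "-2 <= WLOGP <= 5", p$wlogp),
    check(p$tpsa <= 150, "TPSA <= 150", p$tpsa),
    check(p$rings <= 7, "rings <= 7", p$rings),
    check(p$carbons > 4, "carbons > 4", p$carbons),
    check(p$heteroatoms > 1, "heteroatoms > 1", p$heteroatoms),
    check(p$rotb <= 15, "ROTB <= 15", p$rotb),
    check(p$hba <= 10, "HBA <= 10", p$hba),
    check(p$hbd <= 5, "HBD <= 5", p$hbd)))
  empty <- data.frame(condition = character(0), observed = numeric(0))
  rule <- function(name, viol, pass) {
    list(filter = name, pass = pass,
         violations = if (is.null(viol)) empty else viol)
  }
  list(
    lipinski = rule("Lipinski", lip, is.null(lip) || nrow(lip) <= 1L),
    ghose = rule("Ghose", gho, is.null(gho)),
    veber = rule("Veber", veb, is.null(veb)),
    egan = rule("Egan", ega, is.null(ega)),
    muegge = rule("Muegge", mue, is.null(mue)))
}

#' Drug-likeness Yes/No table
#'
#' One row per compound, one column per rule filter, entries
#' \code{"Yes"}/\code{"No"}; the layout used to report drug-likeness of
#' screening hits. Unparseable SMILES are reported per row as \code{NA}.
#'
#' @param smiles character vector of SMILES or data.frame with
#'   \code{id}/\code{smiles}.
#' @param ids compound identifiers.
#' @return data.frame with columns \code{Compound}, \code{Lipinski},
#'   \code{Ghose}, \code{Veber}, \code{Egan}, \code{Muegge}.
#' @export
druglikeness_table <- function(smiles, ids = NULL) {
  if (is.data.frame(smiles)) {
    ids <- as.character(smiles$id)
    smiles <- as.character(smiles$smiles)
  }
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  cols <- c("Lipinski", "Ghose", "Veber", "Egan", "Muegge")
  if (length(smiles) == 0L) {
    out <- data.frame(Compound = character(0))
    for (cl in cols) out[[cl]] <- character(0)
    return(out)
  }
  props <- compute_mol_props(smiles, ids)
  out <- data.frame(Compound = ids, stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- NA_character_
  for (i in seq_len(nrow(props))) {
    rr <- apply_rule_filters(props[i, ])
    j <- match(props$id[i], out$Compound)
    out[j, cols] <- ifelse(vapply(rr, `[[`, TRUE, "pass"), "Yes", "No")
  }
  out
}
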
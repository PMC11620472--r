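# Activity tables, compound libraries and descriptor matrices.

#' Convert IC50 (nM) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50; for an
#' activity in nanomolar units this is \code{9 - log10(IC50_nM)}.
#'
#' @param activity_nM positive IC50 values in nM.
#' @return pIC50 values (unitless).
#' @export
ic50_to_pic50 <- function(activity_nM) {
  if (any(!is.finite(activity_nM)) || any(activity_nM <= 0))
    stop("IC50 values must be positive and finite (nM)")
  9 - log10(activity_nM)
}

#' Convert pIC50 back to IC50 in nM
#' @param pic50 pIC50 values.
#' @return IC50 in nM.
#' @export
pic50_to_ic50 <- function(pic50) 10^(9 - pic50)

#' Read a bioactivity table
#'
#' Reads a delimited activity table (a ChEMBL-style export or a generic
#' CSV), keeps rows with a SMILES and a positive activity, converts the
#' activity to pIC50 and reports dropped rows with reasons.
#'
#' @param file path to a CSV file, or a literal text block.
#' @param dialect \code{"chembl-csv"} (columns
#'   \code{Molecule ChEMBL ID}/\code{Smiles}/\code{Standard Value}, with
#'   \code{Standard Units}) or \code{"generic-csv"} (columns \code{id},
#'   \code{smiles}, \code{activity_nM}, optional \code{units}).
#' @param id_col,smiles_col,activity_col,units_col column-name overrides.
#' @param sep field separator (\code{","}; ChEMBL exports often use
#'   \code{";"}).
#' @return data.frame with columns \code{id}, \code{smiles},
#'   \code{activity_nM}, \code{pic50}, \code{source}; dropped rows are in
#'   the \code{"drops"} attribute as a data.frame of \code{id},
#'   \code{reason}.
#' @export
read_activity_table <- function(file,
                                dialect = c("generic-csv", "chembl-csv"),
                                id_col = NULL, smiles_col = NULL,
                                activity_col = NULL, units_col = NULL,
                                sep = ",") {
  dialect <- match.arg(dialect)
  defaults <- switch(dialect,
    "chembl-csv" = list(id = "Molecule ChEMBL ID", smiles = "Smiles",
                        act = "Standard Value", units = "Standard Units"),
    "generic-csv" = list(id = "id", smiles = "smiles",
                         act = "activity_nM", units = "units"))
  id_col <- id_col %||% defaults$id
  smiles_col <- smiles_col %||% defaults$smiles
  activity_col <- activity_col %||% defaults$act
  units_col <- units_col %||% defaults$units

  txt <- if (file.exists(file)) file else textConnection(file)
  df <- utils::read.csv(txt, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (col in c(id_col, smiles_col, activity_col)) {
    if (!col %in% names(df))
      stop("activity table is missing mandatory column '", col, "'")
  }
  id <- as.character(df[[id_col]])
  smiles <- as.character(df[[smiles_col]])
  act <- suppressWarnings(as.numeric(df[[activity_col]]))
  units <- if (units_col %in% names(df)) as.character(df[[units_col]]) else
    rep("nM", nrow(df))
  units[is.na(units) | units == ""] <- "nM"

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(smiles) | smiles == ""] <- "missing SMILES"
  known <- tolower(units) %in% c("nm", "um", "µm", "mm", "m", "pm")
  reason[is.na(reason) & !known] <- "unknown units"
  reason[is.na(reason) & is.na(act)] <- "missing activity"
  reason[is.na(reason) & act <= 0] <- "non-positive activity"

  mult <- c(pm = 1e-3, nm = 1, um = 1e3, "µm" = 1e3, mm = 1e6, m = 1e9)
  act_nM <- act * unname(mult[tolower(units)])

  keep <- is.na(reason)
  out <- data.frame(id = id[keep], smiles = smiles[keep],
                    activity_nM = act_nM[keep],
                    pic50 = if (any(keep)) ic50_to_pic50(act_nM[keep])
                            else numeric(0),
                    source = rep(dialect, sum(keep)),
                    stringsAsFactors = FALSE)
  drops <- data.frame(id = id[!keep], reason = reason[!keep],
                      stringsAsFactors = FALSE)
  attr(out, "drops") <- drops
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse records to unique canonical structures
#'
#' Canonicalises the SMILES of each record and keeps one record per
#' canonical form. Activities of duplicates are aggregated (median of
#' pIC50 by default). Records whose SMILES fail to parse are dropped and
#' reported.
#'
#' @param records data.frame with \code{id}, \code{smiles} and optionally
#'   \code{pic50} / \code{activity_nM} columns.
#' @param aggregate how duplicate activities are combined:
#'   \code{"median"}, \code{"mean"} or \code{"first"}.
#' @return data.frame of unique records (canonical SMILES in
#'   \code{smiles}); attribute \code{"drops"} lists unparseable ids,
#'   attribute \code{"n_merged"} the number of records absorbed into
#'   another.
#' @export
canonical_dedupe <- function(records,
                             aggregate = c("median", "mean", "first")) {
  aggregate <- match.arg(aggregate)
  can <- canonical_smiles(records$smiles)
  ok <- !is.na(can)
  drops <- records$id[!ok]
  rec <- records[ok, , drop = FALSE]
  rec$smiles <- can[ok]
  groups <- split(seq_len(nrow(rec)), rec$smiles)
  agg_fun <- switch(aggregate, median = stats::median, mean = mean,
                    first = function(x) x[[1L]])
  rows <- lapply(groups, function(ix) {
    r <- rec[ix[1L], , drop = FALSE]
    if (length(ix) > 1L) {
      if ("pic50" %in% names(rec))
        r$pic50 <- agg_fun(rec$pic50[ix])
      if ("activity_nM" %in% names(rec) && "pic50" %in% names(r))
        r$activity_nM <- pic50_to_ic50(r$pic50)
      else if ("activity_nM" %in% names(rec))
        r$activity_nM <- agg_fun(rec$activity_nM[ix])
    }
    r
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$smiles, rec$smiles))  # preserve first-seen order
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  attr(out, "n_merged") <- nrow(rec) - nrow(out)
  out
}

#' Read a DUD-E style .smi file
#'
#' Each non-empty line holds \code{SMILES whitespace id}. The
#' active/decoy label is left to the caller.
#'
#' @param file path or literal text.
#' @return data.frame with \code{id} and \code{smiles}.
#' @export
read_dude_smi <- function(file) {
  lines <- if (file.exists(file)) readLines(file, warn = FALSE) else
    strsplit(file, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 0L) < 2L)
  if (length(bad) > 0L)
    stop("line ", lineno[bad[1L]], " has no id field")
  data.frame(id = vapply(toks, function(t) paste(t[-1L], collapse = " "), ""),
             smiles = vapply(toks, `[[`, "", 1L),
             stringsAsFactors = FALSE)
}

#' Load a precomputed fingerprint table (PaDEL CSV dialect)
#'
#' First column is the compound name; remaining columns must be 0/1.
#' Tables of width other than 881 load with a warning flag (attribute
#' \code{"width_mismatch"}) so nonstandard exports remain usable.
#'
#' @param file path or literal CSV text.
#' @return 0/1 integer matrix, compound names as rownames.
#' @export
read_padel_fingerprints <- function(file) {
  txt <- if (file.exists(file)) file else textConnection(file)
  df <- utils::read.csv(txt, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(vals %in% c(0, 1)))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(vals))
    stop("non-binary fingerprint value at row ", rc[1L], ", column '",
         colnames(vals)[rc[2L]], "'")
  }
  storage.mode(vals) <- "integer"
  rownames(vals) <- ids
  mismatch <- ncol(vals) != 881L
  if (mismatch)
    warning("fingerprint table width is ", ncol(vals), ", not 881")
  attr(vals, "width_mismatch") <- mismatch
  vals
}

validate_descriptor_matrix <- function(mat) {
  stopifnot(is.matrix(mat), all(mat %in% c(0L, 1L)),
            !anyDuplicated(rownames(mat)), !anyDuplicated(colnames(mat)))
  invisible(mat)
}

#' Descriptor schema
#'
#' An ordered list of retained descriptor names together with its
#' provenance tag.
#'
#' @param names unique descriptor names, in order.
#' @param provenance one of \code{"train-retained"},
#'   \code{"library-retained"}, \code{"merged"}.
#' @return object of class \code{descriptor_schema}.
#' @export
descriptor_schema <- function(names, provenance = "train-retained") {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("descriptor names must be unique")
  structure(list(names = names, provenance = provenance),
            class = "descriptor_schema")
}

#' @export
print.descriptor_schema <- function(x, ...) {
  cat("Descriptor schema (", x$provenance, "): ", length(x$names),
      " descriptors\n", sep = "")
  invisible(x)
}

#' @export
length.descriptor_schema <- function(x) length(x$names)

#' Variance-threshold descriptor selection
#'
#' Retains the columns of a binary descriptor matrix whose variance
#' exceeds a threshold. For a 0/1 column with a fraction \eqn{p} of
#' ones the (population) variance is \eqn{p(1-p)}; near-constant bits
#' carry no structure-activity signal and are discarded. Column order is
#' preserved.
#'
#' @param mat 0/1 descriptor matrix (compounds x bits).
#' @param threshold minimum variance, default 0.16 (the 0.8(1-0.8)
#'   convention for binary fingerprints).
#' @param provenance provenance tag for the resulting schema.
#' @return A \code{\link{descriptor_schema}} of retained column names.
#' @export
variance_filter <- function(mat, threshold = 0.16,
                            provenance = "train-retained") {
  stopifnot(threshold >= 0)
  p <- colMeans(mat)
  v <- p * (1 - p)
  descriptor_schema(colnames(mat)[v > threshold], provenance)
}

#' Merge two descriptor schemas
#'
#' Harmonises the retained-descriptor sets of a training matrix and a
#' screening-library matrix. The default (\code{"union"}) keeps every
#' name present in either schema, ordered as the first schema followed by
#' names novel to the second; \code{"intersection"} keeps only shared
#' names.
#'
#' @param a,b \code{\link{descriptor_schema}} objects (or character
#'   vectors).
#' @param mode \code{"union"} or \code{"intersection"}.
#' @return merged \code{\link{descriptor_schema}} with provenance
#'   \code{"merged"}.
#' @export
merge_schemas <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  na <- if (inherits(a, "descriptor_schema")) a$names else as.character(a)
  nb <- if (inherits(b, "descriptor_schema")) b$names else as.character(b)
  out <- if (mode == "union") c(na, setdiff(nb, na)) else intersect(na, nb)
  descriptor_schema(out, "merged")
}

#' Project a descriptor matrix onto a schema
#'
#' Reorders columns to exactly the schema order, filling descriptors
#' absent from the input with zeros and dropping extra columns, so that
#' matrices built from different sources share one layout.
#'
#' @param mat 0/1 descriptor matrix.
#' @param schema \code{\link{descriptor_schema}} or character vector.
#' @return matrix with columns exactly \code{schema$names}.
#' @export
project_descriptors <- function(mat, schema) {
  nm <- if (inherits(schema, "descriptor_schema")) schema$names else
    as.character(schema)
  out <- matrix(0L, nrow(mat), length(nm),
                dimnames = list(rownames(mat), nm))
  shared <- intersect(nm, colnames(mat))
  out[, shared] <- mat[, shared]
  out
}
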
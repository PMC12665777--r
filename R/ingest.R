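#' Convert an IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50, the standard
#' potency scale for QSAR regression: \code{pIC50 = -log10(IC50 * 1e-9)} for
#' an IC50 given in nM, i.e. \code{9 - log10(IC50_nM)}.
#'
#' @param ic50_nM positive numeric vector of IC50 values in nanomolar.
#' @param id optional compound identifiers used in error messages.
#' @return numeric vector of pIC50 values.
#' @examples
#' ic50_to_pic50(1)     # 9
#' ic50_to_pic50(1000)  # 6
#' @export
ic50_to_pic50 <- function(ic50_nM, id = NULL) {
  bad <- !is.finite(ic50_nM) | ic50_nM <= 0
  if (any(bad)) {
    who <- if (!is.null(id)) paste(id[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    stop("IC50 must be a positive finite value (nM); offending compound(s): ",
         who, call. = FALSE)
  }
  -log10(ic50_nM * 1e-9)
}

#' Read a compound activity table
#'
#' Reads a delimited text file of compounds (one row per compound) with an
#' identifier column, an optional structure (SMILES) column and an IC50
#' column in nanomolar, and returns a data frame of compound records with
#' pIC50 populated. Rows whose IC50 cannot be parsed as a positive number are
#' dropped with a message.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map named list mapping the roles \code{id}, \code{smiles},
#'   \code{ic50} to column names in the file. Defaults to
#'   \code{list(id = "id", smiles = "smiles", ic50 = "ic50_nM")}.
#' @return a \code{data.frame} with columns \code{id}, \code{smiles},
#'   \code{ic50_nM}, \code{pic50}.
#' @export
read_compound_table <- function(path,
                                column_map = list(id = "id",
                                                  smiles = "smiles",
                                                  ic50 = "ic50_nM")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  for (role in c("id", "ic50")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop("compound table is missing the mandatory '", role, "' column",
           if (!is.null(col)) paste0(" ('", col, "')"), call. = FALSE)
  }
  smi_col <- column_map[["smiles"]]
  id <- trimws(raw[[column_map$id]])
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicated compound id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  ic50 <- suppressWarnings(as.numeric(raw[[column_map$ic50]]))
  keep <- is.finite(ic50) & ic50 > 0
  if (any(!keep))
    message(sum(!keep), " row(s) dropped: unparseable or non-positive IC50 (",
            paste(id[!keep], collapse = ", "), ")")
  smiles <- if (!is.null(smi_col) && smi_col %in% names(raw))
    raw[[smi_col]] else rep("", nrow(raw))
  out <- data.frame(id = id[keep],
                    smiles = smiles[keep],
                    ic50_nM = ic50[keep],
                    stringsAsFactors = FALSE)
  out$pic50 <- ic50_to_pic50(out$ic50_nM, out$id)
  out
}

#' Collapse duplicate compounds
#'
#' Duplicate compounds are collapsed to a single record carrying the median
#' pIC50 of the duplicate group. The duplicate key is the structure string
#' (whitespace-trimmed) when present, otherwise the exact id.
#'
#' @param records a compound data frame as returned by
#'   \code{\link{read_compound_table}}.
#' @return a compound data frame with at most one record per structure key.
#' @export
deduplicate <- function(records) {
  key <- ifelse(nzchar(trimws(records$smiles)),
                trimws(records$smiles), records$id)
  if (!anyDuplicated(key)) return(records)
  split_idx <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  rows <- lapply(split_idx, function(ix) {
    rec <- records[ix[1], , drop = FALSE]
    rec$pic50 <- stats::median(records$pic50[ix])
    rec$ic50_nM <- 10^(9 - rec$pic50)
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a descriptor matrix from CSV
#'
#' First column is the compound id; remaining columns are numeric molecular
#' descriptors. Columns containing any missing value are dropped with a
#' message (descriptor tables routinely contain undefined entries for some
#' structures). A non-numeric cell in a retained column is an error.
#'
#' @param path path to the CSV file.
#' @return a numeric matrix with compound ids as row names and descriptor
#'   names as column names.
#' @export
read_descriptor_matrix <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("descriptor file ", path, " is empty or has no descriptor columns",
         call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicated row id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- raw[-1]
  num <- lapply(vals, function(col) suppressWarnings(as.numeric(col)))
  is_blank <- function(col) is.na(col) | !nzchar(trimws(col)) |
    toupper(trimws(col)) %in% c("NA", "NAN")
  missing_any <- vapply(vals, function(col) any(is_blank(col)), logical(1))
  if (any(missing_any))
    message("dropping ", sum(missing_any),
            " descriptor column(s) with missing values: ",
            paste(names(vals)[missing_any], collapse = ", "))
  num <- num[!missing_any]
  vals <- vals[!missing_any]
  for (j in seq_along(num)) {
    bad <- is.na(num[[j]])
    if (any(bad))
      stop("non-numeric value '", vals[[j]][which(bad)[1]],
           "' at row ", which(bad)[1], " (id ", ids[which(bad)[1]],
           "), column '", names(vals)[j], "'", call. = FALSE)
  }
  X <- do.call(cbind, num)
  if (is.null(X)) stop("all descriptor columns were dropped", call. = FALSE)
  dimnames(X) <- list(ids, names(vals))
  X
}

#' Write a descriptor matrix to CSV
#'
#' Inverse of \code{\link{read_descriptor_matrix}}: a round trip through
#' write/read reproduces finite values bit-identically (values are written
#' with full double precision).
#'
#' @param X numeric matrix with row and column names.
#' @param path output path.
#' @param id_column name used for the id column header.
#' @return invisibly, \code{path}.
#' @export
write_descriptor_matrix <- function(X, path, id_column = "id") {
  df <- data.frame(rownames(X),
                   as.data.frame(format(X, digits = 17, trim = TRUE,
                                        scientific = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
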
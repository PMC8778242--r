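#' Construct a perturbation signature tensor
#'
#' The central container of the screen: differential-expression z-values
#' indexed by (compound, gene, cell line, timepoint), together with a
#' presence mask. Absent cells are distinguished from zero so that REC
#' denominators count only cell lines actually measured.
#'
#' @param z 4-d numeric array with dimnames `compound`, `gene`, `cell_line`,
#'   `timepoint`; `NA` allowed where absent.
#' @param present logical array of the same shape; defaults to `!is.na(z)`.
#' @return object of class `signature_tensor`.
#' @export
signature_tensor <- function(z, present = NULL) {
  stopifnot(is.array(z), length(dim(z)) == 4L)
  dn <- dimnames(z)
  if (is.null(dn) || any(vapply(dn, is.null, TRUE))) {
    stop("signature tensor requires dimnames on all four axes")
  }
  names(dimnames(z)) <- c("compound", "gene", "cell_line", "timepoint")
  if (is.null(present)) present <- !is.na(z)
  stopifnot(identical(dim(present), dim(z)))
  dimnames(present) <- dimnames(z)
  z[!present] <- NA_real_
  structure(list(z = z, present = present), class = "signature_tensor")
}

#' @export
print.signature_tensor <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("<signature_tensor> %d compounds x %d genes x %d cell lines x %d timepoints (%.1f%% present)\n",
              d[1], d[2], d[3], d[4], 100 * mean(x$present)))
  invisible(x)
}

#' Read a tall-format signature tensor
#'
#' Expects a TSV with header columns `compound`, `gene`, `cell_line`,
#' `timepoint`, `z` (any comment lines starting with `#` are skipped).
#' Combinations not present in the file are marked absent, not zero.
#'
#' @param path file path.
#' @return a [signature_tensor()].
#' @export
read_signature_tensor <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  need <- c("compound", "gene", "cell_line", "timepoint", "z")
  if (!all(need %in% names(df))) {
    stop("signature TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no records in signature TSV: ", path)
  zn <- suppressWarnings(as.numeric(df$z))
  bad <- which(is.na(zn) & !(df$z %in% c("NA", "")))
  if (length(bad)) {
    stop("non-numeric z value at data line ", bad[1], ": '", df$z[bad[1]], "'")
  }
  key <- paste(df$compound, df$gene, df$cell_line, df$timepoint, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[which(dup)[1]], "\r", fixed = TRUE)[[1]]
    stop(sprintf("duplicate signature key (compound=%s, gene=%s, cell_line=%s, timepoint=%s)",
                 k[1], k[2], k[3], k[4]))
  }
  dn <- list(compound = sort(unique(df$compound)),
             gene = sort(unique(df$gene)),
             cell_line = sort(unique(df$cell_line)),
             timepoint = sort(unique(df$timepoint)))
  z <- array(NA_real_, dim = unname(lengths(dn)), dimnames = dn)
  idx <- cbind(match(df$compound, dn$compound), match(df$gene, dn$gene),
               match(df$cell_line, dn$cell_line), match(df$timepoint, dn$timepoint))
  z[idx] <- zn
  signature_tensor(z)
}

#' Write a signature tensor as tall TSV
#'
#' Only present cells are written; rows are sorted by key so write/read
#' round-trips are byte-stable.
#'
#' @param tensor a [signature_tensor()].
#' @param path output path.
#' @param cfg optional `rec_config`; its hash is stamped in a header comment.
#' @export
write_signature_tensor <- function(tensor, path, cfg = NULL) {
  idx <- which(tensor$present, arr.ind = TRUE)
  dn <- dimnames(tensor$z)
  df <- data.frame(compound = dn$compound[idx[, 1]],
                   gene = dn$gene[idx[, 2]],
                   cell_line = dn$cell_line[idx[, 3]],
                   timepoint = dn$timepoint[idx[, 4]],
                   z = tensor$z[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$compound, df$gene, df$cell_line, df$timepoint), , drop = FALSE]
  write_output_tsv(df, path, cfg)
}

#' Read a GMT gene set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are collapsed; duplicate set names error.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: named list of character
#'   member vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1], " has fewer than 3 fields")
  }
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name in GMT: ", nms[duplicated(nms)][1])
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2L), nms)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene set collection to GMT
#' @param sets named list of member vectors (or `gene_set_collection`).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a patient survival cohort CSV
#'
#' Columns `patient_id`, `time`, `event` (0 = censored, 1 = death observed),
#' plus one numeric column per gene. Records with missing expression are
#' excluded with a log entry rather than erroring.
#'
#' @param path CSV path.
#' @return data.frame of class `survival_cohort`.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    stop("survival times must be positive and finite")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be coded 0/1")
  genes <- setdiff(names(df), need)
  if (length(genes)) {
    ok <- stats::complete.cases(df[, genes, drop = FALSE])
    if (any(!ok)) {
      rs_log("core_io", sum(!ok), " patient(s) excluded for missing expression")
      df <- df[ok, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("survival_cohort", "data.frame")
  df
}

#' Write a survival cohort CSV
#' @param cohort data.frame with `patient_id`, `time`, `event`, gene columns.
#' @param path output path.
#' @export
write_survival_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a labelled numeric matrix TSV
#'
#' Used for the basal expression matrix (cell line x gene) and the drug
#' sensitivity table (compound x cell line). First column holds row labels;
#' remaining header fields are column labels.
#'
#' @param path file path.
#' @param row_label name of the first (row label) column on write.
#' @return `read_labeled_matrix`: numeric matrix with dimnames.
#' @export
read_labeled_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix TSV: ", path)
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_labeled_matrix
#' @param m numeric matrix with dimnames.
#' @param cfg optional `rec_config` for the header stamp.
#' @export
write_labeled_matrix <- function(m, path, row_label = "id", cfg = NULL) {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  write_output_tsv(df, path, cfg)
}

#' Read a dose-response viability CSV
#'
#' Columns `dose` (nM, includes a 0 control), `viability` (% of control),
#' `replicate`.
#'
#' @param path CSV path.
#' @return data.frame sorted by dose.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("dose", "viability", "replicate")
  if (!all(need %in% names(df))) {
    stop("dose-response CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$dose < 0)) stop("doses must be nonnegative")
  if (!any(df$dose == 0)) stop("a dose-0 control record is required")
  if (any(!is.finite(df$viability))) stop("viability must be finite")
  df[order(df$dose, df$replicate), , drop = FALSE]
}

#' Write a pipeline output TSV with a reproducibility header
#'
#' All stage outputs share this format: a `# config_hash=... seed=...`
#' comment line, then a tab-separated table with a fixed column order.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param cfg optional `rec_config`.
#' @export
write_output_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(cfg)) {
    writeLines(sprintf("# config_hash=%s seed=%d", config_hash(cfg), cfg$seed), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_output_tsv
#' @export
read_output_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
}
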
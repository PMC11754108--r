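# Family alignments: gapped rows over a fixed set of columns plus the
# per-domain map from residue position to alignment column.

#' Construct a family alignment from gapped rows
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (gap characters `-` and `.` are both accepted and normalized to `-`).
#' @param family_id Family accession for the alignment.
#' @return A `family_alignment`: list with `family_id`, `columns` (count),
#'   `rows` and `column_map` (per row, 1-based residue position to 1-based
#'   alignment column).
#' @export
family_alignment <- function(rows, family_id = "family") {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    abort_foldstab("alignment rows must be named by domain id", "alignment")
  }
  if (anyDuplicated(names(rows))) {
    abort_foldstab(
      paste0(
        "duplicate row ids in alignment: ",
        paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", ")
      ),
      "alignment"
    )
  }
  rows <- gsub(".", "-", rows, fixed = TRUE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    abort_foldstab("ragged alignment: rows have unequal lengths", "alignment")
  }
  column_map <- lapply(rows, function(r) {
    which(strsplit(r, "", fixed = TRUE)[[1]] != "-")
  })
  structure(
    list(
      family_id = family_id,
      columns = unname(widths[1]),
      rows = rows,
      column_map = column_map
    ),
    class = "family_alignment"
  )
}

#' Read an aligned FASTA or Stockholm family alignment
#'
#' Both `-` and `.` gaps are accepted and normalized to `-`. Ragged rows and
#' duplicate row ids are hard errors.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (sniff Stockholm header / file extension),
#'   `"fasta"` or `"stockholm"`.
#' @param family_id Family accession; defaults to the file name without
#'   extension.
#' @return A [family_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm"),
                           family_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first) ||
      grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE)) {
      "stockholm"
    } else {
      "fasta"
    }
  }
  rows <- if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(set), names(set))
  } else {
    aln <- Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    )
    stats::setNames(as.character(aln), names(aln))
  }
  family_alignment(rows, family_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a family alignment as aligned FASTA
#'
#' @param alignment A [family_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "family_alignment"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(alignment$rows), path
  )
  invisible(path)
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(
    "<family_alignment> ", x$family_id, ": ", length(x$rows), " rows x ",
    x$columns, " columns\n",
    sep = ""
  )
  invisible(x)
}

# Ungapped sequence of one alignment row.
ungap_row <- function(row) gsub("-", "", row, fixed = TRUE)

# Residues of each row at a given column (NA when gapped).
column_residues <- function(alignment, column) {
  vapply(
    alignment$rows,
    function(r) {
      ch <- substr(r, column, column)
      if (ch == "-") NA_character_ else ch
    },
    character(1)
  )
}
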
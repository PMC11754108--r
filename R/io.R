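# Readers and writers for per-variant fitness tables. Parsing is
# locale-independent (decimal points only) and every malformed row is
# reported with its line number.

#' Declare the column layout of a variant fitness table
#'
#' @param domain_id,position,wt_aa,mut_aa,fitness,sigma Column names in the
#'   file for the respective fields.
#' @param growth_rate_prefix,count_prefix Prefixes of the per-replicate
#'   growth-rate and read-count columns (suffixed `1..k`); either group may
#'   be absent from the file.
#' @return A dialect description for [read_variant_table()].
#' @export
variant_dialect <- function(domain_id = "domain_id",
                            position = "position",
                            wt_aa = "wt_aa",
                            mut_aa = "mut_aa",
                            fitness = "fitness",
                            sigma = "sigma",
                            growth_rate_prefix = "growth_rate_",
                            count_prefix = "count_") {
  as.list(environment())
}

#' Read a per-variant fitness table from TSV
#'
#' The variant class is derived from the amino acids: a stop (`*`) mutant is
#' nonsense, a mutant equal to the wild type is synonymous, anything else is
#' missense. Missing required columns are a hard error naming the column;
#' non-numeric fitness values are row-level errors with line numbers.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Column layout from [variant_dialect()].
#' @return A tibble of variants with standardized column names.
#' @export
read_variant_table <- function(path, dialect = variant_dialect()) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."),
    progress = FALSE
  )
  required <- c(
    dialect$domain_id, dialect$position, dialect$wt_aa, dialect$mut_aa,
    dialect$fitness, dialect$sigma
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort_foldstab(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      "io"
    )
  }
  parse_num <- function(col, label) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad)) {
      abort_foldstab(
        paste0(
          "non-numeric ", label, " value(s) at line(s) ",
          paste(bad + 1L, collapse = ", "), " of ", path
        ),
        "io"
      )
    }
    x
  }
  out <- tibble::tibble(
    domain_id = raw[[dialect$domain_id]],
    position = as.integer(parse_num(dialect$position, "position")),
    wt_aa = raw[[dialect$wt_aa]],
    mut_aa = raw[[dialect$mut_aa]],
    fitness = parse_num(dialect$fitness, "fitness"),
    sigma = parse_num(dialect$sigma, "sigma")
  )
  out$variant_class <- dplyr::case_when(
    out$mut_aa == "*" ~ "nonsense",
    out$mut_aa == out$wt_aa ~ "synonymous",
    TRUE ~ "missense"
  )
  for (prefix in c(dialect$growth_rate_prefix, dialect$count_prefix)) {
    reps <- grep(
      paste0("^", prefix, "\\d+$"), names(raw),
      value = TRUE
    )
    for (col in reps) {
      std <- if (prefix == dialect$growth_rate_prefix) {
        sub(prefix, "growth_rate_", col)
      } else {
        sub(prefix, "count_", col)
      }
      out[[std]] <- parse_num(col, col)
      if (startsWith(std, "count_")) out[[std]] <- as.integer(out[[std]])
    }
  }
  out[, c(
    "domain_id", "position", "wt_aa", "mut_aa", "variant_class",
    setdiff(names(out), c(
      "domain_id", "position", "wt_aa", "mut_aa", "variant_class"
    ))
  )]
}

#' Write a variant table as TSV
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

#' Validate variants against their domain records
#'
#' Checks that positions fall inside the domain sequence, that the stated
#' wild-type residue matches the sequence, and that errors are positive.
#'
#' @param variants A variant tibble.
#' @param domains A domain tibble with `domain_id` and `sequence`.
#' @return `variants`, invisibly, if valid; otherwise an error listing the
#'   offending `domain_id`/`position` pairs.
#' @export
validate_variants <- function(variants, domains) {
  v <- dplyr::left_join(
    variants, domains[, c("domain_id", "sequence")],
    by = "domain_id"
  )
  if (anyNA(v$sequence)) {
    bad <- unique(v$domain_id[is.na(v$sequence)])
    abort_foldstab(
      paste0("unknown domain id(s): ", paste(bad, collapse = ", ")),
      "validate"
    )
  }
  len <- nchar(v$sequence)
  oob <- v$position < 1 | v$position > len
  seq_aa <- substr(v$sequence, v$position, v$position)
  mismatch <- !oob & seq_aa != v$wt_aa
  bad_sigma <- !is.na(v$sigma) & v$sigma <= 0
  problems <- oob | mismatch | bad_sigma
  if (any(problems)) {
    rows <- utils::head(which(problems), 20)
    abort_foldstab(
      paste0(
        "invalid variant row(s): ",
        paste(
          sprintf(
            "%s:%d (%s)", v$domain_id[rows], v$position[rows],
            dplyr::case_when(
              oob[rows] ~ "position out of range",
              mismatch[rows] ~ paste0(
                "wt_aa disagrees with sequence (", seq_aa[rows], ")"
              ),
              TRUE ~ "sigma must be positive"
            )
          ),
          collapse = "; "
        )
      ),
      "validate"
    )
  }
  invisible(variants)
}

#' Read a clinical annotation table from TSV
#'
#' Labels must be one of pathogenic, benign, vus or population; the allele
#' frequency must be present iff the label is population. When multiple rows
#' give conflicting labels for the same variant, the merged label drops to
#' VUS with a warning.
#'
#' @param path Path to a TSV with columns `domain_id`, `position`, `wt_aa`,
#'   `mut_aa`, `label` and optionally `allele_frequency`.
#' @return A tibble of clinical annotations, one row per variant.
#' @export
read_clinical_table <- function(path) {
  ann <- readr::read_tsv(
    path,
    col_types = readr::cols(
      domain_id = readr::col_character(),
      position = readr::col_integer(),
      wt_aa = readr::col_character(),
      mut_aa = readr::col_character(),
      label = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (!"allele_frequency" %in% names(ann)) ann$allele_frequency <- NA_real_
  bad <- !ann$label %in% c("pathogenic", "benign", "vus", "population")
  if (any(bad)) {
    abort_foldstab(
      paste0("unknown label(s): ", paste(unique(ann$label[bad]), collapse = ", ")),
      "io"
    )
  }
  if (any(ann$label == "population" & is.na(ann$allele_frequency)) ||
    any(ann$label != "population" & !is.na(ann$allele_frequency))) {
    abort_foldstab(
      "allele_frequency must be present iff label is 'population'", "io"
    )
  }
  merged <- ann |>
    dplyr::group_by(dplyr::across(dplyr::all_of(variant_keys))) |>
    dplyr::summarise(
      n_labels = dplyr::n_distinct(.data$label),
      label = if (dplyr::n_distinct(.data$label) == 1L) {
        .data$label[1]
      } else {
        "vus"
      },
      allele_frequency = .data$allele_frequency[1],
      .groups = "drop"
    )
  if (any(merged$n_labels > 1L)) {
    rlang::warn(sprintf(
      "%d variant(s) had conflicting labels across sources; merged to VUS",
      sum(merged$n_labels > 1L)
    ))
    merged$allele_frequency[merged$n_labels > 1L] <- NA_real_
  }
  merged$n_labels <- NULL
  merged
}
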
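# Shared constants and small numeric helpers.

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order. Stop codons are written `"*"` in
#' variant tables and classified as nonsense.
#'
#' @export
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Kyte-Doolittle hydropathy, used only as the default QC hydrophobicity scale;
# any named 20-value vector can be supplied instead.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' Two-state fraction folded
#'
#' Boltzmann occupancy of the folded state, `1 / (1 + exp(dG))`, with folding
#' free energy `dG` in RT units (negative = stable).
#'
#' @param dg Folding free energy (RT units).
#' @return Fraction folded in (0, 1).
#' @export
fraction_folded <- function(dg) stats::plogis(-dg)

#' Derive a stage-specific seed from a master seed
#'
#' Stable sub-seeding: hashing `(seed, label)` means adding new stages never
#' perturbs the random streams of existing ones.
#'
#' @param seed Master seed (single integer).
#' @param label Character label of the consuming stage.
#' @return A single integer below `2^31`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- rlang::hash(list(as.integer(seed), label))
  (strtoi(substr(h, 1L, 7L), base = 16L) + abs(as.integer(seed))) %%
    .Machine$integer.max
}

variant_keys <- c("domain_id", "position", "wt_aa", "mut_aa")

# Benjamini-Hochberg wrapper; kept as one call site so the FDR family used by
# each caller is easy to audit.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

growth_rate_cols <- function(df) {
  grep("^growth_rate_\\d+$", names(df), value = TRUE)
}

count_cols <- function(df) {
  grep("^count_\\d+$", names(df), value = TRUE)
}

`%||%` <- rlang::`%||%`

abort_foldstab <- function(msg, class) {
  rlang::abort(msg, class = paste0("foldstab_", class))
}
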
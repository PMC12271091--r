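# Reading, harmonizing and QC-filtering GWAS summary statistics.
#
# Canonical dialect: whitespace- or tab-delimited text with a header row
# (gzip handled transparently by data.table::fread). A column_map translates
# arbitrary header names onto the canonical fields, so other dialects are
# readable without code changes.

CANONICAL_FIELDS <- c("variant_id", "chrom", "pos", "allele_effect",
                      "allele_other", "z", "beta", "se", "n", "freq_effect",
                      "pvalue")

#' Default column map for common sumstats header conventions
#'
#' Maps the canonical field names onto frequently seen headers
#' (SNP/A1/A2/Z/BETA/SE/N/FRQ/P and close variants).
#' @export
default_column_map <- function() {
  list(variant_id    = c("SNP", "RSID", "ID", "variant_id", "MarkerName"),
       chrom         = c("CHR", "CHROM", "chrom"),
       pos           = c("BP", "POS", "pos"),
       allele_effect = c("A1", "EA", "allele_effect", "EFFECT_ALLELE"),
       allele_other  = c("A2", "OA", "allele_other", "OTHER_ALLELE"),
       z             = c("Z", "ZSCORE", "z"),
       beta          = c("BETA", "B", "beta", "LOG_ODDS"),
       se            = c("SE", "se", "StdErr"),
       n             = c("N", "n", "NEFF", "N_EFF"),
       freq_effect   = c("FRQ", "EAF", "FREQ", "MAF", "freq_effect"),
       pvalue        = c("P", "PVAL", "PVALUE", "pvalue", "P_VALUE"))
}

#' Read one trait's GWAS summary statistics
#'
#' Reads a delimited summary-statistics file, renames columns onto the
#' canonical schema and validates the table invariants. When no Z column is
#' present, Z is computed as beta / se. Row order is preserved.
#'
#' @param path file path (plain or gzipped delimited text with header)
#' @param trait_label short label for the trait
#' @param column_map named list mapping canonical field names to one or more
#'   candidate header names; see [default_column_map()]
#' @return a \code{sumstats_table}: a data.frame with canonical columns and
#'   attribute \code{trait_label}
#' @export
read_sumstats <- function(path, trait_label = basename(path),
                          column_map = default_column_map()) {
  if (!file.exists(path)) stop("sumstats file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  hdr <- names(dt)
  picked <- list()
  for (field in names(column_map)) {
    hit <- intersect(column_map[[field]], hdr)
    if (length(hit) > 0) picked[[field]] <- hit[[1]]
  }
  need <- c("variant_id", "allele_effect", "allele_other", "n")
  missing <- setdiff(need, names(picked))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         " (headers seen: ", paste(hdr, collapse = ", "), ")")
  has_z    <- "z" %in% names(picked)
  has_beta <- all(c("beta", "se") %in% names(picked))
  if (!has_z && !has_beta)
    stop("missing mandatory column: z (or beta and se)")

  out <- data.frame(variant_id = as.character(dt[[picked$variant_id]]),
                    stringsAsFactors = FALSE)
  out$chrom <- if (!is.null(picked$chrom)) as.character(dt[[picked$chrom]]) else NA_character_
  out$pos   <- if (!is.null(picked$pos)) as.integer(dt[[picked$pos]]) else seq_len(nrow(dt))
  out$allele_effect <- toupper(as.character(dt[[picked$allele_effect]]))
  out$allele_other  <- toupper(as.character(dt[[picked$allele_other]]))
  if (has_z) {
    out$z <- suppressWarnings(as.numeric(dt[[picked$z]]))
  } else {
    beta <- suppressWarnings(as.numeric(dt[[picked$beta]]))
    se   <- suppressWarnings(as.numeric(dt[[picked$se]]))
    out$z <- beta / se
  }
  out$n <- suppressWarnings(as.numeric(dt[[picked$n]]))
  out$freq_effect <- if (!is.null(picked$freq_effect))
    suppressWarnings(as.numeric(dt[[picked$freq_effect]])) else NA_real_
  out$pvalue <- if (!is.null(picked$pvalue))
    suppressWarnings(as.numeric(dt[[picked$pvalue]])) else NA_real_

  bad_z <- which(!is.finite(out$z))
  if (length(bad_z) > 0)
    stop("non-numeric or non-finite z at data line(s): ",
         paste(head(bad_z, 5), collapse = ", "))
  bad_n <- which(!is.finite(out$n) | out$n <= 0)
  if (length(bad_n) > 0)
    stop("non-numeric or non-positive n at data line(s): ",
         paste(head(bad_n, 5), collapse = ", "))
  dup <- out$variant_id[duplicated(out$variant_id)]
  if (length(dup) > 0)
    stop("duplicated variant_id: ", paste(unique(head(dup, 5)), collapse = ", "))
  same <- which(out$allele_effect == out$allele_other)
  if (length(same) > 0)
    stop("allele_effect equals allele_other at row(s): ",
         paste(head(same, 5), collapse = ", "))

  structure(out, trait_label = trait_label, class = c("sumstats_table", "data.frame"))
}

#' Write a sumstats table in the canonical dialect
#'
#' @param x a \code{sumstats_table} (or compatible data.frame)
#' @param path output path (".gz" suffix gzips)
#' @export
write_sumstats <- function(x, path) {
  cols <- data.frame(SNP = x$variant_id, CHR = x$chrom, BP = x$pos,
                     A1 = x$allele_effect, A2 = x$allele_other,
                     Z = x$z, N = x$n, FRQ = x$freq_effect, P = x$pvalue)
  data.table::fwrite(cols, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous_pair <- function(a1, a2) {
  single <- nchar(a1) == 1 & nchar(a2) == 1
  comp <- unname(COMPLEMENT[a1])
  single & !is.na(comp) & comp == a2
}

complement_allele <- function(a) {
  out <- unname(COMPLEMENT[a])
  out[is.na(out)] <- a[is.na(out)]  # indels pass through
  out
}

#' Harmonize several sumstats tables onto a shared variant set
#'
#' Intersects variant IDs, aligns every trait's effect allele to the first
#' table's convention (flipping z where effect/other are swapped, with
#' strand-complement matching for non-ambiguous single-base variants), and
#' drops strand-ambiguous (A/T, C/G) variants as well as variants whose
#' allele pairs cannot be reconciled.
#'
#' @param tables list of \code{sumstats_table} (length >= 2)
#' @return a \code{harmonized_panel}: list with \code{traits},
#'   \code{variants} (data.frame of id/chrom/pos/alleles in the first
#'   table's convention), \code{z} and \code{n} (variant x trait matrices),
#'   \code{freq} (from the first table where available), and per-trait
#'   \code{sign_flips} / total \code{dropped_ambiguous} /
#'   \code{dropped_irreconcilable} counts
#' @export
harmonize <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  labels <- unname(vapply(tables, function(t) attr(t, "trait_label") %||% "?", ""))
  if (anyDuplicated(labels))
    labels <- make.unique(labels)

  ids <- Reduce(intersect, lapply(tables, `[[`, "variant_id"))
  if (length(ids) == 0) stop("empty variant intersection across tables")

  ref <- tables[[1]]
  ref <- ref[match(ids, ref$variant_id), , drop = FALSE]

  # drop strand-ambiguous variants if ambiguous in ANY table
  ambig <- is_ambiguous_pair(ref$allele_effect, ref$allele_other)
  for (t in tables[-1]) {
    tt <- t[match(ids, t$variant_id), , drop = FALSE]
    ambig <- ambig | is_ambiguous_pair(tt$allele_effect, tt$allele_other)
  }

  k <- length(tables)
  zmat <- matrix(NA_real_, length(ids), k, dimnames = list(ids, labels))
  nmat <- zmat
  swap_mat <- matrix(FALSE, length(ids), k)
  irrec_any <- rep(FALSE, length(ids))
  for (j in seq_len(k)) {
    tt <- tables[[j]][match(ids, tables[[j]]$variant_id), , drop = FALSE]
    e <- tt$allele_effect; o <- tt$allele_other
    re <- ref$allele_effect; ro <- ref$allele_other
    match_same <- (e == re & o == ro) | (complement_allele(e) == re & complement_allele(o) == ro)
    match_swap <- (e == ro & o == re) | (complement_allele(e) == ro & complement_allele(o) == re)
    match_swap <- match_swap & !match_same  # same wins for palindromic leftovers
    irrec_any <- irrec_any | !(match_same | match_swap)
    swap_mat[, j] <- match_swap
    zmat[, j] <- tt$z * ifelse(match_swap, -1, 1)
    nmat[, j] <- tt$n
  }

  keep <- !ambig & !irrec_any
  n_irrec <- sum(irrec_any & !ambig)
  sign_flips <- colSums(swap_mat[keep, , drop = FALSE])
  names(sign_flips) <- labels
  variants <- data.frame(variant_id = ids, chrom = ref$chrom, pos = ref$pos,
                         allele_effect = ref$allele_effect,
                         allele_other = ref$allele_other,
                         stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # recount flips on surviving variants only
  structure(list(traits = labels,
                 variants = variants,
                 z = zmat[keep, , drop = FALSE],
                 n = nmat[keep, , drop = FALSE],
                 freq = ref$freq_effect[keep],
                 sign_flips = sign_flips,
                 dropped_ambiguous = sum(ambig),
                 dropped_irreconcilable = n_irrec),
            class = "harmonized_panel")
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat("harmonized_panel:", nrow(x$z), "variants x", length(x$traits),
      "traits\n  traits:", paste(x$traits, collapse = ", "),
      "\n  sign flips:", paste(x$sign_flips, collapse = "/"),
      "  dropped ambiguous:", x$dropped_ambiguous,
      "  irreconcilable:", x$dropped_irreconcilable, "\n")
  invisible(x)
}

#' Quality-filter a harmonized panel
#'
#' Removes variants whose effect-allele frequency falls outside
#' \[maf_min, 1 - maf_min\] (where frequency is available) and variants with
#' z^2 above \code{chisq_max} in any trait. With \code{maf_min = 0} and
#' \code{chisq_max = NULL} the filter is the identity.
#'
#' @param panel a \code{harmonized_panel}
#' @param maf_min minimum minor-allele frequency in \[0, 0.5)
#' @param chisq_max drop variants with z^2 above this in any trait;
#'   \code{NULL} disables. The conventional default is
#'   \code{max(80, 0.001 * median(N))}.
#' @return filtered \code{harmonized_panel}
#' @export
qc_filter <- function(panel, maf_min = 0.01, chisq_max = default_chisq_max(panel)) {
  stopifnot(inherits(panel, "harmonized_panel"),
            maf_min >= 0, maf_min < 0.5)
  keep <- rep(TRUE, nrow(panel$z))
  if (maf_min > 0 && any(is.finite(panel$freq))) {
    f <- panel$freq
    keep <- keep & (!is.finite(f) | (f >= maf_min & f <= 1 - maf_min))
  }
  if (!is.null(chisq_max)) {
    keep <- keep & apply(panel$z^2 <= chisq_max, 1, all)
  }
  if (!any(keep)) stop("qc_filter removed all variants")
  panel$variants <- panel$variants[keep, , drop = FALSE]
  panel$z <- panel$z[keep, , drop = FALSE]
  panel$n <- panel$n[keep, , drop = FALSE]
  panel$freq <- panel$freq[keep]
  panel
}

#' Conventional outlier threshold for association chi-square
#' @param panel a \code{harmonized_panel}
#' @export
default_chisq_max <- function(panel) {
  max(80, 0.001 * median(panel$n, na.rm = TRUE))
}

#' Write a harmonized panel as one wide table plus a JSON provenance record
#'
#' @param panel a \code{harmonized_panel}
#' @param path output path for the wide delimited table; a sidecar
#'   \code{<path>.json} records flip/drop counts
#' @export
write_panel <- function(panel, path) {
  wide <- panel$variants
  for (j in seq_along(panel$traits)) {
    wide[[paste0("Z.", panel$traits[j])]] <- panel$z[, j]
    wide[[paste0("N.", panel$traits[j])]] <- panel$n[, j]
  }
  wide$FRQ <- panel$freq
  data.table::fwrite(wide, path, sep = "\t", na = "NA", quote = FALSE)
  write_json_file(list(traits = as.list(panel$traits),
                       n_variants = nrow(panel$z),
                       sign_flips = as.list(panel$sign_flips),
                       dropped_ambiguous = panel$dropped_ambiguous,
                       dropped_irreconcilable = panel$dropped_irreconcilable),
                  paste0(path, ".json"))
  invisible(path)
}

#' Read a reference dosage panel
#'
#' The panel is a delimited genotype dosage matrix (variants x samples,
#' values 0/1/2 or fractional dosages) with a sidecar variant map holding
#' id, chrom, pos and alleles.
#'
#' @param dosage_path delimited dosage matrix, no header, one row per variant
#' @param map_path delimited variant map with header
#'   (variant_id, chrom, pos, allele_effect, allele_other)
#' @return list with \code{dosage} (matrix) and \code{map} (data.frame)
#' @export
read_panel <- function(dosage_path, map_path) {
  dose <- as.matrix(data.table::fread(dosage_path, header = FALSE,
                                      data.table = FALSE, showProgress = FALSE))
  map <- data.table::fread(map_path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  stopifnot(nrow(dose) == nrow(map))
  rownames(dose) <- map$variant_id
  list(dosage = unname(dose), map = map)
}
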
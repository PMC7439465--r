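#' Pairwise differential comparison of two strains
#'
#' Computes, for every protein in the profile, the DAve and DCI indices
#' between the averaged spectral counts of two strains, classifies each
#' protein with the inclusive DAve/DCI threshold filter, and attaches the
#' chromatic code used in the differential table. Orientation: `sample_x`
#' is the X term, so positive DAve means up-represented in `sample_x` (the
#' conventional orientation puts the reference/wild-type strain first, so
#' positive values flag proteins down-represented in the mutant).
#'
#' Proteins with aSpC 0 in both strains are flagged `not_comparable`
#' (rendered white) and excluded from significance counts.
#'
#' @param profile a [average_strain_profiles()] result.
#' @param sample_x,sample_y strain labels present in the profile; `sample_x`
#'   is the first-named (X) sample.
#' @param th an [spc_thresholds()] object.
#' @return A data.frame of class `spc_comparison` with one row per protein:
#'   `accession`, `gene_name`, `x`, `y`, `dave`, `dci`, `status`,
#'   `color_hex`; attributes `sample_x`, `sample_y`, `thresholds`.
#' @export
compare_strains <- function(profile, sample_x, sample_y,
                            th = spc_thresholds()) {
  stopifnot(inherits(profile, "strain_profile"))
  for (s in c(sample_x, sample_y)) {
    if (!s %in% colnames(profile$aspc)) {
      stop("strain not in profile: ", s, call. = FALSE)
    }
  }
  x <- profile$aspc[, sample_x]
  y <- profile$aspc[, sample_y]
  d_ave <- dave(x, y)
  d_ci <- dci(x, y)
  status <- classify(d_ave, d_ci, th)
  col <- color_for(d_ave, significant = status %in% c("up_in_X", "up_in_Y"),
                   t_dave = th$t_dave)
  out <- data.frame(
    accession = rownames(profile$aspc),
    gene_name = profile$annotations$gene_name,
    x = unname(x), y = unname(y),
    dave = unname(d_ave), dci = unname(d_ci),
    status = status, color_hex = col$hex,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, sample_x = sample_x, sample_y = sample_y,
            thresholds = th,
            class = c("spc_comparison", "data.frame"))
}

#' Count significant proteins in a comparison
#'
#' @param comparison an [compare_strains()] result.
#' @return Named integer vector: proteins up in X, up in Y, total
#'   significant, comparable, not comparable.
#' @export
significance_counts <- function(comparison) {
  stopifnot(inherits(comparison, "spc_comparison"))
  up_x <- sum(comparison$status == "up_in_X")
  up_y <- sum(comparison$status == "up_in_Y")
  nc <- sum(comparison$status == "not_comparable")
  c(up_in_x = up_x, up_in_y = up_y, significant = up_x + up_y,
    comparable = nrow(comparison) - nc, not_comparable = nc)
}

#' @export
print.spc_comparison <- function(x, ...) {
  cnt <- significance_counts(x)
  cat(sprintf("<spc_comparison> %s vs %s: %d proteins (%d comparable)\n",
              attr(x, "sample_x"), attr(x, "sample_y"), nrow(x),
              cnt[["comparable"]]))
  cat(sprintf("  up in %s: %d | up in %s: %d (DAve >= %.2g, DCI >= %.2g)\n",
              attr(x, "sample_x"), cnt[["up_in_x"]],
              attr(x, "sample_y"), cnt[["up_in_y"]],
              attr(x, "thresholds")$t_dave, attr(x, "thresholds")$t_dci))
  invisible(x)
}

#' Write a comparison as a TSV table
#'
#' DAve is written rounded to 2 decimals (the display convention); `x`,
#' `y` and DCI keep full precision. An optional annotation table supplies
#' the functional class column.
#'
#' @param comparison an [compare_strains()] result.
#' @param path output file path.
#' @param annotations optional [read_annotation_table()] data.frame.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path, annotations = NULL) {
  stopifnot(inherits(comparison, "spc_comparison"))
  df <- as.data.frame(comparison)
  cls <- rep("unknown", nrow(df))
  if (!is.null(annotations)) {
    m <- match(df$accession, annotations$accession)
    cls[!is.na(m)] <- annotations$class[m[!is.na(m)]]
  }
  out <- data.frame(
    accession = df$accession, gene = df$gene_name, function_class = cls,
    x_aSpC = df$x, y_aSpC = df$y,
    DAve = round(df$dave, 2), DCI = df$dci,
    status = df$status, color_hex = df$color_hex,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
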
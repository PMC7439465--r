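#' Align run lists into a protein-by-run spectral-count matrix
#'
#' Merges a set of per-run identification lists on protein accession. The
#' accession set is the union across runs; a cell holds that run's spectral
#' count, with an explicit 0 where the protein was not identified in the
#' run. Gene names and descriptions are taken from the first run that
#' mentions each accession. Accessions that carry a zero count in every run
#' are dropped, so every row of the result has at least one detection.
#'
#' @param runs a list of [run_list] objects, one per LC-MS/MS run. The
#'   (strain, bio_rep, tech_rep) triples must be distinct.
#' @return An object of class `aligned_matrix`: a list with
#'   \describe{
#'     \item{counts}{integer matrix, accessions x runs (explicit zeros).}
#'     \item{runs}{data.frame of run descriptors (run_id, strain, bio_rep,
#'       tech_rep), one row per column of `counts`.}
#'     \item{annotations}{data.frame of accession, gene_name, description.}
#'   }
#' @export
align_lists <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L ||
      !all(vapply(runs, inherits, logical(1), "run_list"))) {
    stop("runs must be a non-empty list of run_list objects", call. = FALSE)
  }
  meta <- data.frame(
    run_id = vapply(runs, `[[`, character(1), "run_id"),
    strain = vapply(runs, `[[`, character(1), "strain"),
    bio_rep = vapply(runs, `[[`, integer(1), "bio_rep"),
    tech_rep = vapply(runs, `[[`, integer(1), "tech_rep"),
    stringsAsFactors = FALSE
  )
  key <- paste(meta$strain, meta$bio_rep, meta$tech_rep, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (strain, bio_rep, tech_rep): ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }

  all_recs <- do.call(rbind, lapply(runs, `[[`, "records"))
  accessions <- unique(all_recs$accession)
  counts <- matrix(0L, nrow = length(accessions), ncol = length(runs),
                   dimnames = list(accessions, meta$run_id))
  for (j in seq_along(runs)) {
    rec <- runs[[j]]$records
    counts[rec$accession, j] <- rec$spc
  }
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  accessions <- accessions[keep]

  first <- !duplicated(all_recs$accession)
  ann <- all_recs[first, c("accession", "gene_name", "description")]
  ann <- ann[match(accessions, ann$accession), , drop = FALSE]
  rownames(ann) <- NULL

  structure(list(counts = counts, runs = meta, annotations = ann),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d proteins x %d runs (%d strains)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$runs$strain))))
  invisible(x)
}

#' Average an aligned matrix into per-strain spectral-count profiles
#'
#' Collapses replicate runs of each strain to a single averaged spectral
#' count (aSpC) per protein. Two averaging policies are supported:
#' `zeros_included` (default) averages over all runs of the strain, counting
#' non-detections as 0; `detected_only` averages only over runs where the
#' protein was detected (aSpC = 0 if never detected). Optionally the mean is
#' nested: technical replicates are averaged within each biological
#' preparation first, then the preparation means are averaged.
#'
#' @param matrix an [align_lists()] result.
#' @param policy `"zeros_included"` or `"detected_only"`.
#' @param nested if `TRUE`, compute mean-of-biological-means instead of the
#'   flat mean over all runs. Only affects unbalanced designs or the
#'   `detected_only` policy.
#' @return An object of class `strain_profile`: list with `aspc` (numeric
#'   matrix, accessions x strains), `detected_runs` (integer matrix of
#'   per-strain runs with SpC > 0), `n_runs` (runs per strain),
#'   `annotations`, and the `policy` used.
#' @export
average_strain_profiles <- function(matrix,
                                    policy = c("zeros_included",
                                               "detected_only"),
                                    nested = FALSE) {
  stopifnot(inherits(matrix, "aligned_matrix"))
  policy <- match.arg(policy)
  strains <- unique(matrix$runs$strain)
  counts <- matrix$counts

  strain_mean <- function(cols) {
    sub <- counts[, cols, drop = FALSE]
    if (policy == "zeros_included") {
      rowMeans(sub)
    } else {
      det <- rowSums(sub > 0)
      m <- rowSums(sub) / pmax(det, 1L)
      m[det == 0L] <- 0
      m
    }
  }

  n_acc <- nrow(counts)
  aspc <- vapply(strains, function(s) {
    cols <- which(matrix$runs$strain == s)
    if (!nested) return(strain_mean(cols))
    bios <- unique(matrix$runs$bio_rep[cols])
    per_bio <- vapply(bios, function(b) {
      strain_mean(cols[matrix$runs$bio_rep[cols] == b])
    }, numeric(n_acc))
    rowMeans(base::matrix(per_bio, nrow = n_acc))
  }, numeric(n_acc))
  aspc <- base::matrix(aspc, nrow = n_acc,
                       dimnames = list(rownames(counts), strains))

  detected <- vapply(strains, function(s) {
    rowSums(counts[, matrix$runs$strain == s, drop = FALSE] > 0)
  }, numeric(n_acc))
  detected <- base::matrix(as.integer(detected), nrow = n_acc,
                           dimnames = dimnames(aspc))

  structure(
    list(aspc = aspc, detected_runs = detected,
         n_runs = table(factor(matrix$runs$strain, levels = strains)),
         annotations = matrix$annotations, policy = policy),
    class = "strain_profile"
  )
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf("<strain_profile> %d proteins x %d strains (policy: %s)\n",
              nrow(x$aspc), ncol(x$aspc), x$policy))
  invisible(x)
}

#' Write an aligned matrix or strain profile as TSV
#'
#' @param x an `aligned_matrix` or `strain_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  if (inherits(x, "aligned_matrix")) {
    df <- cbind(x$annotations, as.data.frame(x$counts))
  } else if (inherits(x, "strain_profile")) {
    df <- cbind(x$annotations, as.data.frame(x$aspc))
  } else {
    stop("x must be an aligned_matrix or strain_profile", call. = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
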
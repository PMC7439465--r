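#' Construct a per-run protein identification list
#'
#' A `run_list` holds one LC-MS/MS run's identified proteins with their
#' spectral counts (SpC, the number of MS/MS spectra attributed to each
#' protein) and unique-peptide counts, together with the run's position in
#' the experimental design (strain, biological preparation, technical
#' replicate).
#'
#' @param records data.frame with columns `accession`, `gene_name`,
#'   `description`, `unique_peptides`, `spc`. `gene_name` and `description`
#'   may be empty strings; `unique_peptides` and `spc` must be non-negative
#'   integers; accessions must be non-empty and unique within the run.
#' @param strain condition label, e.g. `"WT"` or `"ubp8"`.
#' @param bio_rep biological preparation index (integer >= 1).
#' @param tech_rep technical replicate index (integer >= 1).
#' @param run_id optional run identifier; defaults to
#'   `"<strain>_b<bio_rep>_t<tech_rep>"`.
#' @return An object of class `run_list`.
#' @export
run_list <- function(records, strain, bio_rep = 1L, tech_rep = 1L,
                     run_id = NULL) {
  stopifnot(is.data.frame(records))
  for (col in c("gene_name", "description")) {
    if (is.null(records[[col]])) records[[col]] <- rep("", nrow(records))
    records[[col]][is.na(records[[col]])] <- ""
  }
  required <- c("accession", "gene_name", "description",
                "unique_peptides", "spc")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[required]
  records$accession <- as.character(records$accession)
  records$gene_name <- as.character(records$gene_name)
  records$description <- as.character(records$description)
  records$unique_peptides <- .as_strict_integer(records$unique_peptides,
                                                "unique_peptides")
  records$spc <- .as_strict_integer(records$spc, "spc")
  rownames(records) <- NULL

  if (any(!nzchar(records$accession)) || anyNA(records$accession)) {
    stop("accession must be non-empty for every record", call. = FALSE)
  }
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) within run: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(records$spc < 0L) || any(records$unique_peptides < 0L)) {
    stop("spc and unique_peptides must be non-negative", call. = FALSE)
  }

  bio_rep <- as.integer(bio_rep)
  tech_rep <- as.integer(tech_rep)
  stopifnot(length(strain) == 1L, bio_rep >= 1L, tech_rep >= 1L)
  if (is.null(run_id)) {
    run_id <- sprintf("%s_b%d_t%d", strain, bio_rep, tech_rep)
  }
  structure(
    list(run_id = as.character(run_id), strain = as.character(strain),
         bio_rep = bio_rep, tech_rep = tech_rep, records = records),
    class = "run_list"
  )
}

# strict integer parse: "3" and 3 are fine, "3.5", 3.5 and "x" are not
.as_strict_integer <- function(x, what) {
  if (is.integer(x)) return(x)
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(x != trunc(x))) {
      stop(what, " must be integer-valued", call. = FALSE)
    }
    return(as.integer(x))
  }
  x <- as.character(x)
  bad <- !grepl("^[+-]?[0-9]+$", trimws(x))
  if (any(bad)) {
    stop("non-integer value in column '", what, "' at row ",
         which(bad)[1L], ": '", x[which(bad)[1L]], "'", call. = FALSE)
  }
  as.integer(x)
}

#' @export
print.run_list <- function(x, ...) {
  cat(sprintf("<run_list> %s (strain %s, bio %d, tech %d): %d proteins, total SpC %d\n",
              x$run_id, x$strain, x$bio_rep, x$tech_rep,
              nrow(x$records), sum(x$records$spc)))
  invisible(x)
}

#' Read a protein identification list from a TSV file
#'
#' Parses a tab-separated search-engine export with a header row naming at
#' least `accession`, `unique_peptides` and `spc`; `gene_name` and
#' `description` are optional and default to empty strings. Integer columns
#' are parsed strictly (a non-integer token is an error naming the row).
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @inheritParams run_list
#' @return A [run_list].
#' @seealso [write_run_list()] for the inverse operation.
#' @export
read_run_list <- function(path, strain, bio_rep = 1L, tech_rep = 1L,
                          run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  required <- c("accession", "unique_peptides", "spc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  run_list(df, strain = strain, bio_rep = bio_rep, tech_rep = tech_rep,
           run_id = run_id)
}

#' Write a protein identification list to a TSV file
#'
#' Writes the run's records as UTF-8 tab-separated text with a header row
#' and no quoting, so that [read_run_list()] reproduces the input
#' field-for-field (empty gene names and descriptions stay empty strings).
#'
#' @param run a [run_list].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_list <- function(run, path) {
  stopifnot(inherits(run, "run_list"))
  utils::write.table(run$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter a run list on unique-peptide support
#'
#' Retains proteins identified with at least `min_unique` unique peptides —
#' the standard identification-confidence criterion for spectral-count
#' analysis (default: at least one unique peptide). Record order is
#' preserved and the operation is idempotent.
#'
#' @param run a [run_list].
#' @param min_unique minimum unique-peptide count (integer >= 0).
#' @return A [run_list] with the retained records.
#' @export
filter_min_unique_peptides <- function(run, min_unique = 1L) {
  stopifnot(inherits(run, "run_list"), min_unique >= 0L)
  keep <- run$records$unique_peptides >= min_unique
  out <- run
  out$records <- run$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Read a dataset manifest mapping files to runs
#'
#' The manifest is a tab-separated table with columns `path`, `strain`,
#' `bio_rep`, `tech_rep` (and optionally `run_id`). Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @param min_unique if not `NULL`, apply [filter_min_unique_peptides()]
#'   with this threshold to every run as it is read (the filter is applied
#'   per run, before alignment).
#' @return A list of [run_list] objects.
#' @export
read_manifest <- function(path, min_unique = 1L) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  mf <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  required <- c("path", "strain", "bio_rep", "tech_rep")
  missing_cols <- setdiff(required, names(mf))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  base <- dirname(path)
  lapply(seq_len(nrow(mf)), function(i) {
    f <- mf$path[i]
    if (!file.exists(f)) f <- file.path(base, mf$path[i])
    if (!file.exists(f)) {
      stop("manifest references missing file: ", mf$path[i], call. = FALSE)
    }
    rl <- read_run_list(f, strain = mf$strain[i], bio_rep = mf$bio_rep[i],
                        tech_rep = mf$tech_rep[i],
                        run_id = if ("run_id" %in% names(mf)) mf$run_id[i])
    if (!is.null(min_unique)) {
      rl <- filter_min_unique_peptides(rl, min_unique)
    }
    rl
  })
}
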
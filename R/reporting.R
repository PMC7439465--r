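#' Per-strain protein detection sets
#'
#' A protein belongs to a strain's set when it has a spectral count > 0 in
#' at least `min_runs` runs of that strain. With the default `min_runs = 1`,
#' identification in any run counts as presence, which is how detection
#' Venn diagrams are usually drawn; higher values make presence stricter.
#'
#' @param matrix an [align_lists()] result.
#' @param min_runs minimum number of detecting runs (integer >= 1).
#' @return A named list (class `presence_sets`) of accession character
#'   vectors, one per strain.
#' @export
presence_sets <- function(matrix, min_runs = 1L) {
  stopifnot(inherits(matrix, "aligned_matrix"), min_runs >= 1L)
  strains <- unique(matrix$runs$strain)
  sets <- lapply(strains, function(s) {
    det <- rowSums(matrix$counts[, matrix$runs$strain == s,
                                 drop = FALSE] > 0)
    rownames(matrix$counts)[det >= min_runs]
  })
  names(sets) <- strains
  structure(sets, class = "presence_sets")
}

#' Partition detection sets into disjoint Venn regions
#'
#' Assigns every accession in the union of the sets to exactly one of the
#' 2^n - 1 non-empty membership patterns (15 regions for 4 strains). Also
#' reports two derived aggregates relative to a reference set (default the
#' first): the number of proteins shared with the reference (union of
#' regions containing it) and the number absent from it.
#'
#' @param sets a [presence_sets()] object or named list of 2 to 5 character
#'   vectors.
#' @param reference name of the reference set for the aggregates.
#' @return An object of class `venn_partition`: list with `regions` (a
#'   data.frame of region label, degree, count), `members` (named list of
#'   accessions per region), `union_size`, `reference`, `with_reference`,
#'   `absent_from_reference`.
#' @export
venn_partition <- function(sets, reference = names(sets)[1]) {
  sets <- unclass(sets)
  if (!is.list(sets) || length(sets) < 2L) {
    stop("at least 2 named sets are required", call. = FALSE)
  }
  if (length(sets) > 5L) {
    stop("at most 5 sets are supported", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  stopifnot(reference %in% names(sets))
  labels <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- base::matrix(membership, nrow = length(universe),
                             dimnames = list(universe, labels))

  pattern <- apply(membership, 1L, function(row) {
    paste(labels[row], collapse = "&")
  })
  # all 2^n - 1 patterns, in degree-then-label order
  combos <- unlist(lapply(seq_along(labels), function(k) {
    apply(utils::combn(labels, k), 2L, paste, collapse = "&")
  }))
  members <- lapply(combos, function(cmb) universe[pattern == cmb])
  names(members) <- combos

  regions <- data.frame(
    region = combos,
    degree = lengths(strsplit(combos, "&", fixed = TRUE)),
    count = lengths(members),
    stringsAsFactors = FALSE
  )
  in_ref <- grepl(paste0("(^|&)", reference, "(&|$)"), combos)
  structure(
    list(regions = regions, members = members,
         union_size = length(universe), reference = reference,
         with_reference = sum(regions$count[in_ref]),
         absent_from_reference = sum(regions$count[!in_ref])),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d sets, %d proteins in union\n",
              max(x$regions$degree), x$union_size))
  cat(sprintf("  shared with %s: %d | absent from %s: %d\n",
              x$reference, x$with_reference, x$reference,
              x$absent_from_reference))
  print(x$regions[x$regions$count > 0, ], row.names = FALSE)
  invisible(x)
}

#' @export
#' @importFrom graphics barplot par
plot.venn_partition <- function(x, ...) {
  keep <- x$regions$count > 0
  old <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(x$regions$count[keep],
                    names.arg = x$regions$region[keep], las = 2,
                    ylab = "proteins",
                    main = "Detection-set partition", ...)
  invisible(x)
}

#' Write a Venn partition summary as TSV
#'
#' One row per region with its member accessions, followed by the derived
#' aggregates relative to the reference set.
#'
#' @param partition a [venn_partition()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_venn_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "venn_partition"))
  df <- partition$regions
  df$members <- vapply(partition$members, paste, character(1),
                       collapse = ",")
  extra <- data.frame(
    region = c(paste0("with_", partition$reference),
               paste0("absent_from_", partition$reference), "union"),
    degree = NA_integer_,
    count = c(partition$with_reference,
              partition$absent_from_reference, partition$union_size),
    members = "", stringsAsFactors = FALSE
  )
  utils::write.table(rbind(df, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a functional annotation table
#'
#' TSV with columns `accession`, `class` (functional class, e.g.
#' "glycolysis"; unknowns as "unknown"/"unclear"), and optionally
#' `human_orthologue` and `interactions` (known physical/genetic
#' interaction flags, e.g. "P", "G", "P/G").
#'
#' @param path annotation TSV path.
#' @return data.frame with one row per accession.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("accession", "class"), names(df))
  if (length(missing_cols) > 0L) {
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$accession)) {
    stop("annotation table has duplicate accessions", call. = FALSE)
  }
  for (col in c("human_orthologue", "interactions")) {
    if (is.null(df[[col]])) df[[col]] <- ""
  }
  df
}

#' Assemble the color-coded differential table
#'
#' Builds a table in the style of a multi-comparison differential summary:
#' one row per protein that is significant in at least one of the supplied
#' pairwise comparisons, with a DAve value and chromatic code per
#' comparison (light shades and white for comparisons where the protein
#' does not pass the filter), grouped by functional class. Proteins not
#' significant anywhere are excluded (they remain available in the
#' per-comparison exports).
#'
#' @param comparisons named list of [compare_strains()] results sharing an
#'   accession universe (typically the three mutant-vs-reference
#'   comparisons).
#' @param annotations optional [read_annotation_table()] data.frame; a
#'   missing annotation maps to class "unknown".
#' @return data.frame with columns `accession`, `gene`, `function_class`,
#'   `human_orthologue`, `interactions`, then per comparison
#'   `DAve_<name>` (rounded to 2 decimals) and `color_<name>` (hex), sorted
#'   by functional class then gene.
#' @export
build_differential_table <- function(comparisons, annotations = NULL) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1L,
            all(vapply(comparisons, inherits, logical(1),
                       "spc_comparison")))
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons)))) {
    names(comparisons) <- vapply(comparisons, function(cm) {
      paste0(attr(cm, "sample_x"), "_vs_", attr(cm, "sample_y"))
    }, character(1))
  }
  sig_acc <- unique(unlist(lapply(comparisons, function(cm) {
    cm$accession[cm$status %in% c("up_in_X", "up_in_Y")]
  })))
  first <- comparisons[[1]]
  base <- data.frame(
    accession = sig_acc,
    gene = first$gene_name[match(sig_acc, first$accession)],
    stringsAsFactors = FALSE
  )
  base$gene[is.na(base$gene)] <- ""
  base$function_class <- rep("unknown", nrow(base))
  base$human_orthologue <- rep("", nrow(base))
  base$interactions <- rep("", nrow(base))
  if (!is.null(annotations) && nrow(base) > 0L) {
    m <- match(base$accession, annotations$accession)
    hit <- !is.na(m)
    base$function_class[hit] <- annotations$class[m[hit]]
    base$human_orthologue[hit] <- annotations$human_orthologue[m[hit]]
    base$interactions[hit] <- annotations$interactions[m[hit]]
  }
  for (nm in names(comparisons)) {
    cm <- comparisons[[nm]]
    m <- match(base$accession, cm$accession)
    base[[paste0("DAve_", nm)]] <- round(cm$dave[m], 2)
    base[[paste0("color_", nm)]] <- ifelse(is.na(m), "#FFFFFF",
                                           cm$color_hex[m])
  }
  ord <- order(base$function_class, base$gene, base$accession)
  base <- base[ord, , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Export node and edge tables for a protein interaction network
#'
#' Prepares tables importable by standard graph tools: a node table
#' carrying the per-comparison DAve colors of the differential table, and
#' an edge table filtered on interaction confidence (edges with score below
#' `min_score` are removed; a score exactly at the threshold is kept,
#' matching the conventional "confidence >= 0.4" cut). Nodes left without
#' edges are retained as singletons. Edges naming a protein absent from the
#' node table are skipped with a warning.
#'
#' @param table a [build_differential_table()] result (or any data.frame
#'   with an `accession` column).
#' @param edges data.frame with columns `acc_a`, `acc_b`, `score`
#'   (confidence in \[0, 1\]).
#' @param min_score minimum confidence score to keep an edge.
#' @return list with `nodes` (the input table) and `edges` (the filtered
#'   edge table).
#' @export
export_network <- function(table, edges, min_score = 0.4) {
  stopifnot(is.data.frame(table), "accession" %in% names(table))
  if (is.null(edges) || nrow(edges) == 0L) {
    return(list(nodes = table,
                edges = data.frame(acc_a = character(0),
                                   acc_b = character(0),
                                   score = numeric(0))))
  }
  missing_cols <- setdiff(c("acc_a", "acc_b", "score"), names(edges))
  if (length(missing_cols) > 0L) {
    stop("edge table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("edge scores must lie in [0, 1]", call. = FALSE)
  }
  known <- edges$acc_a %in% table$accession &
    edges$acc_b %in% table$accession
  if (any(!known)) {
    bad <- unique(c(edges$acc_a[!known], edges$acc_b[!known]))
    bad <- setdiff(bad, table$accession)
    warning("skipping ", sum(!known),
            " edge(s) referencing unknown accession(s): ",
            paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    edges <- edges[known, , drop = FALSE]
  }
  edges <- edges[edges$score >= min_score, , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = table, edges = edges)
}
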